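make_segments <- function(length_mm, natural, n_discarded = 0L) {
  n <- length(length_mm)
  df <- data.frame(segment_id = seq_len(n),
                   component = seq_len(n),
                   r1 = rep(1L, n), c1 = rep(1L, n),
                   r2 = rep(2L, n), c2 = rep(2L, n),
                   n_px = rep(10L, n), length_mm = length_mm,
                   orientation_deg = rep(45, n),
                   hemifield = rep("superior", n), stringsAsFactors = FALSE)
  df$natural_oblique <- natural
  structure(df, n_discarded = n_discarded,
            class = c("vessel_segments", "data.frame"))
}

test_that("laterality normalization mirrors left eyes only", {
  sc <- generate_vessel_image(vessel_scene_params(image_size_px = 128,
                                                  n_trunks = 4, seed = 3))
  expect_identical(normalize_laterality(sc$image), sc$image)  # OD untouched

  m <- sc$truth_mask
  os1 <- normalize_laterality(m, "OS")
  expect_identical(normalize_laterality(os1, "OS")$pixels, m$pixels)  # involution
  expect_error(normalize_laterality(m, "LEFT"), "OD")

  # an OS bar at +30 degrees appears at -30 degrees after normalization
  line <- matrix(0L, 128, 128)
  for (i in 0:40) line[80 - round(i * tan(30 * pi / 180)), 40 + i] <- 1L
  seg_od <- decompose_segments(as_skel(line))
  seg_os <- decompose_segments(normalize_laterality(as_skel(line), "OS"))
  expect_equal(seg_os$orientation_deg, -seg_od$orientation_deg, tolerance = 1e-9)
  expect_equal(abs(seg_od$orientation_deg), 30, tolerance = 2)
})

test_that("branch points are skeleton pixels with three or more neighbours", {
  line <- `[<-`(matrix(0L, 64, 64), 30, 5:60, 1L)
  expect_equal(nrow(find_branch_points(as_skel(line))), 0)

  tee <- matrix(0L, 64, 64)
  tee[30, 5:60] <- 1L
  tee[31:50, 32] <- 1L
  expect_equal(nrow(find_branch_points(as_skel(tee))), 1)

  plus <- matrix(0L, 65, 65)
  plus[33, 5:61] <- 1L
  plus[5:61, 33] <- 1L
  bp <- find_branch_points(as_skel(plus))
  expect_equal(nrow(bp), 1)
  expect_equal(c(bp$row, bp$col), c(33, 33))
})

test_that("segment decomposition cuts at branch points and drops loops", {
  line <- `[<-`(matrix(0L, 64, 110), 30, 6:105, 1L)
  segs <- decompose_segments(as_skel(line))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$orientation_deg, 0)
  expect_equal(segs$n_px, 100)

  tee <- matrix(0L, 64, 110)
  tee[30, 6:105] <- 1L
  tee[31:55, 55] <- 1L
  expect_equal(nrow(decompose_segments(as_skel(tee))), 3)

  ring <- matrix(0L, 64, 64)   # diamond loop: no pixel has > 2 neighbours
  for (r in 1:64) for (c in 1:64) if (abs(r - 32) + abs(c - 32) == 6) ring[r, c] <- 1L
  segs <- decompose_segments(as_skel(ring))
  expect_equal(nrow(segs), 0)
  expect_equal(attr(segs, "n_discarded"), 1)
})

test_that("chord orientation is undirected and lands in (-90, 90]", {
  expect_equal(segment_orientation(c(0, 0), c(10, 0)), 0)
  expect_equal(segment_orientation(c(0, 0), c(10, 10)), 45)
  expect_equal(segment_orientation(c(0, 0), c(0, 10)), 90)
  expect_equal(segment_orientation(c(0, 10), c(0, 0)), 90)
  expect_equal(segment_orientation(c(10, 10), c(0, 0)), 45)
  expect_error(segment_orientation(c(1, 1), c(1, 1)), "coincident")
})

test_that("natural-oblique classification follows the vortex-vein quadrants", {
  segs <- make_segments(c(1, 1, 1, 1, 1, 1), rep(NA, 6))
  segs$orientation_deg <- c(37, -37, 37, -37, 0, 90)
  segs$hemifield <- c("superior", "superior", "inferior", "inferior",
                      "superior", "inferior")
  out <- classify_natural_oblique(segs)
  expect_identical(out$natural_oblique, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))

  # inclusive bounds pull the axis-aligned chords into the band
  out2 <- classify_natural_oblique(segs, symmetry_config(include_bounds = TRUE))
  expect_identical(out2$natural_oblique[5:6], c(TRUE, FALSE))
})

test_that("symmetry index is the natural length share", {
  segs <- make_segments(c(2, 1, 1), c(TRUE, TRUE, FALSE))
  res <- symmetry_index(segs)
  expect_equal(res$symmetry_index_pct, 75)
  expect_equal(res$total_length_mm, 4)
  expect_equal(res$n_segments, 3)

  expect_equal(symmetry_index(make_segments(c(1, 2), c(TRUE, TRUE)))$symmetry_index_pct, 100)
  expect_equal(symmetry_index(make_segments(c(1, 2), c(FALSE, FALSE)))$symmetry_index_pct, 0)
  expect_error(symmetry_index(make_segments(numeric(0), logical(0))), "no retained")
})

test_that("a mirror-symmetric oblique pattern scores 100 and its antisymmetric twin 0", {
  # +45-degree segments in the superior quadrants, their -45 mirrors in
  # the inferior quadrants: every segment points at its hemifield's
  # temporal vortex vein
  n <- 129L; fov <- 65L
  sk <- matrix(0L, n, n)
  for (i in 1:40) {
    sk[fov - 10 - i, 14 + i] <- 1L
    sk[fov + 10 + i, 14 + i] <- 1L
    sk[fov - 10 - i, 74 + i] <- 1L
    sk[fov + 10 + i, 74 + i] <- 1L
  }
  segs <- classify_natural_oblique(decompose_segments(as_skel(sk)))
  expect_equal(symmetry_index(segs)$symmetry_index_pct, 100)

  # rotate every segment 90 degrees in place: all chords now point away
  # from the vortex-vein direction and nothing is natural
  anti <- matrix(0L, n, n)
  for (i in 1:40) {
    anti[fov - 10 - i, 55 - i] <- 1L
    anti[fov + 10 + i, 55 - i] <- 1L
    anti[fov - 10 - i, 115 - i] <- 1L
    anti[fov + 10 + i, 115 - i] <- 1L
  }
  segs_a <- classify_natural_oblique(decompose_segments(as_skel(anti)))
  expect_equal(symmetry_index(segs_a)$symmetry_index_pct, 0)
})

test_that("an image and its mirrored OS twin give identical metrics", {
  for (seed in c(4, 9)) {
    sc <- generate_vessel_image(vessel_scene_params(image_size_px = 192,
                                                    n_trunks = 6, seed = seed))
    od <- sc$image
    os <- od
    os$pixels <- od$pixels[, ncol(od$pixels):1, drop = FALSE]
    os$eye_side <- "OS"
    em_od <- compute_eye_metrics(od)
    em_os <- compute_eye_metrics(os)
    expect_identical(em_od$symmetry_index_pct, em_os$symmetry_index_pct)
    expect_identical(em_od$vessel_area_mm2, em_os$vessel_area_mm2)
    expect_identical(em_od$vessel_length_mm, em_os$vessel_length_mm)
  }
})

test_that("segment decomposition conserves skeleton mass", {
  for (seed in 1:3) {
    sc <- generate_vessel_image(vessel_scene_params(image_size_px = 192,
                                                    n_trunks = 6, seed = seed))
    sk <- skeletonize_mask(denoise_mask(binarize_enface(sc$image)))
    segs <- decompose_segments(sk)
    expect_equal(sum(segs$n_px) + attr(segs, "branch_px") +
                   attr(segs, "discarded_px"),
                 attr(segs, "total_skeleton_px"))
  }
})

test_that("the symmetry index always lies in [0, 100]", {
  for (seed in 1:4) {
    s <- c(0, 0.3, 0.7, 1)[seed]
    sc <- generate_vessel_image(vessel_scene_params(image_size_px = 160,
                                                    n_trunks = 5,
                                                    symmetry_fraction = s,
                                                    seed = seed))
    em <- compute_eye_metrics(sc$image)
    expect_gte(em$symmetry_index_pct, 0)
    expect_lte(em$symmetry_index_pct, 100)
  }
})
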