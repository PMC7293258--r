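test_that("local-mean binarization segments the dark phase", {
  # constant image: nothing sits below the local mean minus a positive offset
  flat <- as_image(matrix(100, 100, 100))
  expect_equal(sum(binarize_enface(flat, binarization_config(offset = 5))$pixels), 0)

  # a dark band far below its surround is fully captured
  px <- matrix(200, 120, 120)
  px[51:70, ] <- 30
  m <- binarize_enface(as_image(px), binarization_config(window_px = 51, offset = 10))
  expect_true(all(m$pixels[53:68, 3:118] == 1L))
  expect_identical(dim(m$pixels), dim(px))

  # image smaller than the threshold window is rejected
  expect_error(binarize_enface(as_image(matrix(100, 64, 64)),
                               binarization_config(window_px = 101)),
               "smaller")
})

test_that("binarization recovers the generator's ground-truth mask", {
  sc <- generate_vessel_image(vessel_scene_params(seed = 11))
  m <- denoise_mask(binarize_enface(sc$image))
  expect_gt(dice(m$pixels, sc$truth_mask$pixels), 0.90)
})

test_that("denoising removes specks and fills holes by size", {
  speck <- bar_mask(80, 80, 10:10, 10:14)  # 5-px speck
  expect_equal(sum(denoise_mask(speck, 100, 0)$pixels), 0)

  # zero thresholds are the identity
  m <- bar_mask(80, 80, 20:40, 30:50)
  expect_identical(denoise_mask(m, 0, 0)$pixels, m$pixels)

  # 200-px blob containing a 10-px hole becomes a 210-px solid blob
  blob <- matrix(0L, 80, 80)
  blob[11:31, 11:20] <- 1L          # 210-px rectangle
  blob[15:19, 14:15] <- 0L          # carve a 10-px hole: 200 px remain
  expect_equal(sum(blob), 200)
  out <- denoise_mask(vessel_mask(blob, psz), 0, 50)
  expect_equal(sum(out$pixels), 210)

  expect_error(denoise_mask(m, -1, 0), ">= 0")
})

test_that("hole filling does not touch border-connected background", {
  m <- matrix(1L, 60, 60)
  m[1:30, 30] <- 0L   # channel open to the border: not a hole
  out <- denoise_mask(vessel_mask(m, psz), 0, 1000)
  expect_equal(sum(out$pixels), 60 * 60 - 30)
})

test_that("thinning yields thin, topology-preserving skeletons", {
  empty <- vessel_mask(matrix(0L, 80, 80), psz)
  expect_equal(sum(skeletonize_mask(empty)$pixels), 0)

  # 100 x 5 bar -> a single one-pixel horizontal line
  bar <- bar_mask(80, 120, 40:44, 11:110)
  sk <- skeletonize_mask(bar)
  pxs <- which(sk$pixels == 1L, arr.ind = TRUE)
  expect_length(unique(pxs[, 1]), 1L)               # one row
  expect_gte(nrow(pxs), 92)                          # ~100 px long
  expect_lte(nrow(pxs), 100)
  expect_true(all(bar$pixels[sk$pixels == 1L] == 1L))  # containment

  # plus of two 101 x 5 bars -> connected skeleton, exactly one branch point
  plus <- matrix(0L, 121, 121)
  plus[59:63, 11:111] <- 1L
  plus[11:111, 59:63] <- 1L
  skp <- skeletonize_mask(vessel_mask(plus, psz))
  expect_equal(max(choroidmetrics:::.label_cpp(skp$pixels, 8L)), 1L)
  expect_equal(nrow(find_branch_points(skp)), 1L)
})

test_that("skeletons contain no fully-foreground 2x2 block", {
  for (seed in 1:3) {
    sc <- generate_vessel_image(vessel_scene_params(image_size_px = 192,
                                                    n_trunks = 6, seed = seed))
    sk <- skeletonize_mask(denoise_mask(binarize_enface(sc$image)))$pixels
    n22 <- sum(sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
                 sk[-nrow(sk), -1] & sk[-1, -1])
    expect_equal(n22, 0)
    # every mask component survives thinning
    m <- denoise_mask(binarize_enface(sc$image))$pixels
    expect_equal(max(choroidmetrics:::.label_cpp(m, 8L)) == 0,
                 sum(sk) == 0)
  }
})

test_that("vessel area scales foreground count by the squared pixel pitch", {
  m <- matrix(0L, 512, 512)
  m[1:100, 1:100] <- 1L  # 10,000 px
  expect_equal(vessel_area(vessel_mask(m, psz)), 10000 * psz^2, tolerance = 1e-12)
  expect_equal(vessel_area(vessel_mask(matrix(0L, 64, 64), psz)), 0)
  expect_equal(vessel_area(vessel_mask(matrix(1L, 512, 512), psz)), 49)
})

test_that("skeleton length is the step sum over unique adjacencies", {
  horiz <- as_skel(`[<-`(matrix(0L, 64, 110), 30, 6:105, 1L))
  expect_equal(skeleton_length(horiz), 99 * psz)

  diagm <- matrix(0L, 110, 110)
  diagm[cbind(6:105, 6:105)] <- 1L
  expect_equal(skeleton_length(as_skel(diagm)), 99 * sqrt(2) * psz)

  # L-shape: two 50-px arms sharing the corner pixel. The brute-force
  # pair-counting oracle gives 98 orthogonal steps plus the inner-corner
  # diagonal adjacency.
  lm <- matrix(0L, 80, 80)
  lm[20, 11:60] <- 1L
  lm[20:69, 60] <- 1L
  expect_equal(brute_steps(lm), 98 + sqrt(2))
  expect_equal(skeleton_length(as_skel(lm)), brute_steps(lm) * psz)
})

test_that("mean diameter is area over length with guarded edge cases", {
  expect_equal(mean_vessel_diameter(1.0, 10.0), 0.1)
  expect_equal(mean_vessel_diameter(0, 5), 0)
  expect_error(mean_vessel_diameter(1, 0), "undefined")

  # analytic rectangle: 100 x 5 bar recovers its true width within 10%
  bar <- bar_mask(64, 120, 30:34, 11:110)
  d <- mean_vessel_diameter(vessel_area(bar),
                            skeleton_length(skeletonize_mask(bar)))
  expect_lt(abs(d - 5 * psz) / (5 * psz), 0.10)
})

test_that("diameter recovery holds for bar widths 3..21 px", {
  for (w in seq(3, 21, by = 2)) {
    bar <- bar_mask(64, 420, 30:(30 + w - 1), 11:410)
    d_px <- mean_vessel_diameter(vessel_area(bar),
                                 skeleton_length(skeletonize_mask(bar))) / psz
    expect_lt(abs(d_px - w) / w, 0.15)
  }
})

test_that("per-eye metrics recover generator parameters and are deterministic", {
  p <- vessel_scene_params(vessel_width_px = 12, vessel_width_sd_px = 0,
                           symmetry_fraction = 1, seed = 2)
  sc <- generate_vessel_image(p)
  em <- compute_eye_metrics(sc$image)
  expect_true(em$valid)
  expect_lt(abs(em$mean_diameter_mm - 12 * psz) / (12 * psz), 0.15)
  expect_gte(em$symmetry_index_pct, 90)
  expect_equal(em$vessel_area_mm2,
               em$mean_diameter_mm * em$vessel_length_mm, tolerance = 1e-12)

  expect_identical(em, compute_eye_metrics(sc$image))

  blank <- compute_eye_metrics(as_image(matrix(180, 128, 128)))
  expect_false(blank$valid)
  expect_true(is.na(blank$mean_diameter_mm))
})

test_that("metrics covary correctly with the pixel pitch", {
  sc <- generate_vessel_image(vessel_scene_params(image_size_px = 192,
                                                  n_trunks = 6, seed = 5))
  img2 <- sc$image
  img2$pixel_size_mm <- 2 * sc$image$pixel_size_mm
  a <- compute_eye_metrics(sc$image)
  b <- compute_eye_metrics(img2)
  expect_equal(b$vessel_area_mm2, 4 * a$vessel_area_mm2, tolerance = 1e-12)
  expect_equal(b$vessel_length_mm, 2 * a$vessel_length_mm, tolerance = 1e-12)
  expect_equal(b$mean_diameter_mm, 2 * a$mean_diameter_mm, tolerance = 1e-12)
  expect_equal(b$symmetry_index_pct, a$symmetry_index_pct, tolerance = 1e-12)
})

test_that("rotating a mask by 90 degrees preserves area and near-preserves length", {
  shapes <- list(
    bar_mask(100, 100, 40:44, 11:90)$pixels,
    `[<-`(`[<-`(matrix(0L, 101, 101), 48:52, 11:91, 1L), 11:91, 48:52, 1L))
  for (m in shapes) {
    r <- t(m)[ncol(m):1, , drop = FALSE]  # 90-degree rotation
    expect_equal(vessel_area(vessel_mask(r, psz)),
                 vessel_area(vessel_mask(m, psz)))
    l1 <- skeleton_length(skeletonize_mask(vessel_mask(m, psz)))
    l2 <- skeleton_length(skeletonize_mask(vessel_mask(r, psz)))
    expect_lte(abs(l1 - l2) / psz, sqrt(2))
  }
})
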