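#' Symmetry-index parameters
#'
#' The running-pattern statistic classifies each branch-free centerline
#' segment by the angle of its endpoint chord in the laterality-normalized
#' frame (+x temporal, +y superior). A segment is a "natural oblique
#' vessel" when its chord points from the macula toward the hemifield's
#' temporal vortex vein: within `band_deg` for the superior hemifield and
#' within the mirrored band for the inferior hemifield.
#'
#' @param min_segment_px segments with fewer pixels are discarded as
#'   thinning artifacts (default 5; about 0.07 mm at the 7/512 mm pitch).
#' @param band_deg two angles `c(lo, hi)` bounding the superior natural
#'   band in degrees; default the full open quadrant `c(0, 90)`.
#' @param include_bounds treat segments exactly on a band bound (e.g.
#'   exactly horizontal or vertical) as natural? Default `FALSE`, which
#'   keeps the treatment of the two hemifields exactly mirror-symmetric.
#' @return A `symmetry_config` list.
#' @export
symmetry_config <- function(min_segment_px = 5L, band_deg = c(0, 90),
                            include_bounds = FALSE) {
  if (min_segment_px < 2) stop("`min_segment_px` must be >= 2", call. = FALSE)
  if (length(band_deg) != 2L || band_deg[1] < 0 || band_deg[2] > 90 ||
      band_deg[1] >= band_deg[2])
    stop("`band_deg` must be c(lo, hi) with 0 <= lo < hi <= 90", call. = FALSE)
  structure(list(min_segment_px = as.integer(min_segment_px),
                 band_deg = as.numeric(band_deg),
                 include_bounds = isTRUE(include_bounds)),
            class = "symmetry_config")
}

#' Locate skeleton branch points
#'
#' Branch pixels are skeleton pixels with three or more skeleton
#' neighbours in 8-connectivity. At a junction several adjacent pixels
#' typically satisfy this at once, so adjacent branch pixels are merged
#' into one branch point, reported at the (rounded) cluster centroid;
#' a T- or plus-junction therefore yields exactly one branch point.
#'
#' @param skel a `vessel_skeleton`.
#' @return A data frame with columns `row`, `col` and `n_px` (pixels in
#'   the junction cluster); possibly 0 rows.
#' @export
find_branch_points <- function(skel) {
  stopifnot(inherits(skel, "vessel_mask"))
  bp <- branch_pixel_matrix(skel$pixels)
  lab <- .label_cpp(bp, 8L)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(row = integer(), col = integer(), n_px = integer()))
  idx <- which(lab > 0L, arr.ind = TRUE)
  comp <- lab[lab > 0L]
  data.frame(
    row = as.integer(round(tapply(idx[, 1L], comp, mean))),
    col = as.integer(round(tapply(idx[, 2L], comp, mean))),
    n_px = as.integer(tabulate(comp)),
    row.names = NULL)
}

# 0/1 matrix of skeleton pixels with >= 3 skeleton neighbours.
branch_pixel_matrix <- function(px) {
  nb <- .neighbour_count_cpp(px)
  (px == 1L & nb >= 3L) * 1L
}

# Step-sum length (px units) of the adjacencies within one pixel set,
# given as a logical matrix.
component_steps <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  n_orth <- sum(m[, -nc] & m[, -1L]) + sum(m[-nr, ] & m[-1L, ])
  n_diag <- sum(m[-nr, -nc] & m[-1L, -1L]) + sum(m[-nr, -1L] & m[-1L, -nc])
  n_orth + sqrt(2) * n_diag
}

#' Undirected chord orientation in degrees
#'
#' Angle between the straight line connecting two segment endpoints and
#' the horizontal axis of the normalized frame (+x temporal, +y
#' superior), mapped to (-90, 90]. Endpoint order is irrelevant.
#'
#' @param p1,p2 endpoints as `c(x, y)` in the normalized frame.
#' @return Angle in degrees in (-90, 90].
#' @export
segment_orientation <- function(p1, p2) {
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  if (dx == 0 && dy == 0)
    stop("coincident endpoints have no orientation", call. = FALSE)
  if (dx == 0) return(90)
  atan(dy / dx) * 180 / pi
}

#' Decompose a skeleton into branch-free vessel segments
#'
#' Branch points are removed and each remaining 8-connected component
#' with two endpoints becomes one segment, described by its endpoint
#' chord. Closed loops (no endpoints) and components shorter than
#' `min_segment_px` are discarded but counted. The input skeleton must
#' already be in the laterality-normalized frame (see
#' [normalize_laterality()]).
#'
#' @param skel a `vessel_skeleton` in the normalized frame.
#' @param fovea `c(row, col)` of the fovea; defaults to the image center.
#'   Segments are assigned to the superior or inferior hemifield by the
#'   side of the horizontal fovea line their chord midpoint falls on
#'   (midpoints exactly on the line count as inferior).
#' @param min_segment_px minimum pixel count for a retained segment.
#' @return A data frame of class `vessel_segments`, one row per retained
#'   segment: `segment_id`, endpoint pixel coordinates (`r1`,`c1`,`r2`,
#'   `c2`), `n_px`, `length_mm`, `orientation_deg`, `hemifield`.
#'   Attributes: `n_discarded`, `discarded_px`, `branch_px`,
#'   `total_skeleton_px`, `pixel_size_mm`.
#' @export
decompose_segments <- function(skel, fovea = NULL, min_segment_px = 5L) {
  stopifnot(inherits(skel, "vessel_mask"))
  px <- skel$pixels
  if (is.null(fovea)) fovea <- c(ceiling(nrow(px) / 2), ceiling(ncol(px) / 2))
  total_px <- sum(px)
  branch <- branch_pixel_matrix(px) == 1L
  open <- px
  open[branch] <- 0L
  lab <- .label_cpp(open, 8L)
  ncomp <- max(lab)
  rows <- list(); n_disc <- 0L; disc_px <- 0L; sid <- 0L
  if (ncomp > 0L) {
    idx_all <- which(lab > 0L)
    comp_of <- lab[idx_all]
    ord <- order(comp_of)
    idx_all <- idx_all[ord]; comp_of <- comp_of[ord]
    starts <- c(1L, which(diff(comp_of) > 0L) + 1L, length(comp_of) + 1L)
    nr <- nrow(px)
    for (k in seq_len(ncomp)) {
      idx <- idx_all[starts[k]:(starts[k + 1L] - 1L)]
      r <- (idx - 1L) %% nr + 1L
      cc <- (idx - 1L) %/% nr + 1L
      n_px <- length(idx)
      # neighbours within this component only
      within <- integer(n_px)
      for (i in seq_len(n_px))
        within[i] <- sum(abs(r - r[i]) <= 1L & abs(cc - cc[i]) <= 1L) - 1L
      ends <- which(within <= 1L & n_px > 1L)
      if (length(ends) < 2L || n_px < min_segment_px) {
        n_disc <- n_disc + 1L
        disc_px <- disc_px + n_px
        next
      }
      if (length(ends) > 2L) {  # defensive: keep the most separated pair
        d <- outer(r[ends], r[ends], "-")^2 + outer(cc[ends], cc[ends], "-")^2
        pick <- which(d == max(d), arr.ind = TRUE)[1L, ]
        ends <- ends[pick]
      }
      e1 <- ends[1L]; e2 <- ends[2L]
      sub <- matrix(FALSE, max(r) - min(r) + 1L, max(cc) - min(cc) + 1L)
      sub[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- TRUE
      len_mm <- component_steps(sub) * skel$pixel_size_mm
      # chord in the normalized frame: x = col (temporal), y = -row (superior)
      ang <- segment_orientation(c(cc[e1], -r[e1]), c(cc[e2], -r[e2]))
      mid_row <- (r[e1] + r[e2]) / 2
      sid <- sid + 1L
      rows[[sid]] <- data.frame(
        segment_id = sid, component = k,
        r1 = r[e1], c1 = cc[e1], r2 = r[e2], c2 = cc[e2],
        n_px = n_px, length_mm = len_mm, orientation_deg = ang,
        hemifield = if (mid_row < fovea[1]) "superior" else "inferior",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (sid > 0L) do.call(rbind, rows) else
    data.frame(segment_id = integer(), component = integer(),
               r1 = integer(), c1 = integer(),
               r2 = integer(), c2 = integer(), n_px = integer(),
               length_mm = numeric(), orientation_deg = numeric(),
               hemifield = character(), stringsAsFactors = FALSE)
  structure(out,
            n_discarded = n_disc, discarded_px = disc_px,
            branch_px = sum(branch), total_skeleton_px = total_px,
            pixel_size_mm = skel$pixel_size_mm, label_matrix = lab,
            class = c("vessel_segments", "data.frame"))
}

#' Classify segments as natural oblique vessels
#'
#' In the superior hemifield the natural direction runs from the macula
#' toward the upper-temporal vortex vein (positive chord angles); in the
#' inferior hemifield toward the lower-temporal vortex vein (negative
#' angles). Exactly horizontal or vertical chords are not natural under
#' the default open band.
#'
#' @param segments a `vessel_segments` data frame.
#' @param cfg a [symmetry_config()].
#' @return `segments` with a logical `natural_oblique` column added.
#' @export
classify_natural_oblique <- function(segments, cfg = symmetry_config()) {
  stopifnot(inherits(segments, "vessel_segments"))
  a <- segments$orientation_deg
  lo <- cfg$band_deg[1]; hi <- cfg$band_deg[2]
  inb <- function(x) if (cfg$include_bounds) x >= lo & x <= hi else x > lo & x < hi
  nat <- ifelse(segments$hemifield == "superior", inb(a), inb(-a))
  segments$natural_oblique <- as.logical(nat)
  segments
}

#' Symmetry index of the vessel running pattern
#'
#' The percentage of total retained segment length classified as natural
#' oblique. A high index means the Haller-layer vessels run
#' mirror-symmetrically about the horizontal fovea line, consistent with
#' a vortex-vein watershed beneath the fovea; a low index means an
#' asymmetric drainage pattern.
#'
#' @param segments a `vessel_segments` data frame carrying a
#'   `natural_oblique` column (see [classify_natural_oblique()]).
#' @return A list of class `symmetry_result`: `symmetry_index_pct`,
#'   `natural_length_mm`, `total_length_mm`, `n_segments`, `n_discarded`.
#' @export
symmetry_index <- function(segments) {
  stopifnot(inherits(segments, "vessel_segments"))
  if (is.null(segments$natural_oblique))
    stop("run classify_natural_oblique() first", call. = FALSE)
  if (nrow(segments) == 0L)
    stop("symmetry index is undefined with no retained segments", call. = FALSE)
  tot <- sum(segments$length_mm)
  nat <- sum(segments$length_mm[segments$natural_oblique])
  structure(list(symmetry_index_pct = 100 * nat / tot,
                 natural_length_mm = nat, total_length_mm = tot,
                 n_segments = nrow(segments),
                 n_discarded = attr(segments, "n_discarded")),
            class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf("<symmetry_result> index %.1f%% (%.2f / %.2f mm over %d segments, %d discarded)\n",
              x$symmetry_index_pct, x$natural_length_mm, x$total_length_mm,
              x$n_segments, x$n_discarded))
  invisible(x)
}

#' Write a per-segment table to CSV
#'
#' @param segments a `vessel_segments` data frame (classified or not).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "vessel_segments"))
  write.csv(as.data.frame(segments), path, row.names = FALSE)
  invisible(path)
}
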