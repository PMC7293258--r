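#' Binarization and de-noising parameters
#'
#' Settings for segmenting the dark vessel phase. Thresholding is
#' local-mean (Niblack-style): a pixel is vessel when its intensity lies
#' below the mean over a `window_px` x `window_px` neighbourhood minus
#' `offset`. A local window is used because en face slabs are unevenly
#' illuminated; a global threshold bleeds across the field.
#'
#' @param window_px odd window side in pixels (>= 3). Default 51, about
#'   0.7 mm at the 7/512 mm pitch -- wide enough to straddle the largest
#'   Haller vessels.
#' @param offset intensity subtracted from the local mean before
#'   comparison. `NULL` (default) resolves at run time to 0.2 x the
#'   image's intensity SD, which adapts to contrast. The factor was
#'   calibrated on synthetic scenes of known caliber: smaller offsets
#'   leave the edge ramp above threshold and systematically dilate
#'   vessels (the local mean is depressed by the vessel itself).
#' @param smooth_px odd side of the binomial (Gaussian-like) prefilter
#'   applied to the image before thresholding (1 = none; 3 = one
#'   (1,2,1)/4 pass per axis; 5 = two passes, ...). Default 3. Pointwise
#'   thresholding of a speckled image marks isolated noise pixels as
#'   vessel at densities where they merge into large clusters; a light
#'   blur suppresses this while keeping the vessel edge ramp narrow
#'   enough not to bias the measured caliber.
#' @param min_component_px foreground specks smaller than this
#'   (8-connected) are removed. Default 100 px.
#' @param min_hole_px background holes smaller than this (4-connected)
#'   are filled. Default 100 px.
#' @return A `binarization_config` list.
#' @export
binarization_config <- function(window_px = 51L, offset = NULL,
                                min_component_px = 100L, min_hole_px = 100L,
                                smooth_px = 3L) {
  window_px <- as.integer(window_px)
  if (is.na(window_px) || window_px < 3L || window_px %% 2L == 0L)
    stop("`window_px` must be an odd integer >= 3", call. = FALSE)
  smooth_px <- as.integer(smooth_px)
  if (is.na(smooth_px) || smooth_px < 1L || smooth_px %% 2L == 0L)
    stop("`smooth_px` must be an odd integer >= 1", call. = FALSE)
  if (smooth_px >= window_px)
    stop("`smooth_px` must be smaller than `window_px`", call. = FALSE)
  if (!is.null(offset) && (!is.numeric(offset) || length(offset) != 1L))
    stop("`offset` must be a single number or NULL", call. = FALSE)
  if (min_component_px < 0 || min_hole_px < 0)
    stop("de-noising size thresholds must be >= 0", call. = FALSE)
  structure(list(window_px = window_px, offset = offset,
                 min_component_px = as.integer(min_component_px),
                 min_hole_px = as.integer(min_hole_px),
                 smooth_px = smooth_px),
            class = "binarization_config")
}

# Separable binomial blur: (size - 1) / 2 passes of (1, 2, 1) / 4 per
# axis, edges replicated.
smooth_binomial <- function(m, size) {
  for (i in seq_len((size - 1L) %/% 2L)) {
    nr <- nrow(m); nc <- ncol(m)
    m <- (m[c(1L, 1:(nr - 1L)), , drop = FALSE] + 2 * m +
            m[c(2:nr, nr), , drop = FALSE]) / 4
    m <- (m[, c(1L, 1:(nc - 1L)), drop = FALSE] + 2 * m +
            m[, c(2:nc, nc), drop = FALSE]) / 4
  }
  m
}

# Local mean over a w x w window clamped to the image, via integral image.
local_mean <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  s <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # s[c, r] after second apply
  s <- t(s)                                      # s[r, c] = sum m[1:r, 1:c]
  s <- rbind(0, cbind(0, s))                     # 1-padded for r0/c0 = 0
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  R2 <- matrix(r2 + 1L, nr, nc); R1 <- matrix(r1, nr, nc)
  C2 <- matrix(c2 + 1L, nr, nc, byrow = TRUE); C1 <- matrix(c1, nr, nc, byrow = TRUE)
  tot <- s[cbind(as.vector(R2), as.vector(C2))] -
    s[cbind(as.vector(R1), as.vector(C2))] -
    s[cbind(as.vector(R2), as.vector(C1))] +
    s[cbind(as.vector(R1), as.vector(C1))]
  area <- (r2 - r1 + 1L) %o% rep(1L, nc) * rep(1L, nr) %o% (c2 - c1 + 1L)
  matrix(tot, nr, nc) / area
}

#' Segment the dark vessel phase of an en face image
#'
#' Vessels of Haller's layer appear dark on en face OCT slabs, so the
#' foreground of the returned mask is the black phase: pixels whose
#' intensity falls below the local mean minus an offset.
#'
#' @param image an [enface_image()].
#' @param cfg a [binarization_config()].
#' @return A [vessel_mask()] with the image's dimensions and pixel pitch.
#'   A constant image with a positive offset yields an empty mask.
#' @export
binarize_enface <- function(image, cfg = binarization_config()) {
  stopifnot(inherits(image, "enface_image"))
  if (!inherits(cfg, "binarization_config")) stop("`cfg` must be a binarization_config", call. = FALSE)
  if (cfg$window_px > nrow(image$pixels) || cfg$window_px > ncol(image$pixels))
    stop(sprintf("image (%d x %d) is smaller than the %d-px threshold window",
                 nrow(image$pixels), ncol(image$pixels), cfg$window_px),
         call. = FALSE)
  offset <- if (is.null(cfg$offset)) 0.2 * sd(image$pixels) else cfg$offset
  sm <- smooth_binomial(image$pixels, cfg$smooth_px)
  mu <- local_mean(image$pixels, cfg$window_px)
  fg <- (sm < mu - offset) * 1L
  vessel_mask(fg, image$pixel_size_mm)
}

#' Remove specks and fill holes in a vessel mask
#'
#' Size-based morphological de-noising: 8-connected foreground components
#' with fewer than `min_component_px` pixels are deleted, then 4-connected
#' background holes (background components not touching the image border)
#' with fewer than `min_hole_px` pixels are filled.
#'
#' @param mask a [vessel_mask()].
#' @param min_component_px,min_hole_px size thresholds in pixels (>= 0);
#'   zero disables the corresponding filter.
#' @return The cleaned [vessel_mask()].
#' @export
denoise_mask <- function(mask, min_component_px = 100L, min_hole_px = 100L) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (min_component_px < 0 || min_hole_px < 0)
    stop("size thresholds must be >= 0", call. = FALSE)
  px <- mask$pixels
  if (min_component_px > 0 && any(px == 1L)) {
    lab <- .label_cpp(px, 8L)
    sizes <- tabulate(lab[lab > 0L])
    px[lab > 0L & sizes[pmax(lab, 1L)] < min_component_px] <- 0L
  }
  if (min_hole_px > 0 && any(px == 0L)) {
    bg <- .label_cpp(1L - px, 4L)
    border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
    border <- border[border > 0L]
    sizes <- tabulate(bg[bg > 0L])
    hole <- bg > 0L & !(bg %in% border) & sizes[pmax(bg, 1L)] < min_hole_px
    px[hole] <- 1L
  }
  vessel_mask(px, mask$pixel_size_mm)
}
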