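# Run `expr` with a private RNG stream seeded by `seed`; the caller's
# RNG state is untouched. `seed = NULL` draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters of a synthetic vessel-network scene
#'
#' The generator emulates the en face appearance of the top slab of
#' Haller's layer: a handful of thick, dark, gently curving vessel trunks
#' per hemifield on a brighter stromal background, with additive Gaussian
#' noise. Orientation statistics are controlled by `symmetry_fraction`:
#' each trunk is drawn in its hemifield's natural oblique band
#' (upper-temporal above the fovea line, lower-temporal below) with that
#' probability, and in the mirrored, unnatural band otherwise.
#'
#' Defaults approximate the study conditions: 512 x 512 px covering
#' 7 x 7 mm, trunk width 11 +/- 2 px (0.15 mm, the caliber scale of
#' Haller vessels), 12 trunks per hemifield, and a symmetry fraction of
#' 0.6 (the level seen in healthy eyes).
#'
#' @param image_size_px square image side in pixels (>= 64).
#' @param pixel_size_mm pixel pitch in mm.
#' @param n_trunks number of vessel trunks per hemifield.
#' @param vessel_width_px mean trunk width in pixels (>= 1).
#' @param vessel_width_sd_px SD of trunk width across trunks.
#' @param symmetry_fraction fraction of trunks per hemifield drawn in
#'   the natural oblique band (enforced exactly, up to rounding, so the
#'   scene's ground-truth symmetry equals the dial).
#' @param tortuosity_deg max angular jitter (degrees) of each step's
#'   heading about the trunk's base orientation; 0 gives straight trunks.
#' @param background_intensity,vessel_intensity mean intensities in
#'   `[0, 255]`; vessels must be darker than background.
#' @param noise_sd SD of the additive Gaussian intensity noise.
#' @param seed integer seed; every scene is reproducible from it.
#' @return A `vessel_scene_params` list.
#' @export
vessel_scene_params <- function(image_size_px = 512L, pixel_size_mm = 7 / 512,
                                n_trunks = 12L, vessel_width_px = 11,
                                vessel_width_sd_px = 2,
                                symmetry_fraction = 0.6, tortuosity_deg = 5,
                                background_intensity = 200,
                                vessel_intensity = 80, noise_sd = 15,
                                seed = 1L) {
  if (image_size_px < 64) stop("`image_size_px` must be >= 64", call. = FALSE)
  if (vessel_width_px < 1) stop("`vessel_width_px` must be >= 1", call. = FALSE)
  if (vessel_width_px > image_size_px)
    stop("vessel width exceeds the image size", call. = FALSE)
  if (symmetry_fraction < 0 || symmetry_fraction > 1)
    stop("`symmetry_fraction` must be in [0, 1]", call. = FALSE)
  if (background_intensity < 0 || background_intensity > 255 ||
      vessel_intensity < 0 || vessel_intensity > 255)
    stop("intensities must be in [0, 255]", call. = FALSE)
  if (vessel_intensity >= background_intensity)
    stop("vessels must be darker than the background", call. = FALSE)
  if (noise_sd < 0 || tortuosity_deg < 0)
    stop("`noise_sd` and `tortuosity_deg` must be >= 0", call. = FALSE)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_mm = pixel_size_mm, n_trunks = as.integer(n_trunks),
                 vessel_width_px = vessel_width_px,
                 vessel_width_sd_px = vessel_width_sd_px,
                 symmetry_fraction = symmetry_fraction,
                 tortuosity_deg = tortuosity_deg,
                 background_intensity = background_intensity,
                 vessel_intensity = vessel_intensity,
                 noise_sd = noise_sd, seed = seed),
            class = "vessel_scene_params")
}

#' Generate a synthetic en face vessel scene with ground truth
#'
#' Draws random-walk vessel trunks hemifield by hemifield and returns the
#' noisy grayscale image, the exact pre-noise binary vessel mask, and a
#' table of the drawn trunks (their base orientation, hemifield, width
#' and natural-oblique status). The truth mask and table are the oracle
#' for testing segmentation and the symmetry statistic.
#'
#' @param params a [vessel_scene_params()].
#' @return A list with elements `image` ([enface_image()]), `truth_mask`
#'   ([vessel_mask()]) and `truth_segments` (data frame: `trunk`,
#'   `hemifield`, `orientation_deg`, `natural_oblique`, `width_px`,
#'   `n_steps`).
#' @export
generate_vessel_image <- function(params = vessel_scene_params()) {
  stopifnot(inherits(params, "vessel_scene_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$image_size_px
    fov_row <- ceiling(n / 2)
    mask <- matrix(0L, n, n)
    n_steps <- round(0.55 * n)
    truth <- vector("list", 2L * p$n_trunks)
    ti <- 0L
    for (hemi in c("superior", "inferior")) {
      # exact quota of natural-oblique trunks, in shuffled order, so the
      # scene's true natural fraction equals symmetry_fraction up to
      # rounding rather than fluctuating binomially
      n_nat <- round(p$symmetry_fraction * p$n_trunks)
      nat_flags <- sample(rep(c(TRUE, FALSE), c(n_nat, p$n_trunks - n_nat)))
      for (k in seq_len(p$n_trunks)) {
        ti <- ti + 1L
        natural <- nat_flags[k]
        # band of the chord angle (frame: +x temporal, +y superior);
        # natural = positive slope superiorly, negative inferiorly
        band <- runif(1, 20, 70)
        ang <- if (hemi == "superior") (if (natural) band else -band)
               else (if (natural) -band else band)
        width <- max(1, round(rnorm(1, p$vessel_width_px, p$vessel_width_sd_px)))
        rad <- width / 2
        # trunks emanate from near the horizontal fovea line (the
        # vortex-vein watershed) and run away from it toward the
        # periphery, so the drawn pattern converges at the watershed
        r0 <- if (hemi == "superior") fov_row - 1 - rad - runif(1, 0, 0.08 * n)
              else fov_row + 1 + rad + runif(1, 0, 0.08 * n)
        # walk direction along the chord that moves away from the line
        sgn <- if (hemi == "superior") sign(ang) else -sign(ang)
        # stratify start columns (evenly spaced bins, jittered) so trunks
        # spread across the field instead of clustering and merging;
        # shift the fan against the walk direction so trunks have room
        bin <- 0.7 * n / p$n_trunks
        c_base <- (k - 1 + runif(1)) * bin
        c0 <- if (sgn > 0) 1 + c_base else n - c_base
        jit <- if (p$tortuosity_deg > 0)
          runif(n_steps, -p$tortuosity_deg, p$tortuosity_deg) else numeric(n_steps)
        theta <- (ang + jit) * pi / 180
        dc <- sgn * cos(theta)
        dr <- -sgn * sin(theta)      # +y superior = decreasing row
        rr <- r0 + cumsum(dr); ccol <- c0 + cumsum(dc)
        # truncate at the image edge and at the watershed line
        ok <- ccol >= 1 & ccol <= n &
          if (hemi == "superior") rr >= 1 & rr <= fov_row - 1 - rad
          else rr >= fov_row + 1 + rad & rr <= n
        stop_at <- which(!ok)[1L]
        if (!is.na(stop_at)) { rr <- rr[seq_len(stop_at - 1L)]; ccol <- ccol[seq_len(stop_at - 1L)] }
        if (length(rr) >= 2L) {
          mask <- stamp_path(mask, rr, ccol, width)
        }
        truth[[ti]] <- data.frame(
          trunk = ti, hemifield = hemi, orientation_deg = ang,
          natural_oblique = natural, width_px = width,
          n_steps = length(rr), stringsAsFactors = FALSE)
      }
    }
    img <- matrix(p$background_intensity, n, n)
    img[mask == 1L] <- p$vessel_intensity
    if (p$noise_sd > 0) img <- img + matrix(rnorm(n * n, 0, p$noise_sd), n, n)
    img <- round(pmin(pmax(img, 0), 255))  # 8-bit bitmap, PNG-exact
    list(image = enface_image(img, p$pixel_size_mm, eye_side = "OD"),
         truth_mask = vessel_mask(mask, p$pixel_size_mm),
         truth_segments = do.call(rbind, truth))
  })
}

# Paint a disk of diameter `width` around every (continuous) path point.
stamp_path <- function(mask, rr, cc, width) {
  n <- nrow(mask)
  rad <- width / 2
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                     dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2, , drop = FALSE]
  ri <- round(rr); ci <- round(cc)
  pts <- !duplicated(cbind(ri, ci))
  ri <- ri[pts]; ci <- ci[pts]
  R <- rep(ri, each = nrow(off)) + off$dr
  C <- rep(ci, each = nrow(off)) + off$dc
  ok <- R >= 1 & R <= n & C >= 1 & C <= n
  mask[cbind(R[ok], C[ok])] <- 1L
  mask
}

#' Parameters of a synthetic per-eye metric cohort
#'
#' Group-wise means and SDs default to the published cohort structure of
#' the study population this package models: healthy controls, unaffected
#' fellow eyes, and eyes with central serous chorioretinopathy (CSC),
#' 41 eyes each. Metrics are vessel area (mm^2), vessel length (mm), mean
#' vessel diameter (mm), symmetry index (%) and central choroidal
#' thickness (um). Rank-correlation targets couple diameter, length and
#' symmetry index to CCT.
#'
#' @param n_per_group eyes per group (>= 3).
#' @param groups named list; each element is a list with two-element
#'   `c(mean, sd)` entries `area`, `length`, `diameter`, `symmetry`,
#'   `cct`, plus Spearman targets `r_diameter_cct`, `r_length_cct`,
#'   `r_symmetry_cct`. See the default for the expected shape.
#' @param seed integer seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_per_group = 41L, groups = NULL, seed = 1L) {
  if (n_per_group < 3) stop("`n_per_group` must be >= 3", call. = FALSE)
  if (is.null(groups)) {
    groups <- list(
      control = list(area = c(23.4, 3.3), length = c(164.7, 24.5),
                     diameter = c(0.144, 0.020), symmetry = c(59.4, 5.8),
                     cct = c(259, 87),
                     r_diameter_cct = 0.746, r_length_cct = -0.364,
                     r_symmetry_cct = 0),
      fellow = list(area = c(26.4, 4.8), length = c(156.6, 20.5),
                    diameter = c(0.171, 0.038), symmetry = c(55.3, 7.2),
                    cct = c(343, 100),
                    r_diameter_cct = 0.775, r_length_cct = 0,
                    r_symmetry_cct = -0.405),
      csc = list(area = c(27.4, 4.7), length = c(150.0, 17.1),
                 diameter = c(0.185, 0.039), symmetry = c(53.7, 6.0),
                 cct = c(391, 101),
                 r_diameter_cct = 0.745, r_length_cct = 0,
                 r_symmetry_cct = -0.660))
  }
  for (g in names(groups)) {
    gp <- groups[[g]]
    for (m in c("area", "length", "diameter", "symmetry", "cct")) {
      if (is.null(gp[[m]]) || length(gp[[m]]) != 2L || gp[[m]][2] <= 0)
        stop(sprintf("group '%s': `%s` must be c(mean, sd) with sd > 0", g, m),
             call. = FALSE)
    }
    for (r in c("r_diameter_cct", "r_length_cct", "r_symmetry_cct")) {
      if (is.null(gp[[r]])) groups[[g]][[r]] <- 0
      else if (abs(gp[[r]]) > 1)
        stop(sprintf("group '%s': correlation target `%s` = %.3f is infeasible (|rho| > 1)",
                     g, r, gp[[r]]), call. = FALSE)
    }
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 seed = seed),
            class = "cohort_params")
}

# Truncated-normal quantile function via inverse-CDF mapping.
qtruncnorm <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm((lo - mean) / sd); phi <- pnorm((hi - mean) / sd)
  qnorm(plo + u * (phi - plo)) * sd + mean
}

#' Simulate a per-eye metric cohort
#'
#' Samples mean vessel diameter, vessel length, symmetry index and CCT
#' from truncated-normal marginals coupled by a one-factor Gaussian
#' copula in which CCT is the factor: each metric's copula loading is its
#' Spearman target against CCT (converted to the Pearson scale), so the
#' requested rank correlations are achieved and metrics are conditionally
#' independent given CCT — a structure that is positive semi-definite for
#' any feasible set of targets. Vessel area is then derived as diameter
#' times length, which keeps the per-eye records exactly self-consistent
#' (diameter = area / length).
#'
#' @param params a [cohort_params()].
#' @return A data frame with one row per eye: `id`, `group`,
#'   `vessel_area_mm2`, `vessel_length_mm`, `mean_diameter_mm`,
#'   `symmetry_index_pct`, `cct_um`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    out <- lapply(names(params$groups), function(g) {
      gp <- params$groups[[g]]
      n <- params$n_per_group
      # Spearman -> Pearson copula parameter for bivariate normal ranks
      lam <- vapply(c("r_diameter_cct", "r_length_cct", "r_symmetry_cct"),
                    function(r) 2 * sin(pi * gp[[r]] / 6), numeric(1))
      z_cct <- rnorm(n)
      z <- vapply(lam, function(l) l * z_cct + sqrt(1 - l^2) * rnorm(n),
                  numeric(n))
      if (n == 1L) z <- matrix(z, nrow = 1L)
      u <- pnorm(cbind(z, z_cct))
      diam <- qtruncnorm(u[, 1], gp$diameter[1], gp$diameter[2], lo = 0)
      len <- qtruncnorm(u[, 2], gp$length[1], gp$length[2], lo = 0)
      sym <- qtruncnorm(u[, 3], gp$symmetry[1], gp$symmetry[2], lo = 0, hi = 100)
      cct <- qtruncnorm(u[, 4], gp$cct[1], gp$cct[2], lo = 0)
      data.frame(id = sprintf("%s_%03d", g, seq_len(n)), group = g,
                 vessel_area_mm2 = diam * len, vessel_length_mm = len,
                 mean_diameter_mm = diam, symmetry_index_pct = sym,
                 cct_um = cct, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
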