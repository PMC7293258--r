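# Fixture builders and independent oracles shared across the suite.

psz <- 7 / 512

# Rectangular bar mask inside an nr x nc field.
bar_mask <- function(nr, nc, rows, cols, pixel_size_mm = psz) {
  m <- matrix(0L, nr, nc)
  m[rows, cols] <- 1L
  vessel_mask(m, pixel_size_mm)
}

# Skeleton object from an explicit 0/1 matrix (bypasses thinning).
as_skel <- function(m, pixel_size_mm = psz) {
  obj <- vessel_mask(m, pixel_size_mm)
  class(obj) <- c("vessel_skeleton", class(obj))
  obj
}

# Dice overlap of two binary matrices.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Brute-force step-sum length (px) of a pixel set: double loop over all
# unique pairs, counting 8-adjacencies.
brute_steps <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  total <- 0
  n <- nrow(idx)
  if (n < 2L) return(0)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    dr <- abs(idx[i, 1] - idx[j, 1]); dc <- abs(idx[i, 2] - idx[j, 2])
    if (dr <= 1L && dc <= 1L)
      total <- total + if (dr + dc == 2L) sqrt(2) else 1
  }
  total
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank
# assignments (no ties assumed).
enum_mw_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  ws <- apply(combos, 2L, function(ix) sum(ix) - m * (m + 1) / 2)
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Naive per-threshold scan for the Youden cutoff, written as explicit
# loops so it shares no code with roc_youden().
brute_youden <- function(values, labels) {
  cuts <- sort(unique(values))
  js <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    t <- cuts[k]
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in seq_along(values)) {
      pos <- values[i] > t
      if (labels[i] == 1) { if (pos) tp <- tp + 1 else fn <- fn + 1 }
      else               { if (pos) fp <- fp + 1 else tn <- tn + 1 }
    }
    js[k] <- tp / (tp + fn) + tn / (tn + fp) - 1
  }
  jm <- max(js)
  list(J = jm, cutoff = max(cuts[js > jm - 1e-12]))  # ties -> larger cutoff
}

# A small grayscale image object from a matrix of intensities.
as_image <- function(px, ...) enface_image(px, ...)
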