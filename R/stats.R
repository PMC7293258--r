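#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples with midrank tie
#' handling. The p-value is computed by exact enumeration when the
#' combined sample size is at most 16 and there are no ties, and by the
#' continuity-corrected normal approximation with tie correction
#' otherwise.
#'
#' @param a,b numeric samples (both nonempty).
#' @return A list: `U` (the Mann-Whitney statistic for `a`), `p.value`
#'   (two-sided), `exact` (logical).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 16L) && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p.value = ht$p.value, exact = exact)
}

#' Chi-square test on a 2 x 2 table with Yates continuity correction
#'
#' @param table 2 x 2 matrix of nonnegative integer counts with all row
#'   and column margins positive.
#' @return A list: `statistic` (corrected X-squared, df = 1), `p.value`
#'   (two-sided).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("`table` must be 2 x 2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all table margins must be positive", call. = FALSE)
  ht <- suppressWarnings(chisq.test(table, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' @param x,y paired numeric vectors, n >= 3, neither constant. Ties are
#'   handled by midranks.
#' @return A list: `rho`, `p.value` (two-sided, asymptotic t).
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation is undefined for a constant vector", call. = FALSE)
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p.value = ht$p.value)
}

#' ROC curve and Youden-index cutoff
#'
#' Builds the ROC curve for a continuous marker against a binary disease
#' label under the rule "positive iff value > cutoff", evaluating every
#' observed value as a candidate cutoff. The reported cutoff maximizes
#' the Youden index J = sensitivity + specificity - 1 (the ROC point
#' farthest from the chance diagonal); ties are broken toward the larger
#' cutoff, i.e. toward higher specificity. AUC is computed by the
#' trapezoidal rule.
#'
#' @param values numeric marker values.
#' @param labels disease labels (logical, or coercible 0/1; 1 = disease).
#' @return A list of class `roc_result`: `curve` (data frame: `cutoff`,
#'   `sensitivity`, `specificity`), `auc`, `youden_cutoff`, `youden_J`,
#'   `sensitivity_at_cutoff`, `specificity_at_cutoff`.
#' @export
roc_youden <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(values) != length(labels)) stop("lengths differ", call. = FALSE)
  if (anyNA(values) || anyNA(labels)) stop("missing values", call. = FALSE)
  pos <- values[labels == 1L]; neg <- values[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present", call. = FALSE)
  cuts <- sort(unique(values))
  sens <- vapply(cuts, function(t) mean(pos > t), numeric(1))
  spec <- vapply(cuts, function(t) mean(neg <= t), numeric(1))
  j <- sens + spec - 1
  best <- max(which(j > max(j) - 1e-12))  # ties -> larger cutoff, higher specificity
  # full curve including the all-positive anchor for the trapezoid AUC
  curve <- data.frame(cutoff = c(-Inf, cuts),
                      sensitivity = c(1, sens), specificity = c(0, spec))
  fpr <- 1 - curve$specificity; tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
  structure(list(curve = curve, auc = auc,
                 youden_cutoff = cuts[best], youden_J = j[best],
                 sensitivity_at_cutoff = sens[best],
                 specificity_at_cutoff = spec[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f; Youden cutoff %.4g (J = %.3f, sens %.1f%%, spec %.1f%%)\n",
              x$auc, x$youden_cutoff, x$youden_J,
              100 * x$sensitivity_at_cutoff, 100 * x$specificity_at_cutoff))
  invisible(x)
}

#' Sensitivity, specificity and cell percentages of a confusion table
#'
#' @param tp,fp,tn,fn nonnegative integer counts; the positive class
#'   (disease) must have `tp + fn > 0` and the negative class
#'   `tn + fp > 0`.
#' @return A list: `sensitivity_pct`, `specificity_pct` (percent, rounded
#'   to one decimal), and `cell_pct`, the within-class percentage of each
#'   cell (rows: test negative/positive; columns: disease absent/present).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (tp + fn == 0) stop("no diseased subjects (tp + fn = 0)", call. = FALSE)
  if (tn + fp == 0) stop("no healthy subjects (tn + fp = 0)", call. = FALSE)
  cell <- matrix(c(tn / (tn + fp), fn / (tp + fn),
                   fp / (tn + fp), tp / (tp + fn)) * 100,
                 2L, 2L, byrow = TRUE,
                 dimnames = list(c("negative", "positive"),
                                 c("healthy", "disease")))
  list(sensitivity_pct = round(100 * tp / (tp + fn), 1L),
       specificity_pct = round(100 * tn / (tn + fp), 1L),
       cell_pct = round(cell, 1L))
}

#' Pairwise group comparisons of cohort metrics
#'
#' Per metric and group pair: group means and SDs plus the two-sided
#' Mann-Whitney p-value. Output layout mirrors a per-parameter comparison
#' table with one row per metric-pair combination. No multiple-testing
#' correction is applied.
#'
#' @param cohort data frame of per-eye metrics (e.g. from
#'   [generate_cohort()] or [run_analyze()]).
#' @param metrics character vector of metric column names; defaults to
#'   the four vessel metrics.
#' @param pairs list of 2-element character vectors of group labels;
#'   defaults to all pairs present.
#' @param group_col name of the group column.
#' @return A data frame: `metric`, `group_a`, `group_b`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `U`, `p.value`.
#' @export
compare_groups <- function(cohort,
                           metrics = c("vessel_area_mm2", "vessel_length_mm",
                                       "mean_diameter_mm", "symmetry_index_pct"),
                           pairs = NULL, group_col = "group") {
  if (!group_col %in% names(cohort))
    stop("missing group column: ", group_col, call. = FALSE)
  missing_cols <- setdiff(metrics, names(cohort))
  if (length(missing_cols) > 0L)
    stop("missing metric column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  groups <- sort(unique(cohort[[group_col]]))  # row order must not matter
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(pairs)) {
    cmb <- utils::combn(groups, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  rows <- list()
  for (m in metrics) for (pr in pairs) {
    xa <- cohort[[m]][cohort[[group_col]] == pr[1]]
    xb <- cohort[[m]][cohort[[group_col]] == pr[2]]
    mw <- mann_whitney_u(xa, xb)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, group_a = pr[1], group_b = pr[2],
      mean_a = mean(xa), sd_a = sd(xa), mean_b = mean(xb), sd_b = sd(xb),
      U = mw$U, p.value = mw$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
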