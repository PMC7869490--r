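#' Regression and threshold-classification metrics
#'
#' Computes the full evaluation suite for continuous solubility
#' predictions: RMSE, the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot`, and, after thresholding both vectors at
#' `threshold` (a value equal to the threshold counts as soluble), the
#' confusion counts with accuracy, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`, and the area under
#' the ROC curve computed rank-based (midpoint ranks for ties, equivalent
#' to trapezoidal integration of the ROC) from the continuous predictions
#' against the thresholded actuals.
#'
#' Degenerate cases: zero variance in `actual` leaves `r2` as `NA` with a
#' warning; a zero denominator in precision, recall or F1 reports 0 with a
#' warning; AUC is `NA` when only one class is present.
#'
#' @param predicted,actual numeric vectors of equal length (>= 2) in
#'   \[0, 1\].
#' @param threshold solubility cutoff defining the soluble class.
#' @return a one-row tibble: `rmse`, `r2`, `threshold`, `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.6, 0.2, 0.4), c(1, 0.7, 0.55, 0.1, 0.45))
#' @export
compute_metrics <- function(predicted, actual, threshold = 0.5) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 2L)
  rmse <- sqrt(mean((predicted - actual)^2))
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) {
    warning("actual values have zero variance; R2 is undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((actual - predicted)^2) / ss_tot
  }
  pc <- predicted >= threshold
  ac <- actual >= threshold
  tp <- sum(pc & ac); fp <- sum(pc & !ac)
  tn <- sum(!pc & !ac); fn <- sum(!pc & ac)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", what))
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 undefined (zero denominator); reported as 0")
    0
  } else 2 * precision * recall / (precision + recall)
  auc <- auc_score(predicted, ac)
  tibble::tibble(rmse = rmse, r2 = r2, threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(actual),
                 precision = precision, recall = recall, f1 = f1,
                 auc = auc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midpoint ranks for tied scores;
#' identical to trapezoidal integration of the empirical ROC curve.
#'
#' @param scores continuous predictions.
#' @param labels logical (or 0/1) class labels.
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve coordinates
#'
#' @param predicted continuous predictions.
#' @param actual continuous actual solubilities.
#' @param label_threshold cutoff turning `actual` into class labels.
#' @return tibble with `cutoff`, `fpr`, `tpr`, sorted for plotting.
#' @export
roc_curve <- function(predicted, actual, label_threshold = 0.5) {
  labels <- actual >= label_threshold
  cuts <- c(Inf, sort(unique(predicted), decreasing = TRUE), -Inf)
  np <- sum(labels); nn <- sum(!labels)
  purrr::map_dfr(cuts, function(ct) {
    pc <- predicted >= ct
    tibble::tibble(cutoff = ct,
                   fpr = if (nn) sum(pc & !labels) / nn else 0,
                   tpr = if (np) sum(pc & labels) / np else 0)
  })
}

#' Precision-recall curve coordinates
#'
#' @inheritParams roc_curve
#' @return tibble with `cutoff`, `recall`, `precision`.
#' @export
pr_curve <- function(predicted, actual, label_threshold = 0.5) {
  labels <- actual >= label_threshold
  cuts <- sort(unique(predicted), decreasing = TRUE)
  np <- sum(labels)
  purrr::map_dfr(cuts, function(ct) {
    pc <- predicted >= ct
    tp <- sum(pc & labels)
    tibble::tibble(cutoff = ct,
                   recall = if (np) tp / np else 0,
                   precision = if (sum(pc)) tp / sum(pc) else 0)
  })
}

#' Metrics as a function of the classification threshold
#'
#' Evaluates [compute_metrics()] at each threshold of a grid and also
#' returns ROC and precision-recall curve coordinates (labels fixed by the
#' 0.5 actual-solubility cutoff).
#'
#' @param predicted,actual numeric vectors in \[0, 1\].
#' @param grid thresholds to evaluate, all within \[0, 1\].
#' @return a `threshold_sweep` object: list with `metrics` (one row per
#'   grid point), `roc` and `pr` tibbles.
#' @export
threshold_sweep <- function(predicted, actual, grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(grid >= 0 & grid <= 1))
  metrics <- purrr::map_dfr(grid, function(th) {
    suppressWarnings(compute_metrics(predicted, actual, threshold = th))
  })
  out <- list(metrics = metrics,
              roc = roc_curve(predicted, actual),
              pr = pr_curve(predicted, actual))
  class(out) <- "threshold_sweep"
  out
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep: %d thresholds>\n", nrow(x$metrics)))
  print(x$metrics)
  invisible(x)
}
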