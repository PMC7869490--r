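#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model's optimization history
#'
#' @param x a `solgcn_fit`.
#' @param ... unused.
#' @return tibble with one row per epoch: `epoch`, `rmse` (training),
#'   `val_r2`.
#' @method tidy solgcn_fit
#' @export
tidy.solgcn_fit <- function(x, ...) x$history

#' One-row summary of a trained model
#'
#' @param x a `solgcn_fit`.
#' @param ... unused.
#' @return tibble with the architecture, epochs run and final losses.
#' @method glance solgcn_fit
#' @export
glance.solgcn_fit <- function(x, ...) {
  n_par <- length(flatten_params(x$params))
  tibble::tibble(
    n_train = x$n_train,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    final_rmse = if (nrow(x$history)) x$history$rmse[nrow(x$history)] else NA_real_,
    best_val_r2 = if (all(is.na(x$history$val_r2))) NA_real_
                  else max(x$history$val_r2, na.rm = TRUE),
    n_parameters = n_par,
    gcn_dims = paste(x$config$gcn_dims, collapse = "-"),
    attention_heads = x$config$attention_heads
  )
}

#' Tidy cross-validation metrics
#'
#' @param x a `solgcn_cv`.
#' @param ... unused.
#' @return the per-(seed, fold) metrics tibble.
#' @method tidy solgcn_cv
#' @export
tidy.solgcn_cv <- function(x, ...) x$metrics

#' Aggregate cross-validation summary
#'
#' @param x a `solgcn_cv`.
#' @param ... unused.
#' @return the two-row aggregation tibble (pooled and per-seed means).
#' @method glance solgcn_cv
#' @export
glance.solgcn_cv <- function(x, ...) x$summary

#' Plot a training trajectory
#'
#' @param object a `solgcn_fit`.
#' @param ... unused.
#' @return a ggplot of training RMSE (and validation R-squared when
#'   available) against the epoch.
#' @method autoplot solgcn_fit
#' @export
autoplot.solgcn_fit <- function(object, ...) {
  hist <- object$history |>
    tidyr::pivot_longer(c("rmse", "val_r2"), names_to = "metric") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(hist, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training trajectory")
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `solgcn_cv`.
#' @param metric column of the metrics tibble to display.
#' @param ... unused.
#' @return a ggplot with one point per (seed, fold).
#' @method autoplot solgcn_cv
#' @export
autoplot.solgcn_cv <- function(object, metric = "r2", ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(factor(.data$seed), .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::labs(x = "CV seed", colour = "fold",
                  title = "Cross-validation metrics by seed and fold")
}

#' Plot a threshold sweep
#'
#' @param object a `threshold_sweep`.
#' @param what `"accuracy"` (accuracy vs threshold), `"roc"` or `"pr"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, what = c("accuracy", "roc", "pr"),
                                     ...) {
  what <- match.arg(what)
  switch(what,
    accuracy = ggplot2::ggplot(object$metrics,
                               ggplot2::aes(.data$threshold, .data$accuracy)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = "Accuracy as a function of the threshold"),
    roc = ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::labs(title = "ROC curve"),
    pr = ggplot2::ggplot(object$pr, ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::labs(title = "Precision-recall curve")
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
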