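#' Training configuration
#'
#' @param epochs number of passes over the training set (0 leaves the
#'   parameters at initialization).
#' @param learning_rate Adam step size.
#' @param seed RNG seed controlling initialization and shuffling; fixed seed
#'   gives a bit-identical trajectory on one platform.
#' @param patience early-stopping patience in epochs, judged on validation
#'   R-squared; ignored when no validation set is supplied.
#' @param validation_fraction fraction of the training records held out
#'   internally for early stopping (0 disables).
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-3, seed = 1L,
                         patience = 10L, validation_fraction = 0) {
  stopifnot(epochs >= 0, learning_rate > 0, patience >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config: %d epochs, lr %g, seed %d>\n",
              x$epochs, x$learning_rate, x$seed))
  invisible(x)
}

#' Assemble a solubility dataset
#'
#' @param graphs list of `protein_graph` objects.
#' @param targets numeric vector of solubility values in \[0, 1\].
#' @param ids unique identifiers (defaults to the graph ids).
#' @return a tibble with columns `id`, `graph` (list-column), `target`.
#' @export
solubility_dataset <- function(graphs, targets, ids = NULL) {
  stopifnot(length(graphs) == length(targets))
  if (any(targets < 0 | targets > 1)) {
    stop("targets must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- vapply(graphs, function(g) g$id %||% NA_character_, character(1))
    if (anyNA(ids)) ids <- sprintf("protein_%04d", seq_along(graphs))
  }
  if (anyDuplicated(ids)) stop("identifiers must be unique", call. = FALSE)
  tibble::tibble(id = as.character(ids), graph = graphs,
                 target = as.numeric(targets))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dataset_tensors <- function(dataset) {
  lapply(dataset$graph, function(g) {
    list(X = graph_features(g), Ahat = normalize_adjacency(g$A))
  })
}

#' Train the solubility model
#'
#' Minimizes the mean squared error (the same argmin as the RMSE the model
#' is evaluated with) by Adam, one stochastic update per protein per epoch.
#' With a validation set (explicit or carved out via
#' `validation_fraction`), training keeps the parameters of the best
#' validation R-squared and stops early after `patience` epochs without
#' improvement.
#'
#' @param dataset a tibble from [solubility_dataset()].
#' @param config a [model_config()]; defaults to the canonical architecture
#'   with `input_dim` taken from the data.
#' @param tconfig a [train_config()].
#' @param validation optional validation dataset (same form as `dataset`).
#' @param verbose print per-epoch loss.
#' @return a `solgcn_fit`: list with `params` (a `model_params`), `config`,
#'   `tconfig`, `history` (tibble of per-epoch training loss and validation
#'   R-squared) and `best_epoch`.
#' @export
train_model <- function(dataset, config = NULL, tconfig = train_config(),
                        validation = NULL, verbose = FALSE) {
  stopifnot(nrow(dataset) >= 1L, inherits(tconfig, "train_config"))
  if (is.null(config)) {
    config <- model_config(input_dim = ncol(graph_features(dataset$graph[[1]])))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tconfig$seed)
  if (is.null(validation) && tconfig$validation_fraction > 0) {
    sp <- split_dataset(dataset, 1 - tconfig$validation_fraction,
                        seed = tconfig$seed)
    dataset <- sp$train
    validation <- sp$test
  }
  tensors <- dataset_tensors(dataset)
  y <- dataset$target
  n <- length(y)
  val_tensors <- if (!is.null(validation) && nrow(validation) > 0)
    dataset_tensors(validation) else NULL

  params <- init_model_params(config, seed = tconfig$seed)
  theta <- flatten_params(params)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- vector("list", tconfig$epochs)
  best <- list(theta = theta, r2 = -Inf, epoch = 0L)
  wait <- 0L

  for (epoch in seq_len(tconfig$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    for (i in ord) {
      cur <- unflatten_params(theta, params)
      gout <- .cpp_loss_grad(tensors[[i]]$X, tensors[[i]]$Ahat,
                             params_core(cur), y[i],
                             layer_norm = config$layer_norm)
      if (!is.finite(gout$loss)) {
        stop(sprintf("non-finite loss at epoch %d, record '%s'; try a smaller learning rate",
                     epoch, dataset$id[i]), call. = FALSE)
      }
      losses[i] <- gout$loss
      g <- unlist(gout$grads, use.names = FALSE)
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - tconfig$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    epoch_rmse <- sqrt(mean(losses))
    val_r2 <- NA_real_
    if (!is.null(val_tensors)) {
      cur <- unflatten_params(theta, params)
      pv <- vapply(val_tensors, function(tns)
        .cpp_forward(tns$X, tns$Ahat, params_core(cur),
                     layer_norm = config$layer_norm)$S, numeric(1))
      av <- validation$target
      val_r2 <- 1 - sum((av - pv)^2) / sum((av - mean(av))^2)
      if (val_r2 > best$r2) {
        best <- list(theta = theta, r2 = val_r2, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, rmse = epoch_rmse,
                                       val_r2 = val_r2)
    if (verbose) {
      message(sprintf("epoch %3d  train RMSE %.4f  val R2 %s", epoch,
                      epoch_rmse,
                      if (is.na(val_r2)) "-" else sprintf("%.4f", val_r2)))
    }
    if (!is.null(val_tensors) && wait >= tconfig$patience) break
  }
  if (!is.null(val_tensors) && is.finite(best$r2)) {
    theta <- best$theta
  } else {
    best$epoch <- tconfig$epochs
  }
  fit <- list(params = unflatten_params(theta, params), config = config,
              tconfig = tconfig,
              history = dplyr::bind_rows(history),
              best_epoch = best$epoch,
              n_train = n)
  class(fit) <- "solgcn_fit"
  fit
}

#' @export
print.solgcn_fit <- function(x, ...) {
  last <- if (nrow(x$history)) x$history$rmse[nrow(x$history)] else NA_real_
  cat(sprintf("<solgcn_fit: %d proteins, %d epochs run, final train RMSE %.4f>\n",
              x$n_train, nrow(x$history), last))
  invisible(x)
}

#' Predict solubility for a dataset or a single graph
#'
#' @param object a `solgcn_fit`.
#' @param newdata a dataset tibble (with a `graph` column) or a single
#'   `protein_graph`.
#' @param ... unused.
#' @return a tibble with `id`, `predicted` (and `actual` when targets are
#'   present), or a scalar for a single graph.
#' @export
predict.solgcn_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "protein_graph")) {
    return(predict_solubility(newdata, object$params))
  }
  preds <- vapply(newdata$graph, predict_solubility, numeric(1),
                  params = object$params)
  out <- tibble::tibble(id = newdata$id, predicted = preds)
  if (!is.null(newdata$target)) out$actual <- newdata$target
  out
}

#' Split a dataset into train and test partitions
#'
#' Records are shuffled with a seeded uniform permutation; the first
#' `floor(fraction * n)` form the training set and the remainder the test
#' set.
#'
#' @param dataset a dataset tibble, or a single integer `n` (in which case
#'   index vectors are returned).
#' @param fraction training fraction in (0, 1\].
#' @param seed RNG seed for the shuffle.
#' @return list with elements `train` and `test`.
#' @examples
#' split_dataset(2737, fraction = 0.75, seed = 1)$train |> length()
#' @export
split_dataset <- function(dataset, fraction = 0.75, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- if (is.numeric(dataset) && length(dataset) == 1L) as.integer(dataset)
       else nrow(dataset)
  if (n == 0L) stop("cannot split an empty dataset", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  ntr <- floor(fraction * n)
  tr <- sort(perm[seq_len(ntr)])
  te <- sort(perm[setdiff(seq_len(n), seq_len(ntr))])
  if (is.numeric(dataset) && length(dataset) == 1L) {
    list(train = tr, test = te)
  } else {
    list(train = dataset[tr, , drop = FALSE],
         test = dataset[te, , drop = FALSE])
  }
}

# balanced contiguous fold sizes after a seeded shuffle; remainder spread
# over the first n %% k folds
fold_assignment <- function(n, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

#' k-fold cross-validation repeated over random seeds
#'
#' For each seed the records are shuffled and partitioned into `k` folds of
#' sizes differing by at most one; each fold serves once as validation while
#' a model is trained on the remaining folds.  Metrics are reported per
#' (seed, fold) and aggregated two ways: pooled over all `k * length(seeds)`
#' runs, and per-seed means averaged across seeds.
#'
#' @param dataset a dataset tibble.
#' @param k number of folds.
#' @param seeds integer vector of shuffle seeds (one CV repetition each).
#' @param config a [model_config()] (defaults from the data).
#' @param tconfig a [train_config()]; its `seed` is re-derived per
#'   (seed, fold) so every run is reproducible.
#' @param threshold classification threshold for the fold metrics.
#' @param verbose print progress.
#' @return a `solgcn_cv`: list with `metrics` (per seed x fold tibble),
#'   `summary`, `models` (the k * length(seeds) fits) and `predictions`
#'   (out-of-fold predictions per seed).
#' @export
cross_validate <- function(dataset, k = 5L, seeds = 1:5, config = NULL,
                           tconfig = train_config(), threshold = 0.5,
                           verbose = FALSE) {
  n <- nrow(dataset)
  if (n < k) stop(sprintf("need at least k = %d records, got %d", k, n),
                  call. = FALSE)
  if (is.null(config)) {
    config <- model_config(input_dim = ncol(graph_features(dataset$graph[[1]])))
  }
  metrics <- list()
  models <- list()
  preds <- list()
  for (s in seeds) {
    fold <- fold_assignment(n, k, seed = s)
    for (fd in seq_len(k)) {
      tc <- tconfig
      tc$seed <- as.integer((s * 1000L + fd) %% .Machine$integer.max)
      fit <- train_model(dataset[fold != fd, , drop = FALSE], config, tc)
      pv <- predict(fit, dataset[fold == fd, , drop = FALSE])
      mrow <- compute_metrics(pv$predicted, pv$actual, threshold = threshold)
      metrics[[length(metrics) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(seed = s, fold = fd,
                                        n_val = sum(fold == fd)), mrow)
      models[[length(models) + 1L]] <- fit
      preds[[length(preds) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(seed = s, fold = fd), pv)
      if (verbose) message(sprintf("seed %d fold %d done", s, fd))
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  pooled <- metrics |>
    dplyr::summarise(dplyr::across(c("rmse", "r2", "accuracy", "precision",
                                     "recall", "f1", "auc"),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~sd(.x, na.rm = TRUE)))) |>
    dplyr::mutate(aggregation = "pooled", .before = 1)
  by_seed <- metrics |>
    dplyr::group_by(.data$seed) |>
    dplyr::summarise(dplyr::across(c("rmse", "r2", "accuracy", "precision",
                                     "recall", "f1", "auc"),
                                   ~mean(.x, na.rm = TRUE)), .groups = "drop") |>
    dplyr::summarise(dplyr::across(-"seed",
                                   list(mean = mean, sd = sd))) |>
    dplyr::mutate(aggregation = "seed_means", .before = 1)
  out <- list(metrics = metrics,
              summary = dplyr::bind_rows(pooled, by_seed),
              models = models,
              predictions = dplyr::bind_rows(preds),
              k = k, seeds = seeds)
  class(out) <- "solgcn_cv"
  out
}

#' @export
print.solgcn_cv <- function(x, ...) {
  cat(sprintf("<solgcn_cv: %d folds x %d seeds>\n", x$k, length(x$seeds)))
  cat(sprintf("  R2 %.3f +/- %.3f, RMSE %.3f (pooled over %d runs)\n",
              x$summary$r2_mean[1], x$summary$r2_sd[1],
              x$summary$rmse_mean[1], nrow(x$metrics)))
  invisible(x)
}

#' Ensemble prediction by model averaging
#'
#' Averages the predictions of several trained models (e.g. the k
#' cross-validation fold models) for one graph or a dataset.  All members
#' must share a model configuration.
#'
#' @param models list of `solgcn_fit` or `model_params` objects.
#' @param newdata a `protein_graph` or dataset tibble.
#' @return scalar or tibble as in [predict.solgcn_fit()].
#' @export
ensemble_predict <- function(models, newdata) {
  stopifnot(length(models) >= 1L)
  params <- lapply(models, function(m) {
    if (inherits(m, "solgcn_fit")) m$params else m
  })
  cfgs <- lapply(params, function(p) unclass(p$config))
  if (!all(vapply(cfgs[-1], identical, logical(1), y = cfgs[[1]]))) {
    stop("ensemble members have mismatched model configurations", call. = FALSE)
  }
  if (inherits(newdata, "protein_graph")) {
    return(mean(vapply(params, function(p)
      predict_solubility(newdata, p), numeric(1))))
  }
  mat <- vapply(params, function(p) {
    vapply(newdata$graph, predict_solubility, numeric(1), params = p)
  }, numeric(nrow(newdata)))
  mat <- matrix(mat, nrow = nrow(newdata))
  out <- tibble::tibble(id = newdata$id, predicted = rowMeans(mat))
  if (!is.null(newdata$target)) out$actual <- newdata$target
  out
}
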