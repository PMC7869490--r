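#' Default run configuration
#'
#' All knobs of the command-line workflows, with their defaults.  Unknown
#' keys passed to [resolve_run_config()] are rejected; the fully resolved
#' configuration (every default echoed) is written into the output
#' directory of each run so it can be replayed bit-identically.
#'
#' @return a named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L, out_dir = "contactsol_run", verbosity = 1L,
    # inputs
    fasta = NULL, feature_dir = NULL, contact_format = "auto",
    graphs = NULL, targets = NULL, checkpoints = NULL, predictions = NULL,
    spd33_angles = "degrees",
    # edge scheme
    edge_mode = "full", alpha = 0, edge_weighting = "continuous",
    # model
    gcn_dims = c(256L, 64L), attention_heads = 4L, attention_hidden = 128L,
    head_hidden = integer(0), layer_norm = TRUE,
    # training
    epochs = 100L, learning_rate = 1e-3, patience = 10L,
    validation_fraction = 0,
    # cross-validation
    folds = 5L, cv_seeds = 1:5,
    # evaluation
    threshold = 0.5,
    # simulation
    n_proteins = 50L, length_min = 30L, length_max = 80L, noise = 0.2,
    write_fixtures = FALSE
  )
}

#' Resolve a run configuration against the defaults
#'
#' @param config a named list of overrides, or the path of a YAML file.
#' @return the merged configuration list.
#' @export
resolve_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(config)] <- config
  defaults
}

config_scheme <- function(config) {
  edge_scheme(config$edge_mode, alpha = config$alpha,
              weighting = config$edge_weighting)
}

config_model <- function(config, input_dim) {
  model_config(input_dim = input_dim, gcn_dims = config$gcn_dims,
               attention_heads = config$attention_heads,
               attention_hidden = config$attention_hidden,
               head_hidden = config$head_hidden,
               layer_norm = config$layer_norm)
}

config_train <- function(config) {
  train_config(epochs = config$epochs, learning_rate = config$learning_rate,
               seed = config$seed, patience = config$patience,
               validation_fraction = config$validation_fraction)
}

run_log <- function(state, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = state$log, append = TRUE, sep = "")
  if (state$verbosity > 0) {
    message(sprintf("[contactsol] %s", event))
  }
  invisible(rec)
}

init_run <- function(config, command) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- config
  resolved$command <- command
  resolved$package_version <- as.character(utils::packageVersion("contactsol"))
  jsonlite::write_json(resolved,
                       file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  list(out_dir = config$out_dir,
       log = file.path(config$out_dir, "run_log.jsonl"),
       verbosity = config$verbosity)
}

#' Build protein graphs from feature files and contact maps
#'
#' For every record of the input FASTA, expects `<id>.pssm`, `<id>.hhm`,
#' `<id>.spd33` and `<id>.cmap` in `feature_dir`, assembles the five
#' feature groups (unstandardized; standardization statistics belong to a
#' trained checkpoint), applies the configured edge scheme and writes one
#' archive per protein plus a manifest under `out_dir/graphs`.  Missing or
#' unreadable files are reported per protein before the run fails.
#'
#' @param config a (possibly partial) run configuration; see
#'   [default_run_config()].  Requires `fasta` and `feature_dir`.
#' @return invisibly, the dataset tibble of built graphs.
#' @export
run_build_graph <- function(config = list()) {
  config <- resolve_run_config(config)
  if (is.null(config$fasta) || is.null(config$feature_dir)) {
    stop("build-graph requires 'fasta' and 'feature_dir'", call. = FALSE)
  }
  state <- init_run(config, "build-graph")
  seqs <- read_fasta_sequences(config$fasta)
  scheme <- config_scheme(config)
  gdir <- file.path(config$out_dir, "graphs")
  dir.create(gdir, showWarnings = FALSE)
  errors <- character(0)
  rows <- list()
  graphs <- list()
  for (id in names(seqs)) {
    files <- file.path(config$feature_dir,
                       paste0(id, c(".pssm", ".hhm", ".spd33", ".cmap")))
    names(files) <- c("PSSM", "HMM", "SPIDER3", "contact map")
    missing <- !file.exists(files)
    if (any(missing)) {
      errors <- c(errors, sprintf("%s: missing %s file (%s)", id,
                                  names(files)[missing][1],
                                  files[missing][1]))
      next
    }
    res <- tryCatch({
      L <- nchar(seqs[[id]])
      groups <- list(encode_blosum62(seqs[[id]]),
                     encode_aaphy7(seqs[[id]]),
                     read_profile("PSSM", files[["PSSM"]]),
                     read_profile("HMM", files[["HMM"]]),
                     read_profile("SPIDER3", files[["SPIDER3"]],
                                  angles = config$spd33_angles))
      nL <- vapply(groups, function(g) nrow(g$values), integer(1))
      if (any(nL != L)) {
        stop(sprintf("%s: feature rows (%s) do not match sequence length %d",
                     id, paste(nL, collapse = "/"), L))
      }
      feats <- assemble_features(groups)
      P <- read_contact_map(files[["contact map"]], L = L,
                            format = config$contact_format)
      build_contact_graph(P, feats, scheme, id = id)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, sprintf("%s: %s", id, res))
      next
    }
    archive <- list(id = id, graph = res, scheme = scheme,
                    provenance = as.list(tools::md5sum(unname(files))))
    saveRDS(archive, file.path(gdir, paste0(id, ".rds")))
    graphs[[id]] <- res
    rows[[id]] <- tibble::tibble(id = id, length = nchar(seqs[[id]]),
                                 file = paste0(id, ".rds"))
  }
  if (length(errors) > 0L) {
    stop(paste(c("graph construction failed for:", errors), collapse = "\n  "),
         call. = FALSE)
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(gdir, "manifest.csv"), row.names = FALSE)
  run_log(state, "build-graph complete", n = nrow(manifest))
  invisible(solubility_dataset(unname(graphs),
                               targets = rep(0, length(graphs)),
                               ids = names(graphs)))
}

load_graph_dataset <- function(config) {
  gdir <- config$graphs
  if (is.null(gdir)) stop("configuration key 'graphs' is required", call. = FALSE)
  manifest <- read.csv(file.path(gdir, "manifest.csv"))
  graphs <- lapply(manifest$file, function(f) readRDS(file.path(gdir, f))$graph)
  targets <- rep(NA_real_, nrow(manifest))
  if (!is.null(config$targets)) {
    tg <- read.csv(config$targets)
    targets <- tg$target[match(manifest$id, tg$id)]
  }
  tibble::tibble(id = manifest$id, graph = graphs, target = targets)
}

standardize_dataset <- function(dataset, scaler) {
  dataset$graph <- lapply(dataset$graph, function(g) {
    g$features <- apply_feature_scaler(scaler, g$features)
    g
  })
  dataset
}

save_checkpoint <- function(path, fit, scaler, scheme) {
  obj <- list(format = "contactsol_checkpoint", version = 1L,
              package_version = as.character(utils::packageVersion("contactsol")),
              model_config = fit$config, params = fit$params,
              scaler = scaler, scheme = scheme, history = fit$history)
  saveRDS(obj, path)
  invisible(path)
}

load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "contactsol_checkpoint")) {
    stop(sprintf("'%s' is not a contactsol checkpoint", path), call. = FALSE)
  }
  obj
}

#' Run a pipeline command
#'
#' Reproducible workflows binding the package together; each writes its
#' artifacts plus a resolved configuration and a JSON-lines log under
#' `out_dir`.
#'
#' * `simulate`: generate `n` synthetic proteins; writes `manifest.csv`
#'   (id, length, target) and, optionally, the external-format fixture
#'   files.
#' * `train`: fit one model on a graph archive (see [run_build_graph()]) or
#'   simulated data; writes `checkpoint.rds` (parameters + feature scaler +
#'   edge scheme).
#' * `cv`: k-fold cross-validation over the configured seeds; writes
#'   `cv_metrics.csv`, `cv_summary.csv` and the fold checkpoints.
#' * `predict`: score graphs with one checkpoint or an ensemble (the mean
#'   over checkpoints); writes `predictions.tsv`.
#' * `evaluate`: metrics for a predictions table; writes `metrics.csv` and
#'   `roc_curve.csv`.
#'
#' @param command one of `"simulate"`, `"train"`, `"cv"`, `"predict"`,
#'   `"evaluate"`.
#' @param config named list of overrides of [default_run_config()], or a
#'   YAML file path.
#' @return the command's main artifact, invisibly (dataset, fit, CV
#'   result, predictions or metrics).
#' @export
run_pipeline <- function(command = c("simulate", "train", "cv", "predict",
                                     "evaluate"),
                         config = list()) {
  command <- match.arg(command)
  config <- resolve_run_config(config)
  state <- init_run(config, command)
  switch(command,
    simulate = pipeline_simulate(config, state),
    train = pipeline_train(config, state),
    cv = pipeline_cv(config, state),
    predict = pipeline_predict(config, state),
    evaluate = pipeline_evaluate(config, state)
  )
}

pipeline_simulate <- function(config, state) {
  spec <- synthetic_protein_spec(
    length_range = c(config$length_min, config$length_max),
    noise = config$noise)
  sim <- simulate_proteins(config$n_proteins, spec, seed = config$seed)
  write.csv(sim[, c("id", "length", "target")],
            file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
  if (isTRUE(config$write_fixtures)) {
    fdir <- file.path(config$out_dir, "fixtures")
    for (p in sim$protein) write_fixture_files(p, fdir)
    fa <- unlist(lapply(sim$protein,
                        function(p) c(paste0(">", p$id), p$sequence)))
    writeLines(fa, file.path(config$out_dir, "proteins.fasta"))
  }
  run_log(state, "simulate complete", n = config$n_proteins)
  invisible(sim)
}

pipeline_dataset <- function(config) {
  if (!is.null(config$graphs)) {
    dataset <- load_graph_dataset(config)
    if (anyNA(dataset$target)) {
      stop("targets are required (configuration key 'targets')", call. = FALSE)
    }
  } else {
    spec <- synthetic_protein_spec(
      length_range = c(config$length_min, config$length_max),
      noise = config$noise)
    sim <- simulate_proteins(config$n_proteins, spec, seed = config$seed)
    dataset <- build_graph_dataset(sim, config_scheme(config))
  }
  dataset
}

pipeline_train <- function(config, state) {
  dataset <- pipeline_dataset(config)
  scaler <- fit_feature_scaler(lapply(dataset$graph, `[[`, "features"))
  dataset <- standardize_dataset(dataset, scaler)
  mcfg <- config_model(config, ncol(graph_features(dataset$graph[[1]])))
  fit <- train_model(dataset, mcfg, config_train(config))
  save_checkpoint(file.path(config$out_dir, "checkpoint.rds"), fit, scaler,
                  config_scheme(config))
  write.csv(fit$history, file.path(config$out_dir, "training_log.csv"),
            row.names = FALSE)
  run_log(state, "train complete", n = nrow(dataset),
          final_rmse = fit$history$rmse[nrow(fit$history)])
  invisible(fit)
}

pipeline_cv <- function(config, state) {
  dataset <- pipeline_dataset(config)
  scaler <- fit_feature_scaler(lapply(dataset$graph, `[[`, "features"))
  dataset <- standardize_dataset(dataset, scaler)
  mcfg <- config_model(config, ncol(graph_features(dataset$graph[[1]])))
  cv <- cross_validate(dataset, k = config$folds, seeds = config$cv_seeds,
                       config = mcfg, tconfig = config_train(config),
                       threshold = config$threshold)
  write.csv(cv$metrics, file.path(config$out_dir, "cv_metrics.csv"),
            row.names = FALSE)
  write.csv(cv$summary, file.path(config$out_dir, "cv_summary.csv"),
            row.names = FALSE)
  ckdir <- file.path(config$out_dir, "checkpoints")
  dir.create(ckdir, showWarnings = FALSE)
  for (i in seq_along(cv$models)) {
    save_checkpoint(file.path(ckdir, sprintf("fold_%02d.rds", i)),
                    cv$models[[i]], scaler, config_scheme(config))
  }
  run_log(state, "cv complete", runs = nrow(cv$metrics),
          r2_mean = cv$summary$r2_mean[1])
  invisible(cv)
}

pipeline_predict <- function(config, state) {
  if (is.null(config$checkpoints)) {
    stop("predict requires one or more 'checkpoints'", call. = FALSE)
  }
  cks <- lapply(config$checkpoints, load_checkpoint)
  dataset <- if (!is.null(config$graphs)) load_graph_dataset(config)
             else stop("predict requires a 'graphs' archive", call. = FALSE)
  per_model <- vapply(cks, function(ck) {
    ds <- standardize_dataset(dataset, ck$scaler)
    vapply(ds$graph, predict_solubility, numeric(1), params = ck$params)
  }, numeric(nrow(dataset)))
  per_model <- matrix(per_model, nrow = nrow(dataset))
  out <- tibble::tibble(id = dataset$id, predicted = rowMeans(per_model))
  if (!all(is.na(dataset$target))) out$actual <- dataset$target
  utils::write.table(out, file.path(config$out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run_log(state, "predict complete", n = nrow(out),
          n_models = length(cks))
  invisible(out)
}

pipeline_evaluate <- function(config, state) {
  if (is.null(config$predictions)) {
    stop("evaluate requires a 'predictions' TSV", call. = FALSE)
  }
  tab <- utils::read.delim(config$predictions)
  if (!all(c("predicted", "actual") %in% names(tab))) {
    stop("predictions file must have 'predicted' and 'actual' columns",
         call. = FALSE)
  }
  metrics <- compute_metrics(tab$predicted, tab$actual,
                             threshold = config$threshold)
  sweep <- threshold_sweep(tab$predicted, tab$actual)
  write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(sweep$roc, file.path(config$out_dir, "roc_curve.csv"),
            row.names = FALSE)
  write.csv(sweep$metrics, file.path(config$out_dir, "threshold_sweep.csv"),
            row.names = FALSE)
  run_log(state, "evaluate complete", n = nrow(tab), r2 = metrics$r2)
  invisible(metrics)
}
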