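# End-to-end experiment orchestration: flat key-value run configs and a
# single entry point executing simulate/load -> preprocess -> split ->
# train -> evaluate and writing plain-text/CSV reports.

run_config_keys <- function() {
  c("master_seed", "data.csv",
    "synth.benchmark", "synth.n_per_class", "synth.noise_sd",
    "pipeline.steps",
    paste0("pipeline.sg_derivative.",
           c("window", "polyorder", "deriv", "mode", "step_nm")),
    paste0("pipeline.sg_smooth.", c("window", "polyorder", "mode")),
    "pipeline.snv.sd_type", "pipeline.trim.from", "pipeline.trim.to",
    "split.fraction", "split.on",
    "model.method", "model.k", "model.metric", "model.n_hidden",
    "model.learning_rate", "model.epochs", "model.cost", "model.gamma",
    "model.kernel_size",
    "train.batch_size", "train.epochs", "train.learning_rate",
    "evaluate.n_runs")
}

#' Read and validate a flat run configuration
#'
#' Run configs are flat key-value YAML files whose keys cover the synth /
#' pipeline / split / model / train / evaluate sections plus
#' `master_seed`.  Unknown keys are rejected by name.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  check(is.list(cfg) && length(cfg) > 0, "empty run configuration")
  unknown <- setdiff(names(cfg), run_config_keys())
  check(length(unknown) == 0, "unknown config key '%s'", unknown[1])
  if (is.null(cfg$master_seed)) cfg$master_seed <- 1L
  if (is.null(cfg$`split.fraction`)) cfg$`split.fraction` <- 0.7
  if (is.null(cfg$`split.on`)) cfg$`split.on` <- "preprocessed"
  if (is.null(cfg$`model.method`)) cfg$`model.method` <- "elm"
  if (is.null(cfg$`evaluate.n_runs`)) cfg$`evaluate.n_runs` <- 1L
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run a complete discrimination experiment
#'
#' Executes the full workflow described by a [read_run_config()] config:
#' load a CSV dataset (or simulate one), preprocess, Kennard-Stone split,
#' train the configured classifier (repeatedly for stochastic models),
#' and evaluate.  Reports — the resolved config, the per-run accuracy
#' table, the aggregate table, and each run's test confusion matrix —
#' are written to `out_dir` as CSV/plain text; identical config and
#' master seed give byte-identical reports.
#'
#' @param config a `run_config` (or path / named list accepted by
#'   [read_run_config()]).
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with the split, per-run NERs and the
#'   aggregate summary.
#' @export
run_experiment <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$master_seed)

  set <- stage("load", {
    if (!is.null(config$`data.csv`)) {
      read_spectra_csv(config$`data.csv`)
    } else if (identical(config$`synth.benchmark`, "easy") ||
               is.null(config$`synth.benchmark`)) {
      easy_benchmark(seed = seed,
                     n_per_class = config$`synth.n_per_class` %||% 56)
    } else {
      scfg <- synth_config(n_per_class = config$`synth.n_per_class` %||% 56,
                           noise_sd = config$`synth.noise_sd` %||% 0.005,
                           seed = seed)
      simulate_dataset(scfg)
    }
  })
  X_raw <- spectra_matrix(set)
  y <- droplevels(maturity_labels(set))

  pl_keys <- grep("^pipeline\\.", names(config), value = TRUE)
  pipeline <- stage("preprocess", {
    if (length(pl_keys)) {
      pc <- config[pl_keys]
      names(pc) <- sub("^pipeline\\.", "", names(pc))
      pipeline_from_config(pc)
    } else {
      default_pipeline(step_nm = set$grid$step_nm)
    }
  })

  split_X <- if (identical(config$`split.on`, "raw")) X_raw else {
    stage("preprocess", apply_pipeline(fit_pipeline(pipeline, X_raw), X_raw))
  }
  sp <- stage("split", split_dataset(set, config$`split.fraction`, X = split_X))

  pipeline <- stage("preprocess",
                    fit_pipeline(pipeline, X_raw[sp$train_indices, , drop = FALSE]))
  x_tr <- apply_pipeline(pipeline, X_raw[sp$train_indices, , drop = FALSE])
  x_te <- apply_pipeline(pipeline, X_raw[sp$test_indices, , drop = FALSE])
  y_tr <- y[sp$train_indices]
  y_te <- y[sp$test_indices]

  method <- config$`model.method`
  n_runs <- as.integer(config$`evaluate.n_runs`)
  deterministic <- method %in% c("knn", "svm")
  if (deterministic) n_runs <- 1L

  model_args <- function(run_seed) {
    a <- switch(method,
      knn = list(k = config$`model.k` %||% 5,
                 metric = config$`model.metric` %||% "euclidean"),
      svm = list(cost = config$`model.cost` %||% 32,
                 gamma = config$`model.gamma` %||% (1 / ncol(x_tr))),
      elm = list(n_hidden = config$`model.n_hidden` %||% 150, seed = run_seed),
      bpnn = list(n_hidden = config$`model.n_hidden` %||% 20,
                  learning_rate = config$`model.learning_rate` %||% 1e-4,
                  epochs = config$`model.epochs` %||% 500, seed = run_seed),
      cnn = list(architecture = cnn_architecture(
                   input_length = ncol(x_tr), n_classes = nlevels(y_tr),
                   kernel_size = config$`model.kernel_size` %||% 5),
                 control = cnn_control(
                   batch_size = config$`train.batch_size` %||% 64,
                   epochs = config$`train.epochs` %||% 300,
                   learning_rate = config$`train.learning_rate` %||% 1e-3,
                   seed = run_seed)))
    a
  }

  runs <- stage("train", lapply(seq_len(n_runs), function(r) {
    model <- do.call(train_classifier,
                     c(list(method = method, x = x_tr, y = y_tr),
                       model_args(seed + r)))
    list(train = evaluate_model(model, x_tr, y_tr),
         test = evaluate_model(model, x_te, y_te))
  }))

  stage("evaluate", {
    train_ner <- vapply(runs, function(r) r$train$ner, 0)
    test_ner <- vapply(runs, function(r) r$test$ner, 0)
    per_run <- data.frame(run = seq_len(n_runs),
                          training = round_half_up(train_ner, 2),
                          testing = round_half_up(test_ner, 2))
    utils::write.csv(per_run, file.path(out_dir, "per_run.csv"),
                     row.names = FALSE)
    for (r in seq_len(n_runs)) {
      utils::write.csv(as.data.frame.matrix(unclass(runs[[r]]$test$confusion)),
                       file.path(out_dir, sprintf("confusion_run%d.csv", r)))
    }
    agg <- if (n_runs >= 2) {
      atr <- aggregate_runs(train_ner); ate <- aggregate_runs(test_ner)
      sprintf("%s  training %.2f +/- %.2f  testing %.2f +/- %.2f (%d runs)",
              method, round_half_up(atr$mean, 2), round_half_up(atr$sd, 2),
              round_half_up(ate$mean, 2), round_half_up(ate$sd, 2), n_runs)
    } else {
      sprintf("%s  training %.2f  testing %.2f (single run)",
              method, round_half_up(train_ner, 2), round_half_up(test_ner, 2))
    }
    writeLines(agg, file.path(out_dir, "aggregate.txt"))
    cfg_lines <- vapply(names(config), function(k)
      sprintf("%s: %s", k, paste(config[[k]], collapse = ",")), "")
    writeLines(c("# resolved configuration", sort(cfg_lines), "",
                 "# results", agg),
               file.path(out_dir, "report.txt"))
    invisible(list(split = sp, train_ner = train_ner, test_ner = test_ner,
                   summary = agg))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
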