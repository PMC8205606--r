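# The three experimental protocols: pretreatment comparison, CNN
# hyperparameter tuning (one factor at a time), and baseline tuning.

#' The five standard pretreatment pipelines
#'
#' The pipelines compared in the pretreatment-selection protocol: raw
#' spectra, first and second Savitzky-Golay derivatives, SNV, and MSC,
#' the four treatments coupled with SG smoothing and min-max
#' normalisation.
#'
#' @param window,polyorder SG filter parameters.
#' @param step_nm grid spacing for derivative scaling.
#' @return named list of [preprocess_pipeline()]s.
#' @export
standard_pretreatments <- function(window = 59, polyorder = 2, step_nm = 3.125) {
  list(
    raw = preprocess_pipeline(pp_step("minmax_norm")),
    first_derivative = preprocess_pipeline(
      pp_step("sg_derivative", window = window, polyorder = polyorder,
              deriv = 1, mode = "valid", step_nm = step_nm),
      pp_step("minmax_norm")),
    second_derivative = preprocess_pipeline(
      pp_step("sg_derivative", window = window, polyorder = polyorder,
              deriv = 2, mode = "valid", step_nm = step_nm),
      pp_step("minmax_norm")),
    snv = preprocess_pipeline(
      pp_step("sg_smooth", window = window, polyorder = polyorder,
              mode = "valid"),
      pp_step("snv"),
      pp_step("minmax_norm")),
    msc = preprocess_pipeline(
      pp_step("sg_smooth", window = window, polyorder = polyorder,
              mode = "valid"),
      pp_step("msc"),
      pp_step("minmax_norm")))
}

fit_predict_ner <- function(method, params, x_tr, y_tr, x_te, y_te) {
  model <- do.call(train_classifier,
                   c(list(method = method, x = x_tr, y = y_tr), params))
  evaluate_model(model, x_te, y_te)$ner
}

#' Pretreatment comparison protocol
#'
#' For each repeat, draws `n_subset` samples at random from the supplied
#' (training) data, splits them at `ratio` (calibration : internal test),
#' fits each candidate pipeline on the calibration rows, trains each
#' model, and records the internal-test NER.  Mean NER over repeats is
#' reported per (pretreatment, model) cell.
#'
#' @param X raw spectra matrix (training rows).
#' @param y class labels aligned with `X`.
#' @param methods named list of [preprocess_pipeline()]s; defaults to
#'   [standard_pretreatments()].
#' @param models named list: model name (see [train_classifier()]) mapped
#'   to a list of fitting parameters.
#' @param n_subset number of samples drawn per repeat (default 450).
#' @param ratio calibration fraction of the subset (default 2/3, the
#'   2:1 split).
#' @param n_repeats number of random repeats (default 5).
#' @param seed master seed; the subsampling and every model seed derive
#'   from it.
#' @return matrix of mean NER, rows = pretreatments, columns = models.
#' @export
compare_preprocessing <- function(X, y, methods = standard_pretreatments(),
                                  models = list(knn = list(k = 5),
                                                elm = list(n_hidden = 100)),
                                  n_subset = 450, ratio = 2 / 3,
                                  n_repeats = 5, seed = 1) {
  y <- as.factor(y)
  check(nrow(X) >= n_subset,
        "dataset has %d rows but n_subset is %d", nrow(X), n_subset)
  res <- array(0, c(length(methods), length(models), n_repeats),
               dimnames = list(names(methods), names(models), NULL))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      sub <- sample(nrow(X), n_subset)
      n_cal <- round_half_up(n_subset * ratio)
      cal <- sub[seq_len(n_cal)]
      tst <- sub[(n_cal + 1):n_subset]
      for (m in seq_along(methods)) {
        pl <- fit_pipeline(methods[[m]], X[cal, , drop = FALSE])
        x_tr <- apply_pipeline(pl, X[cal, , drop = FALSE])
        x_te <- apply_pipeline(pl, X[tst, , drop = FALSE])
        for (k in seq_along(models)) {
          params <- models[[k]]
          if (names(models)[k] %in% c("elm", "bpnn", "cnn") &&
              is.null(params$seed)) {
            params$seed <- seed + r
          }
          res[m, k, r] <- fit_predict_ner(names(models)[k], params,
                                          x_tr, y[cal], x_te, y[tst])
        }
      }
    }
  })
  apply(res, c(1, 2), mean)
}

#' One-factor-at-a-time CNN hyperparameter tuning
#'
#' Reproduces the tuning protocol: `n_val` samples are drawn at random
#' from the training set as a validation set (the rest forming the
#' calibration set), the procedure is repeated `n_repeats` times, and
#' mean calibration/validation accuracies are recorded for every grid
#' value.  The three factors are swept in the order kernel size ->
#' batch size -> epochs, each sweep fixing the previous factor at its
#' best (highest mean validation accuracy, ties to the first value).
#'
#' @param x preprocessed training spectra matrix.
#' @param y class labels.
#' @param kernel_grid,batch_grid,epoch_grid candidate values; defaults
#'   are the published search grids.
#' @param n_val validation-set size per repeat (default 150).
#' @param n_repeats number of repeats (default 5).
#' @param base_control a [cnn_control()] providing the non-swept training
#'   settings (its `batch_size` and `epochs` seed the first sweeps).
#' @param architecture_for function mapping a kernel size to a
#'   [cnn_architecture()]; defaults to the standard two-block
#'   architecture sized to the data.
#' @param seed master seed.
#' @return list with `best` (kernel, batch_size, epochs) and `curves`
#'   (per-factor data frames of mean calibration/validation accuracy).
#' @export
tune_cnn <- function(x, y,
                     kernel_grid = c(5, 9, 13, 17, 21),
                     batch_grid = c(16, 32, 64, 128, 256),
                     epoch_grid = c(50, 100, 150, 200, 300, 500, 750, 1000),
                     n_val = 150, n_repeats = 5,
                     base_control = cnn_control(),
                     architecture_for = NULL, seed = 1) {
  y <- as.factor(y)
  check(nrow(x) > n_val, "training set must exceed n_val (%d)", n_val)
  splits <- with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    val <- sample(nrow(x), n_val)
    list(val = val, cal = setdiff(seq_len(nrow(x)), val))
  }))

  sweep1 <- function(values, make_run) {
    acc <- lapply(seq_along(values), function(vi) {
      runs <- vapply(seq_len(n_repeats), function(r) {
        make_run(values[vi], splits[[r]], seed + r)
      }, numeric(2))
      c(cal = mean(runs[1, ]), val = mean(runs[2, ]))
    })
    df <- data.frame(value = values,
                     calibration = vapply(acc, `[[`, 0, "cal"),
                     validation = vapply(acc, `[[`, 0, "val"))
    list(df = df, best = values[which.max(df$validation)])
  }

  if (is.null(architecture_for)) {
    architecture_for <- function(kernel)
      cnn_architecture(input_length = ncol(x), n_classes = nlevels(y),
                       kernel_size = kernel)
  }

  run_config <- function(kernel, batch, epochs, split, run_seed) {
    ctl <- cnn_control(batch_size = batch, epochs = epochs,
                       learning_rate = base_control$learning_rate,
                       seed = run_seed)
    arch <- architecture_for(kernel)
    fit <- cnn(x[split$cal, , drop = FALSE], y[split$cal],
               architecture = arch, control = ctl)
    c(evaluate_model(fit, x[split$cal, , drop = FALSE], y[split$cal])$ner,
      evaluate_model(fit, x[split$val, , drop = FALSE], y[split$val])$ner)
  }

  ks <- sweep1(kernel_grid, function(v, split, s)
    run_config(v, base_control$batch_size, base_control$epochs, split, s))
  bs <- sweep1(batch_grid, function(v, split, s)
    run_config(ks$best, v, base_control$epochs, split, s))
  es <- sweep1(epoch_grid, function(v, split, s)
    run_config(ks$best, bs$best, v, split, s))

  list(best = list(kernel_size = ks$best, batch_size = bs$best,
                   epochs = es$best),
       curves = list(kernel_size = ks$df, batch_size = bs$df,
                     epochs = es$df))
}

#' Tune the four baseline classifiers
#'
#' KNN's neighbour count is selected by k-fold cross-validated accuracy;
#' the SVM penalty and kernel parameters by a power-of-two grid search
#' under the same cross-validation; ELM and BPNN hidden-layer widths by
#' accuracy on a seeded held-out validation split.  The output schema
#' mirrors the optimal-parameter report table.
#'
#' @param x preprocessed training spectra matrix.
#' @param y class labels.
#' @param knn_k_grid candidate neighbour counts.
#' @param svm_cost_grid,svm_gamma_grid power-of-two grids (defaults
#'   `2^(-10:10)`).
#' @param elm_grid,bpnn_grid candidate hidden-layer widths.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param val_fraction held-out fraction for the ELM/BPNN selection.
#' @param bpnn_args,elm_args extra fitting arguments (epochs, learning
#'   rate, ...) used during selection.
#' @param seed master seed.
#' @return list with elements `knn` (k), `svm` (cost, gamma), `elm` and
#'   `bpnn` (n_hidden), each including the achieved selection accuracy.
#' @export
tune_baselines <- function(x, y,
                           knn_k_grid = 1:20,
                           svm_cost_grid = 2^(-10:10),
                           svm_gamma_grid = 2^(-10:10),
                           elm_grid = seq(20, 200, by = 20),
                           bpnn_grid = 1:30,
                           cv_folds = 10, val_fraction = 0.25,
                           bpnn_args = list(epochs = 200, learning_rate = 0.05),
                           elm_args = list(), seed = 1) {
  y <- as.factor(y)
  n <- nrow(x)
  check(n >= cv_folds, "dataset too small for %d folds", cv_folds)
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(cv_folds), n))

    cv_acc <- function(fit_fun) {
      correct <- 0
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        model <- fit_fun(x[tr, , drop = FALSE], droplevels(y[tr]))
        pred <- stats::predict(model, x[!tr, , drop = FALSE])
        correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
      }
      100 * correct / n
    }

    knn_acc <- vapply(knn_k_grid, function(k)
      cv_acc(function(xx, yy) knn_classifier(xx, yy, k = k)), 0)
    best_k <- knn_k_grid[which.max(knn_acc)]

    svm_grid <- expand.grid(cost = svm_cost_grid, gamma = svm_gamma_grid)
    svm_acc <- vapply(seq_len(nrow(svm_grid)), function(i)
      cv_acc(function(xx, yy) svm_rbf(xx, yy, cost = svm_grid$cost[i],
                                      gamma = svm_grid$gamma[i])), 0)
    best_svm <- svm_grid[which.max(svm_acc), ]

    val <- sample(n, max(1, round_half_up(n * val_fraction)))
    cal <- setdiff(seq_len(n), val)
    val_acc <- function(fit_fun) {
      model <- fit_fun(x[cal, , drop = FALSE], droplevels(y[cal]))
      pred <- stats::predict(model, x[val, , drop = FALSE])
      100 * mean(as.character(pred) == as.character(y[val]))
    }
    elm_acc <- vapply(elm_grid, function(h)
      val_acc(function(xx, yy) do.call(elm, c(list(x = xx, y = yy,
                                                   n_hidden = h, seed = seed),
                                              elm_args))), 0)
    bpnn_acc <- vapply(bpnn_grid, function(h)
      val_acc(function(xx, yy) do.call(bpnn, c(list(x = xx, y = yy,
                                                    n_hidden = h, seed = seed),
                                               bpnn_args))), 0)

    list(knn = list(k = best_k, accuracy = max(knn_acc)),
         svm = list(cost = best_svm$cost, gamma = best_svm$gamma,
                    accuracy = max(svm_acc)),
         elm = list(n_hidden = elm_grid[which.max(elm_acc)],
                    accuracy = max(elm_acc)),
         bpnn = list(n_hidden = bpnn_grid[which.max(bpnn_acc)],
                     accuracy = max(bpnn_acc)))
  })
}
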