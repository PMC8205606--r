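# Spectral pretreatment operators.  All operators act row-wise on a matrix
# (one spectrum per row) and are pure except for the MSC reference, which is
# fitted on training rows and frozen thereafter.

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering of each spectrum.  With
#' `deriv = 1` or `2` the filter returns the first or second derivative of
#' the fitted polynomial, scaled by the grid spacing so that derivatives
#' carry units of reflectance per nm.  `mode = "valid"` keeps only the
#' positions where the full window fits, shortening each row by
#' `window - 1` points; `mode = "same"` keeps the original length, fitting
#' shifted windows at the edges.
#'
#' Filter coefficients are taken from [signal::sgolay()]; the result is
#' exact (to rounding) for any polynomial of degree at most `polyorder`.
#'
#' @param X numeric matrix (rows = spectra) or a single spectrum vector.
#' @param window odd filter window length, `polyorder < window <= ncol(X)`.
#' @param polyorder degree of the local polynomial fit.
#' @param deriv derivative order, 0 (smoothing), 1 or 2.
#' @param mode `"same"` or `"valid"`.
#' @param step_nm grid spacing used to scale derivatives (default 1).
#' @return filtered matrix with `ncol(X)` columns (`same`) or
#'   `ncol(X) - window + 1` columns (`valid`).
#' @examples
#' wl <- seq(0, 10, by = 0.5)
#' X <- rbind(2 * wl, wl^2)
#' d1 <- sg_filter(X, window = 7, polyorder = 2, deriv = 1,
#'                 mode = "valid", step_nm = 0.5)
#' d1[1, 1:3]  # constant 2: exact derivative of 2*lambda
#' @export
sg_filter <- function(X, window, polyorder, deriv = 0,
                      mode = c("same", "valid"), step_nm = 1) {
  mode <- match.arg(mode)
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  p <- ncol(X)
  check(window %% 2 == 1, "window must be odd, got %d", window)
  check(polyorder < window, "window (%d) must exceed polyorder (%d)",
        window, polyorder)
  check(deriv %in% 0:2 && deriv <= polyorder,
        "deriv must be 0, 1 or 2 and at most polyorder")
  check(window <= p, "window (%d) exceeds spectrum length (%d)", window, p)
  check(step_nm > 0, "step_nm must be positive")

  FF <- unclass(signal::sgolay(p = polyorder, n = window, m = deriv, ts = 1))
  half <- (window - 1) / 2
  centre <- FF[half + 1, ]
  n_valid <- p - window + 1

  # valid region for every row at once: sum over window offsets
  Yv <- matrix(0, nrow(X), n_valid)
  for (i in seq_len(window)) {
    Yv <- Yv + centre[i] * X[, i:(i + n_valid - 1), drop = FALSE]
  }
  Yv <- Yv / step_nm^deriv
  if (mode == "valid") return(Yv)

  # same mode: shifted-window fits at the two edges (rows of the sgolay
  # matrix other than the centre one), as in signal::sgolayfilt
  left  <- X[, 1:window, drop = FALSE] %*% t(FF[1:half, , drop = FALSE])
  right <- X[, (p - window + 1):p, drop = FALSE] %*%
    t(FF[(half + 2):window, , drop = FALSE])
  cbind(left / step_nm^deriv, Yv, right / step_nm^deriv)
}

#' Standard normal variate (SNV) transformation
#'
#' Centres each spectrum by its own mean and divides by its own standard
#' deviation, removing additive offsets and multiplicative scatter.  The
#' denominator uses the sample (n-1) standard deviation by default.
#'
#' @param X numeric matrix, rows = spectra.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return matrix of the same shape; each row has mean 0 and the chosen
#'   standard deviation 1.
#' @export
snv <- function(X, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- rowSums(Xc^2)
  denom <- if (sd_type == "sample") ncol(X) - 1 else ncol(X)
  s <- sqrt(ss / denom)
  bad <- which(s < .Machine$double.eps * 100)
  check(length(bad) == 0,
        "snv: row %d is (near-)constant and cannot be scaled",
        if (length(bad)) bad[1] else 0L)
  Xc / s
}

#' Multiplicative scatter correction (MSC)
#'
#' `msc_fit()` computes the reference spectrum (the column mean of the
#' training rows).  `msc_apply()` regresses each spectrum `x` on the
#' reference, `x ~ a + b * ref` by ordinary least squares, and returns the
#' corrected spectrum `(x - a) / b`.  The reference is fitted on training
#' rows only and frozen when correcting test rows.
#'
#' @param X_train numeric matrix of training spectra (>= 2 rows).
#' @return `msc_fit()` returns an object of class `msc_reference` holding
#'   `reference_spectrum`.
#' @examples
#' ref <- seq(0, 1, length.out = 20)
#' X <- rbind(1 + 2 * ref, 0.5 + 0.8 * ref)
#' fit <- msc_fit(X)
#' corrected <- msc_apply(X, fit)   # both rows collapse onto colMeans(X)
#' @export
msc_fit <- function(X_train) {
  check(is.matrix(X_train) && nrow(X_train) >= 2,
        "msc_fit needs a matrix with at least 2 training rows")
  structure(list(reference_spectrum = colMeans(X_train)),
            class = "msc_reference")
}

#' @param X numeric matrix of spectra to correct.
#' @param ref an `msc_reference` from [msc_fit()], or a plain numeric
#'   vector used directly as the reference spectrum.
#' @rdname msc_fit
#' @export
msc_apply <- function(X, ref) {
  if (inherits(ref, "msc_reference")) ref <- ref$reference_spectrum
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  check(length(ref) == ncol(X),
        "reference length %d does not match spectrum length %d",
        length(ref), ncol(X))
  refc <- ref - mean(ref)
  sxx <- sum(refc^2)
  check(sxx > 0, "msc reference is constant")
  b <- as.vector((X %*% refc)) / sxx        # row-wise slope
  bad <- which(abs(b) < 1e-12)
  check(length(bad) == 0,
        "msc: row %d has slope ~0 against the reference and cannot be corrected",
        if (length(bad)) bad[1] else 0L)
  a <- rowMeans(X) - b * mean(ref)
  (X - a) / b
}

#' Per-spectrum min-max normalisation to [0, 1]
#'
#' @param X numeric matrix, rows = spectra; no constant rows.
#' @return matrix with each row affinely mapped so its minimum is 0 and
#'   maximum is 1.
#' @export
minmax_norm <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  bad <- which(hi - lo <= 0)
  check(length(bad) == 0,
        "minmax_norm: row %d is constant", if (length(bad)) bad[1] else 0L)
  (X - lo) / (hi - lo)
}

#' Per-spectrum unit-vector (L2) normalisation
#'
#' An alternative normalisation: each row is divided by its Euclidean norm.
#'
#' @param X numeric matrix, rows = spectra.
#' @export
unit_norm <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm <= 0)
  check(length(bad) == 0,
        "unit_norm: row %d is all-zero", if (length(bad)) bad[1] else 0L)
  X / nrm
}

# ---- pipelines --------------------------------------------------------------

pp_step_names <- c("sg_smooth", "sg_derivative", "snv", "msc",
                   "minmax_norm", "unit_norm", "trim")

#' Preprocessing pipelines
#'
#' A pipeline is an ordered list of operator steps applied row-wise to a
#' spectra matrix.  Stateful steps (only MSC) must be fitted on training
#' rows with [fit_pipeline()] before the pipeline can be applied to test
#' rows; all other operators are pure.
#'
#' Available step names and their parameters:
#' \describe{
#'   \item{sg_smooth}{`window`, `polyorder`, `mode` — Savitzky-Golay smoothing.}
#'   \item{sg_derivative}{`window`, `polyorder`, `deriv` (1 or 2), `mode`,
#'     `step_nm` — SG derivative.}
#'   \item{snv}{`sd_type` — standard normal variate.}
#'   \item{msc}{no parameters; reference fitted by [fit_pipeline()].}
#'   \item{minmax_norm}{per-row min-max to [0,1].}
#'   \item{unit_norm}{per-row L2 normalisation.}
#'   \item{trim}{`from`, `to` — keep columns `from:to`.}
#' }
#'
#' @param ... steps created with [pp_step()].
#' @return object of class `preprocess_pipeline`.
#' @examples
#' pl <- preprocess_pipeline(
#'   pp_step("sg_derivative", window = 7, polyorder = 2, deriv = 1),
#'   pp_step("minmax_norm"))
#' X <- matrix(rnorm(200), 10, 20)
#' apply_pipeline(fit_pipeline(pl, X), X)
#' @export
preprocess_pipeline <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) && !inherits(steps[[1]], "pp_step"))
    steps <- steps[[1]]
  for (s in steps) check(inherits(s, "pp_step"), "all steps must be pp_step objects")
  structure(list(steps = steps, fitted = FALSE), class = "preprocess_pipeline")
}

#' @param name step name, one of the vocabulary above.
#' @param ... named step parameters.
#' @rdname preprocess_pipeline
#' @export
pp_step <- function(name, ...) {
  check(name %in% pp_step_names, "unknown preprocessing step '%s'", name)
  structure(list(name = name, params = list(...)), class = "pp_step")
}

#' The default pretreatment pipeline
#'
#' First-derivative Savitzky-Golay filtering (window 59, quadratic fit,
#' valid mode) followed by per-spectrum min-max normalisation.  On the
#' default 512-point acquisition grid this yields 454-point rows, the
#' input width of the default CNN architecture.
#'
#' @param window,polyorder SG parameters.
#' @param step_nm grid spacing for derivative scaling (default 3.125 nm).
#' @rdname preprocess_pipeline
#' @export
default_pipeline <- function(window = 59, polyorder = 2, step_nm = 3.125) {
  preprocess_pipeline(
    pp_step("sg_derivative", window = window, polyorder = polyorder,
            deriv = 1, mode = "valid", step_nm = step_nm),
    pp_step("minmax_norm"))
}

#' @param pipeline a `preprocess_pipeline`.
#' @param X_train training spectra matrix used to fit stateful steps.
#' @return `fit_pipeline()` returns the pipeline with fitted state attached.
#' @rdname preprocess_pipeline
#' @export
fit_pipeline <- function(pipeline, X_train) {
  stopifnot(inherits(pipeline, "preprocess_pipeline"))
  Z <- X_train
  for (i in seq_along(pipeline$steps)) {
    s <- pipeline$steps[[i]]
    if (s$name == "msc") {
      pipeline$steps[[i]]$params$ref <- msc_fit(Z)
    }
    Z <- apply_step(Z, pipeline$steps[[i]], i)
  }
  pipeline$fitted <- TRUE
  pipeline
}

#' @return `apply_pipeline()` returns the transformed matrix; width may
#'   shrink (valid-mode SG, trim) but is identical for every row.
#' @rdname preprocess_pipeline
#' @export
apply_pipeline <- function(pipeline, X) {
  stopifnot(inherits(pipeline, "preprocess_pipeline"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  Z <- X
  for (i in seq_along(pipeline$steps)) {
    s <- pipeline$steps[[i]]
    if (s$name == "msc" && is.null(s$params$ref))
      stop(sprintf("step %d (msc): reference not fitted; call fit_pipeline() on training rows first", i),
           call. = FALSE)
    Z <- apply_step(Z, s, i)
  }
  Z
}

apply_step <- function(Z, s, idx) {
  res <- tryCatch(switch(
    s$name,
    sg_smooth = do.call(sg_filter, c(list(X = Z, deriv = 0),
                                     s$params[setdiff(names(s$params), "deriv")])),
    sg_derivative = do.call(sg_filter, c(list(X = Z), s$params)),
    snv = do.call(snv, c(list(X = Z), s$params)),
    msc = msc_apply(Z, s$params$ref),
    minmax_norm = minmax_norm(Z),
    unit_norm = unit_norm(Z),
    trim = Z[, s$params$from:s$params$to, drop = FALSE]
  ), error = function(e) {
    stop(sprintf("step %d (%s): %s", idx, s$name, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' @export
print.preprocess_pipeline <- function(x, ...) {
  cat(sprintf("<preprocess_pipeline> %d step(s)%s\n", length(x$steps),
              if (x$fitted) " [fitted]" else ""))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    pars <- s$params[setdiff(names(s$params), "ref")]
    cat(sprintf("  %d. %s(%s)\n", i, s$name,
                paste(names(pars), unlist(pars), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

# flat key-value (de)serialisation of a pipeline, YAML dialect
#' Serialise / deserialise a pipeline as a flat key-value config
#'
#' The config maps `steps` to a comma-separated step-name list and each
#' parameter to `<step>.<param>` keys, e.g. `sg_derivative.window: 59`.
#'
#' @param pipeline a [preprocess_pipeline()].
#' @return `pipeline_to_config()` a named list; `pipeline_from_config()`
#'   the reconstructed pipeline.
#' @param config named list as produced by `pipeline_to_config()` or read
#'   from a YAML file.
#' @export
pipeline_to_config <- function(pipeline) {
  cfg <- list(steps = paste(vapply(pipeline$steps, `[[`, "", "name"),
                            collapse = ","))
  for (s in pipeline$steps) {
    for (p in setdiff(names(s$params), "ref")) {
      cfg[[paste(s$name, p, sep = ".")]] <- s$params[[p]]
    }
  }
  cfg
}

#' @rdname pipeline_to_config
#' @export
pipeline_from_config <- function(config) {
  check(!is.null(config$steps), "pipeline config lacks a 'steps' key")
  names_ <- strsplit(config$steps, ",")[[1]]
  steps <- lapply(trimws(names_), function(nm) {
    keys <- grep(paste0("^", nm, "\\."), names(config), value = TRUE)
    params <- config[keys]
    names(params) <- sub(paste0("^", nm, "\\."), "", keys)
    do.call(pp_step, c(list(name = nm), params))
  })
  preprocess_pipeline(steps)
}

#' Principal component scores of a spectra matrix
#'
#' Column-mean-centred PCA (no scaling: spectra share one unit).  Used to
#' visualise class clustering; scores are the projections on the leading
#' principal axes and the variance ratios are each component's share of
#' total variance.
#'
#' @param X numeric matrix, rows = spectra.
#' @param n_components number of leading components,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return list with `scores` (n x n_components) and
#'   `explained_variance_ratio` (descending, each in [0,1], summing to
#'   at most 1).
#' @export
pca_scores <- function(X, n_components) {
  check(is.matrix(X) && nrow(X) >= 2, "pca_scores needs a matrix with >= 2 rows")
  kmax <- min(nrow(X) - 1, ncol(X))
  check(n_components >= 1 && n_components <= kmax,
        "n_components must be in 1..%d, got %d", kmax, n_components)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance_ratio = evr[seq_len(n_components)])
}
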