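# The NER discriminant-accuracy statistic, confusion matrices, and
# repeated-run aggregation.

#' Confusion matrix of true vs predicted labels
#'
#' Rows index the true class, columns the predicted class, both in the
#' order of `levels`.
#'
#' @param truth,predicted factors (or coercible) of equal length.
#' @param levels class levels; defaults to the union of levels of both.
#' @return object of class `confusion_matrix`: an integer G x G matrix
#'   with attributes `n` (total) and `G` (number of categories).
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- union(levels(as.factor(truth)),
                                       levels(as.factor(predicted)))
  truth <- factor(truth, levels = levels)
  predicted <- factor(predicted, levels = levels)
  check(length(truth) == length(predicted), "truth and predicted differ in length")
  check(!anyNA(truth) && !anyNA(predicted), "labels outside the given levels")
  m <- table(truth = truth, predicted = predicted)
  structure(unclass(m), class = "confusion_matrix",
            n = length(truth), G = length(levels))
}

#' NER: discriminant accuracy from a confusion matrix
#'
#' The percentage of samples on the confusion-matrix diagonal,
#' `100 * sum(n_gg) / n` where `n_gg` counts samples of true class g
#' predicted as class g.  Full precision is retained; reports round
#' half-up to 2 decimals via [round_half_up()].
#'
#' @param confusion a [confusion_matrix()] or any square count matrix.
#' @return NER as a percentage in [0, 100].
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' ner(cm)  # 66.67 (2 of 3 on the diagonal) at full precision
#' @export
ner <- function(confusion) {
  m <- unclass(confusion)
  check(is.matrix(m) && nrow(m) == ncol(m), "confusion must be a square matrix")
  check(all(m >= 0), "confusion counts must be non-negative")
  n <- sum(m)
  check(n > 0, "empty evaluation: confusion matrix has no samples")
  100 * sum(diag(m)) / n
}

#' Aggregate repeated-run accuracies
#'
#' Arithmetic mean and sample (n-1) standard deviation of a vector of
#' per-run percentages, the aggregation used for the repeated-run report
#' tables ("mean +/- sd").
#'
#' @param values numeric vector of at least 2 per-run values.
#' @return list with `mean`, `sd`, `n_runs`, and `per_run_values`.
#' @examples
#' aggregate_runs(c(95.86, 95.86, 96.15, 96.45, 95.86,
#'                  96.15, 96.45, 96.15, 96.45, 96.45))
#' @export
aggregate_runs <- function(values) {
  check(length(values) >= 2,
        "sd undefined: need at least 2 run values, got %d", length(values))
  list(mean = mean(values), sd = stats::sd(values),
       n_runs = length(values), per_run_values = values)
}

#' Relative improvement of one accuracy over another
#'
#' `100 * (a - b) / b`: the percent change of `a` relative to baseline
#' `b`, the arithmetic behind "increased by x%" model comparisons.
#'
#' @param a new value.
#' @param b baseline value (> 0).
#' @return percentage change.
#' @examples
#' relative_improvement(96.18, 84.02)  # 14.47 after 2-decimal rounding
#' @export
relative_improvement <- function(a, b) {
  check(b > 0, "baseline must be positive, got %g", b)
  100 * (a - b) / b
}

#' Evaluate a fitted classifier on a test set
#'
#' @param model a fitted `nir_model`.
#' @param x test spectra matrix.
#' @param y true labels.
#' @return list with the `confusion_matrix` and `ner`.
#' @export
evaluate_model <- function(model, x, y) {
  y <- as.factor(y)
  pred <- stats::predict(model, x)
  cm <- confusion_matrix(y, pred, levels = model$levels)
  list(confusion = cm, ner = ner(cm))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d samples, %d classes, NER %.2f%%\n",
              attr(x, "n"), attr(x, "G"), round_half_up(ner(x), 2)))
  print(unclass(x))
  invisible(x)
}
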