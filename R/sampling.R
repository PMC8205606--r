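# Deterministic calibration/test partitioning.

#' Training-set size under round-half-up
#'
#' The number of calibration samples for a split fraction: `fraction * n`
#' rounded half-up, the convention that reproduces the published split
#' sizes including the exact-half case (70% of 1085 = 759.5 -> 760).
#'
#' @param n total number of samples (>= 2).
#' @param fraction calibration fraction in (0, 1).
#' @return integer training-set size; the complement goes to the test set.
#' @examples
#' train_size(1128, 0.7)  # 790
#' train_size(1085, 0.7)  # 760
#' @export
train_size <- function(n, fraction) {
  check(n >= 2, "n must be at least 2, got %g", n)
  check(fraction > 0 && fraction < 1, "fraction must be in (0,1), got %g", fraction)
  as.integer(round_half_up(n * fraction))
}

#' Kennard-Stone sample selection
#'
#' Deterministic max-min selection of a representative subset: the first
#' two picks are a globally farthest pair; every subsequent pick maximises
#' its minimum distance to the already-selected set.  Ties (equal
#' distances) are broken by the lowest row index, so the algorithm is
#' fully deterministic across platforms.  Output order is selection order.
#'
#' @param X numeric matrix, one sample per row.
#' @param n_select number of samples to select (2 .. nrow(X)).
#' @param metric distance metric; only `"euclidean"` is supported.
#' @return integer vector of selected row indices, in selection order.
#' @examples
#' X <- matrix(c(0, 1, 10), ncol = 1)
#' kennard_stone(X, 2)  # rows 1 and 3: the farthest pair
#' @export
kennard_stone <- function(X, n_select, metric = "euclidean") {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  n <- nrow(X)
  check(metric == "euclidean", "unsupported metric '%s'", metric)
  check(n_select >= 2, "n_select must be at least 2, got %d", n_select)
  check(n_select <= n, "n_select (%d) exceeds number of rows (%d)", n_select, n)

  # farthest pair; ties -> lexicographically smallest (i, j)
  d2 <- cross_dist2(X, X)
  check(max(d2) > 0, "all rows coincide; no farthest pair exists")
  idx <- which(d2 == max(d2), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- c(idx[1, 1], idx[1, 2])

  # min squared distance from every row to the selected set
  mind <- pmin(d2[, sel[1]], d2[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_select) {
    nxt <- which.max(mind)            # which.max takes the first (lowest index) tie
    sel <- c(sel, nxt)
    mind <- pmin(mind, d2[, nxt])
    mind[nxt] <- -Inf
  }
  as.integer(sel)
}

#' Kennard-Stone train/test split of a dataset
#'
#' Selects `train_size(n, fraction)` calibration rows by [kennard_stone()]
#' on the supplied feature matrix (typically the preprocessed spectra) and
#' assigns the complement to the test set.
#'
#' By default KS runs globally over the dataset (split totals are
#' conventionally reported per dataset, not per class); `stratify = TRUE`
#' instead runs KS within each maturity class and unions the selections,
#' guaranteeing every class its share of both subsets.
#'
#' @param set a [spectra_set()] whose records align with the matrix rows,
#'   or `NULL` to split a bare matrix.
#' @param fraction calibration fraction in (0, 1).
#' @param X feature matrix on which distances are computed; defaults to
#'   the set's mean-spectra matrix.
#' @param stratify run KS per maturity class (requires `set`).
#' @return object of class `split_result`: `train_indices`,
#'   `test_indices` (both in ascending order), `fraction`.
#' @export
split_dataset <- function(set = NULL, fraction = 0.7, X = NULL,
                          stratify = FALSE) {
  if (is.null(X)) {
    check(inherits(set, "spectra_set"), "either a spectra_set or a matrix X is required")
    X <- spectra_matrix(set)
  }
  if (!is.null(set)) {
    check(nrow(X) == length(set$records),
          "matrix rows (%d) do not align with set records (%d)",
          nrow(X), length(set$records))
  }
  n <- nrow(X)
  if (stratify) {
    check(inherits(set, "spectra_set"), "stratified splitting needs a spectra_set")
    y <- maturity_labels(set)
    tr <- integer(0)
    for (lvl in levels(droplevels(y))) {
      rows <- which(y == lvl)
      tr <- c(tr, rows[kennard_stone(X[rows, , drop = FALSE],
                                     train_size(length(rows), fraction))])
    }
    tr <- sort(tr)
  } else {
    tr <- sort(kennard_stone(X, train_size(n, fraction)))
  }
  structure(list(train_indices = tr,
                 test_indices = setdiff(seq_len(n), tr),
                 fraction = fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> train %d / test %d (fraction %.3g)\n",
              length(x$train_indices), length(x$test_indices), x$fraction))
  invisible(x)
}
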