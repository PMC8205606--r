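# Shared fixtures and independent oracles, all built in code.

# Brute-force Kennard-Stone oracle: plain loops over the full distance
# matrix, independent of the package's incremental implementation.
ks_oracle <- function(X, k) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    score <- sapply(cand, function(c0) min(D[c0, sel]))
    sel <- c(sel, cand[which.max(score)])
  }
  as.integer(sel)
}

# A minimal labelled spectra_set on a short grid.
tiny_set <- function(n_points = 10, n_spots = 2, seed = 1) {
  g <- make_grid(0, n_points, 1)
  withr::with_seed(seed, {
    recs <- list(
      spectrum_record("s1", "upper", "ripe",
                      matrix(rnorm(n_spots * n_points), n_spots)),
      spectrum_record("s2", "middle", "unripe",
                      matrix(rnorm(n_spots * n_points), n_spots)),
      spectrum_record("s3", "lower", "overmature",
                      matrix(rnorm(n_spots * n_points), n_spots)))
    spectra_set(g, recs)
  })
}

# Cached easy benchmark with its default preprocessing and split, shared
# across test files to avoid regenerating it.
bench_env <- new.env()
bench_split <- function() {
  if (is.null(bench_env$data)) {
    set <- easy_benchmark(seed = 1)
    X <- spectra_matrix(set)
    y <- droplevels(maturity_labels(set))
    pl <- fit_pipeline(default_pipeline(), X)
    Xp <- apply_pipeline(pl, X)
    sp <- split_dataset(set, 0.7, X = Xp)
    bench_env$data <- list(
      set = set, y = y, Xp = Xp, split = sp,
      x_tr = Xp[sp$train_indices, ], y_tr = y[sp$train_indices],
      x_te = Xp[sp$test_indices, ], y_te = y[sp$test_indices])
  }
  bench_env$data
}

# Small architecture used wherever the full 128/64-filter network would be
# needlessly slow.
small_arch <- function(input_length, n_classes = 5, kernel = 3) {
  cnn_architecture(input_length = input_length, n_classes = n_classes,
                   blocks = list(
                     conv_block(8, kernel, pool_size = 2, pool_stride = 2),
                     conv_block(4, kernel, pool_size = 1, pool_stride = 1)),
                   dense_units = 16)
}
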