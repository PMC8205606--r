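test_that("pure spectra are Gaussian band sums on the grid", {
  g <- make_grid(900, 2500, 5)
  cfg <- synth_config(grid = g, positions = "upper",
                      bands = list(band_spec(1500, 80, 0.5)),
                      n_per_class = 1, seed = 1)
  s <- pure_spectrum(cfg, "upper", "ripe")
  wl <- wavelengths(g)
  expect_equal(wl[which.max(s)], 1500)
  expect_equal(max(s), 0.5, tolerance = 1e-6)

  cfg0 <- synth_config(grid = g, positions = "upper", bands = list(),
                       n_per_class = 1)
  expect_equal(pure_spectrum(cfg0, "upper", "ripe"), rep(0, g$n_points))
})

test_that("a pure centre shift translates the spectrum by the shift lag", {
  g <- make_grid(900, 2500, 5)
  # levels 1 and 2 differ only by a 15 nm (3-point) centre shift
  b <- band_spec(1500, 60, 0.5, maturity_shift_nm = c(0, 15, 0, 0, 0))
  cfg <- synth_config(grid = g, positions = "upper", bands = list(b),
                      n_per_class = 1)
  s1 <- pure_spectrum(cfg, "upper", "unripe")
  s2 <- pure_spectrum(cfg, "upper", "mature")
  # cross-correlation oracle: the best alignment lag equals the shift
  n <- g$n_points
  lags <- -10:10
  cc <- sapply(lags, function(l) {
    if (l >= 0) sum(s1[1:(n - l)] * s2[(1 + l):n])
    else sum(s1[(1 - l):n] * s2[1:(n + l)])
  })
  expect_equal(lags[which.max(cc)], 3)
})

test_that("simulated datasets honour counts, seeds, and the noise-free limit", {
  g <- make_grid(900, 2500, 50)
  cfg <- synth_config(grid = g, positions = c("upper", "lower"),
                      n_per_class = 3, n_spots = 2, seed = 5)
  set1 <- simulate_dataset(cfg)
  set2 <- simulate_dataset(cfg)
  expect_identical(spectra_matrix(set1), spectra_matrix(set2))
  counts <- table(position_labels(set1), maturity_labels(set1))
  expect_true(all(counts[c("upper", "lower"), ] == 3))
  expect_identical(length(set1), 2L * 5L * 3L)

  # all randomness off: every spot equals the class's pure spectrum
  cfg0 <- synth_config(grid = g, positions = "upper", n_per_class = 2,
                       n_spots = 3, scatter_mult_range = c(1, 1),
                       scatter_add_sd = 0, baseline_slope_sd = 0,
                       noise_sd = 0, seed = 1)
  set0 <- simulate_dataset(cfg0)
  for (r in set0$records) {
    pure <- pure_spectrum(cfg0, r$position, r$maturity)
    expect_equal(max(abs(sweep(r$spot_spectra, 2, pure))), 0)
  }
})

test_that("per-point spot variance matches the generative closed form", {
  g <- make_grid(900, 2500, 25)
  cfg <- synth_config(grid = g, positions = "upper", n_per_class = 300,
                      n_spots = 4, scatter_mult_range = c(0.8, 1.2),
                      scatter_add_sd = 0.04, baseline_slope_sd = 0.03,
                      noise_sd = 0.01, seed = 8)
  set <- simulate_dataset(cfg)
  ripe <- set[maturity_labels(set) == "ripe"]
  spots <- do.call(rbind, lapply(ripe$records, `[[`, "spot_spectra"))
  emp <- apply(spots, 2, var)

  pure <- pure_spectrum(cfg, "upper", "ripe")
  wl <- wavelengths(g)
  s01 <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
  theo <- (0.4^2 / 12) * pure^2 + 0.04^2 + 0.03^2 * s01^2 + 0.01^2
  expect_equal(mean(emp / theo), 1, tolerance = 0.05)
  expect_lt(max(abs(emp / theo - 1)), 0.25)
})

test_that("SNV exactly removes multiplicative/additive scatter at zero noise", {
  g <- make_grid(900, 2500, 12.5)
  cfg <- synth_config(grid = g, positions = "upper", n_per_class = 8,
                      n_spots = 1, scatter_mult_range = c(0.7, 1.3),
                      scatter_add_sd = 0.1, baseline_slope_sd = 0,
                      noise_sd = 0, seed = 2)
  set <- simulate_dataset(cfg)
  X <- spectra_matrix(set)
  Z <- snv(X)
  for (lvl in maturity_levels()) {
    rows <- Z[maturity_labels(set) == lvl, ]
    expect_lt(max(dist(rows)), 1e-6)
  }
})

test_that("MSC with the true pure spectrum as reference recovers it", {
  g <- make_grid(900, 2500, 12.5)
  cfg <- synth_config(grid = g, positions = "upper", n_per_class = 6,
                      n_spots = 1, scatter_mult_range = c(0.7, 1.3),
                      scatter_add_sd = 0.1, baseline_slope_sd = 0,
                      noise_sd = 0, seed = 3)
  set <- simulate_dataset(cfg)
  for (lvl in c("unripe", "overmature")) {
    pure <- pure_spectrum(cfg, "upper", lvl)
    X <- spectra_matrix(set)[maturity_labels(set) == lvl, ]
    Z <- msc_apply(X, pure)
    expect_lt(max(abs(sweep(Z, 2, pure))), 1e-8)
  }
})

test_that("easy_benchmark is deterministic, complete, and well separated", {
  b1 <- easy_benchmark(seed = 4, n_per_class = 4)
  b2 <- easy_benchmark(seed = 4, n_per_class = 4)
  expect_identical(spectra_matrix(b1), spectra_matrix(b2))
  expect_setequal(as.character(unique(maturity_labels(b1))),
                  maturity_levels())

  bench <- easy_benchmark(seed = 1, n_per_class = 12)
  Z <- snv(spectra_matrix(bench))
  y <- maturity_labels(bench)
  centroids <- t(sapply(maturity_levels(), function(l) colMeans(Z[y == l, ])))
  spread <- mean(sapply(maturity_levels(), function(l) {
    mean(sqrt(rowSums(sweep(Z[y == l, ], 2, centroids[l, ])^2)))
  }))
  centroid_d <- dist(centroids)
  expect_gt(min(centroid_d), 10 * spread)
})
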