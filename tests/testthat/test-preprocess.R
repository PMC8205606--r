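test_that("Savitzky-Golay filtering is exact on polynomials", {
  wl <- seq(900, 2500, by = 3.125)[1:512]

  d1 <- sg_filter(matrix(rep(5, 512), 1), 59, 2, deriv = 1,
                  mode = "valid", step_nm = 3.125)
  expect_equal(max(abs(d1)), 0)

  lin <- sg_filter(matrix(2 * wl, 1), 59, 2, deriv = 1,
                   mode = "valid", step_nm = 3.125)
  expect_equal(unname(drop(lin)), rep(2, 454), tolerance = 1e-8)

  # analytic second derivative of lambda^2 is the constant 2
  quad <- sg_filter(matrix(wl^2, 1), 31, 3, deriv = 2,
                    mode = "valid", step_nm = 3.125)
  expect_equal(unname(drop(quad)), rep(2, 512 - 30), tolerance = 1e-6)
})

test_that("sg_filter matches signal::sgolayfilt in same mode", {
  withr::with_seed(11, {
    v <- rnorm(100)
    for (cfg in list(c(7, 2, 0), c(9, 3, 1), c(11, 4, 2))) {
      mine <- sg_filter(matrix(v, 1), cfg[1], cfg[2], deriv = cfg[3])
      ref <- signal::sgolayfilt(v, p = cfg[2], n = cfg[1], m = cfg[3], ts = 1)
      expect_equal(unname(drop(mine)), ref, tolerance = 1e-10)
    }
  })
})

test_that("sg_filter validates its window contract", {
  X <- matrix(rnorm(40), 2)
  expect_error(sg_filter(X, 6, 2), "odd")
  expect_error(sg_filter(X, 31, 2), "exceeds spectrum length")
  expect_error(sg_filter(X, 5, 5), "polyorder")
  # deriv 0 with polyorder = window - 1 interpolates: identity on interior
  id <- sg_filter(X, 5, 4, deriv = 0, mode = "valid")
  expect_equal(id, X[, 3:18], tolerance = 1e-8)
})

test_that("SNV centres and scales each spectrum", {
  expect_equal(drop(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))

  withr::with_seed(2, {
    X <- matrix(rnorm(60), 5)
    Z <- snv(X)
    expect_equal(rowMeans(Z), rep(0, 5), tolerance = 1e-10)
    expect_equal(apply(Z, 1, sd), rep(1, 5), tolerance = 1e-10)
    # affine invariance: snv(a + b x) = snv(x) for b > 0
    expect_equal(snv(3.2 + 1.7 * X), Z, tolerance = 1e-10)
  })
  expect_error(snv(matrix(1, 2, 5)), "row 1")
})

test_that("MSC reproduces an explicit normal-equations fit", {
  withr::with_seed(5, {
    X <- matrix(rnorm(100, mean = 2), 5, 20)
    fit <- msc_fit(X)
    expect_equal(fit$reference_spectrum, colMeans(X))
    Z <- msc_apply(X, fit)
    ref <- fit$reference_spectrum
    for (i in 1:5) {
      cf <- solve(crossprod(cbind(1, ref)), crossprod(cbind(1, ref), X[i, ]))
      expect_equal(Z[i, ], (X[i, ] - cf[1]) / cf[2], tolerance = 1e-10)
    }
  })
})

test_that("MSC inverts exact affine scatter and fixes its reference", {
  ref <- sin(seq(0, 3, length.out = 30)) + 2
  ab <- cbind(runif(6, -1, 1), runif(6, 0.5, 2))
  X <- sweep(outer(ab[, 2], ref), 1, ab[, 1], "+")
  Z <- msc_apply(X, ref)
  expect_lt(max(abs(sweep(Z, 2, ref))), 1e-9)
  expect_equal(drop(msc_apply(matrix(ref, 1), ref)), ref, tolerance = 1e-12)
  expect_error(msc_apply(matrix(rep(1, 30), 1) * 0 + 5, ref), "slope")
})

test_that("min-max normalisation maps rows onto [0, 1] idempotently", {
  expect_equal(drop(minmax_norm(matrix(c(2, 4, 6), 1))), c(0, 0.5, 1))
  withr::with_seed(8, {
    X <- matrix(rnorm(80), 4)
    Z <- minmax_norm(X)
    expect_equal(apply(Z, 1, min), rep(0, 4))
    expect_equal(apply(Z, 1, max), rep(1, 4))
    expect_equal(minmax_norm(Z), Z)
  })
  expect_error(minmax_norm(matrix(1, 1, 4)), "constant")
})

test_that("pipelines compose, shrink width as declared, and label failures", {
  withr::with_seed(4, {
    X <- matrix(rnorm(5 * 512, mean = 3), 5)
    # empty pipeline is the identity
    expect_equal(apply_pipeline(preprocess_pipeline(), X), X)

    # default pipeline: 512 -> 454 columns, the CNN input width
    out <- apply_pipeline(default_pipeline(), X)
    expect_identical(ncol(out), 454L)
    expect_identical(nrow(out), 5L)

    Z <- apply_pipeline(preprocess_pipeline(pp_step("snv"),
                                            pp_step("minmax_norm")), X)
    expect_true(all(Z >= 0 & Z <= 1))

    # msc before fitting is an error naming the step
    pl <- preprocess_pipeline(pp_step("msc"))
    expect_error(apply_pipeline(pl, X), "step 1 \\(msc\\)")
    pl <- fit_pipeline(pl, X)
    expect_equal(dim(apply_pipeline(pl, X)), dim(X))
  })
})

test_that("row permutation commutes with every operator", {
  withr::with_seed(13, {
    X <- matrix(rnorm(8 * 60, mean = 2), 8)
    perm <- sample(8)
    ops <- list(function(m) snv(m),
                function(m) minmax_norm(m),
                function(m) sg_filter(m, 9, 2, deriv = 1, mode = "valid"),
                function(m) msc_apply(m, colMeans(X)))
    for (op in ops) expect_equal(op(X[perm, ]), op(X)[perm, ])
  })
})

test_that("pipeline configs round-trip through flat key-value form", {
  pl <- default_pipeline()
  cfg <- pipeline_to_config(pl)
  expect_identical(cfg$steps, "sg_derivative,minmax_norm")
  pl2 <- pipeline_from_config(cfg)
  X <- matrix(rnorm(2 * 512), 2)
  expect_equal(apply_pipeline(pl2, X), apply_pipeline(pl, X))
})

test_that("PCA scores explain variance as the covariance eigenvalues do", {
  withr::with_seed(21, {
    # rank-1 data: first component carries everything
    v <- rnorm(12)
    X1 <- outer(rnorm(30), v)
    p1 <- pca_scores(X1, 2)
    expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-9)

    # isotropic 2-D Gaussian: ratios near (0.5, 0.5)
    X2 <- matrix(rnorm(4000), 2000, 2)
    p2 <- pca_scores(X2, 2)
    expect_equal(p2$explained_variance_ratio, c(0.5, 0.5), tolerance = 0.06)
    expect_true(all(diff(p2$explained_variance_ratio) <= 0))

    # full reconstruction equals the centred data
    X3 <- matrix(rnorm(15 * 6), 15)
    pc <- prcomp(X3, center = TRUE, scale. = FALSE)
    rec <- pc$x %*% t(pc$rotation)
    expect_equal(rec, scale(X3, scale = FALSE), tolerance = 1e-8,
                 ignore_attr = TRUE)

    expect_error(pca_scores(X3, 10), "n_components")
  })
})
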