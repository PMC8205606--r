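test_that("layer shapes follow the conv/pool length formulas", {
  sh <- cnn_output_shapes(cnn_architecture())
  expect_equal(sh$length[sh$layer == "conv1"], 450)
  expect_equal(sh$length[sh$layer == "pool1"], 225)
  expect_equal(sh$length[sh$layer == "conv2"], 221)
  expect_equal(sh$length[sh$layer == "pool2"], 221)
  expect_equal(sh$width[sh$layer == "flatten"], 14144)

  # kernel-13 configuration, worked through the length formula by hand:
  # 454-13+1 = 442; pool 221; 221-13+1 = 209; flatten 209*64 = 13376
  sh13 <- cnn_output_shapes(cnn_architecture(kernel_size = 13))
  expect_equal(sh13$length[sh13$layer == "conv1"], 442)
  expect_equal(sh13$length[sh13$layer == "conv2"], 209)
  expect_equal(sh13$width[sh13$layer == "flatten"], 13376)

  # boundary: kernel spanning the whole input leaves a single position
  shb <- cnn_output_shapes(cnn_architecture(
    blocks = list(conv_block(4, 454, pool_size = 1, pool_stride = 1))))
  expect_equal(shb$length[shb$layer == "conv1"], 1)

  expect_error(cnn_architecture(input_length = 10,
                                blocks = list(conv_block(4, 21))),
               "conv block 1")
})

test_that("symbolic shapes agree with runtime tensors on random architectures", {
  withr::with_seed(55, {
    for (trial in 1:20) {
      L <- sample(30:80, 1)
      k1 <- sample(seq(3, 9, 2), 1)
      k2 <- sample(c(3, 5), 1)
      arch <- try(cnn_architecture(
        input_length = L, n_classes = sample(2:5, 1),
        blocks = list(
          conv_block(sample(2:6, 1), k1, pool_size = sample(1:3, 1)),
          conv_block(sample(2:6, 1), k2, pool_size = 1, pool_stride = 1)),
        dense_units = sample(4:12, 1),
        global_max_pool = sample(c(TRUE, FALSE), 1)), silent = TRUE)
      if (inherits(arch, "try-error")) next  # lengths underflowed; rejected
      sym <- cnn_output_shapes(arch)
      run <- cnn_runtime_shapes(arch, n = 3, seed = trial)
      expect_identical(run$length, sym$length)
      expect_identical(run$channels, sym$channels)
    }
  })
})

test_that("the CNN backward pass matches numerical gradients", {
  arch <- cnn_architecture(input_length = 20, n_classes = 3, blocks = list(
    conv_block(4, 3, pool_size = 2, pool_stride = 2),
    conv_block(3, 3, pool_size = 1, pool_stride = 1)), dense_units = 6)
  withr::with_seed(9, {
    X <- matrix(rnorm(5 * 20), 5, 20)
    Y <- nirleaf:::one_hot(factor(c(1, 2, 3, 1, 2)))
  })
  params <- withr::with_seed(4, nirleaf:::cnn_init_params(arch))
  lossfun <- function(p) {
    fw <- nirleaf:::cnn_forward(p, arch, X, training = TRUE)
    -mean(log(fw$probs[cbind(1:5, max.col(Y))]))
  }
  fw <- nirleaf:::cnn_forward(params, arch, X, training = TRUE)
  gr <- nirleaf:::cnn_backward(params, arch, fw, Y)
  gl <- nirleaf:::param_leaves(gr, arch)
  pl <- nirleaf:::param_leaves(params, arch)
  # conv biases are cancelled by batch norm (true gradient ~ 0); check the
  # informative leaves against central differences
  for (nm in c("blocks.1.W", "blocks.1.gamma", "blocks.1.beta",
               "blocks.2.W", "Wd1", "bd1", "Wd2", "bd2")) {
    for (idx in seq_len(min(length(pl[[nm]]), 3))) {
      eps <- 1e-5
      up <- nirleaf:::set_leaf(params, nm, replace(pl[[nm]], idx, pl[[nm]][idx] + eps))
      dn <- nirleaf:::set_leaf(params, nm, replace(pl[[nm]], idx, pl[[nm]][idx] - eps))
      gnum <- (lossfun(up) - lossfun(dn)) / (2 * eps)
      expect_equal(unname(gl[[nm]][idx]), gnum, tolerance = 1e-4)
    }
  }
})

test_that("softmax probabilities are proper and training is seed-reproducible", {
  withr::with_seed(29, {
    x <- matrix(rnorm(30 * 16), 30, 16)
    y <- factor(sample(c("a", "b", "c"), 30, TRUE))
  })
  arch <- small_arch(16, n_classes = 3)
  fit <- cnn(x, y, architecture = arch,
             control = cnn_control(epochs = 3, batch_size = 10, seed = 2))
  p <- predict(fit, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-6)
  expect_true(all(p >= 0))

  fit2 <- cnn(x, y, architecture = arch,
              control = cnn_control(epochs = 3, batch_size = 10, seed = 2))
  expect_identical(predict(fit, x), predict(fit2, x))
  expect_identical(fit$loss, fit2$loss)
})

test_that("the CNN fits a linearly separable two-class fixture perfectly", {
  # classes differ by a mean shift, so a linear model already separates them
  withr::with_seed(61, {
    x <- rbind(matrix(rnorm(25 * 24, 0, 0.5), 25, 24),
               matrix(rnorm(25 * 24, 2, 0.5), 25, 24))
    y <- factor(rep(c("lo", "hi"), each = 25))
  })
  fit <- cnn(x, y, architecture = small_arch(24, n_classes = 2),
             control = cnn_control(epochs = 50, batch_size = 16, seed = 1))
  expect_equal(evaluate_model(fit, x, y)$ner, 100)
})

test_that("the CNN surfaces contract violations", {
  x <- matrix(rnorm(10 * 12), 10, 12)
  y <- factor(rep(c("a", "b"), each = 5))
  expect_error(cnn(x, y, architecture = small_arch(20, n_classes = 2)),
               "12 columns")
  expect_error(cnn(x, factor(rep("a", 10), levels = c("a", "b")),
                   architecture = small_arch(12, n_classes = 2)),
               "class")
})
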