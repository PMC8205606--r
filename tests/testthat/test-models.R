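test_that("ELM interpolates distinct rows once capacity reaches n_train", {
  withr::with_seed(31, {
    x <- matrix(rnorm(20 * 5), 20, 5)
    y <- factor(sample(letters[1:3], 20, TRUE))
    fit <- elm(x, y, n_hidden = 25, seed = 1)
    expect_equal(mean(predict(fit, x) == y), 1)
    # pseudo-inverse solution reproduces the one-hot targets exactly
    H <- nirleaf:::sigmoid(x %*% fit$W + matrix(fit$b, 20, 25, byrow = TRUE))
    expect_equal(H %*% fit$beta, nirleaf:::one_hot(y), tolerance = 1e-6,
                 ignore_attr = TRUE)
  })
})

test_that("ELM cannot fit duplicate rows with conflicting labels", {
  x <- matrix(rep(c(0, 1), each = 8), 8, 2)
  y <- factor(c("a", "b", "a", "b", "a", "b", "a", "b"))
  fit <- elm(x, y, n_hidden = 20, seed = 2)
  expect_lt(mean(predict(fit, x) == y), 1)
})

test_that("ELM is seed-reproducible and monotone in capacity", {
  withr::with_seed(17, {
    x <- matrix(rnorm(40 * 6), 40, 6)
    y <- factor(sample(letters[1:3], 40, TRUE))
  })
  f1 <- elm(x, y, n_hidden = 30, seed = 5)
  f2 <- elm(x, y, n_hidden = 30, seed = 5)
  expect_identical(f1$beta, f2$beta)

  sse <- sapply(c(2, 5, 10, 20, 40), function(h) {
    f <- elm(x, y, n_hidden = h, seed = 9)
    H <- nirleaf:::sigmoid(x %*% f$W + matrix(f$b, 40, h, byrow = TRUE))
    sum((H %*% f$beta - nirleaf:::one_hot(y))^2)
  })
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("KNN weights neighbours by inverse distance", {
  # query at 0; neighbours at distances 1, 1, 2 labelled A, A, B
  x <- matrix(c(-1, 1, 2), ncol = 1)
  y <- factor(c("A", "A", "B"))
  fit <- knn_classifier(x, y, k = 3)
  expect_identical(as.character(predict(fit, matrix(0))), "A")

  # an exact-match neighbour dominates at k = 1
  fit1 <- knn_classifier(x, y, k = 1)
  expect_identical(as.character(predict(fit1, matrix(2))), "B")

  # unanimous neighbourhoods win regardless of distance
  xx <- matrix(c(1, 2, 3, 50), ncol = 1)
  fit2 <- knn_classifier(xx, factor(c("A", "A", "A", "B")), k = 3)
  expect_identical(as.character(predict(fit2, matrix(0))), "A")

  expect_error(knn_classifier(x, y, k = 9), "k must be")
})

test_that("KNN supports the Mahalanobis metric when covariance permits", {
  withr::with_seed(23, {
    x <- matrix(rnorm(60 * 2), 60, 2) %*% matrix(c(3, 1, 1, 1), 2)
    y <- factor(rep(c("A", "B"), each = 30))
    x[y == "B", 1] <- x[y == "B", 1] + 6
    fit <- knn_classifier(x, y, k = 5, metric = "mahalanobis")
    expect_gt(mean(predict(fit, x) == y), 0.9)
    # singular covariance is refused
    xs <- cbind(x[, 1], x[, 1])
    expect_error(knn_classifier(xs, y, metric = "mahalanobis"), "singular")
  })
})

test_that("BPNN solves XOR and honours the zero-epoch contract", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- factor(c("off", "on", "on", "off"))
  fit <- bpnn(x, y, n_hidden = 8, learning_rate = 0.5, epochs = 5000, seed = 3)
  expect_equal(mean(predict(fit, x) == y), 1)

  f0a <- bpnn(x, y, n_hidden = 4, epochs = 0, seed = 11)
  f0b <- bpnn(x, y, n_hidden = 4, epochs = 0, seed = 11)
  expect_identical(f0a$W1, f0b$W1)
  expect_identical(predict(f0a, x), predict(f0b, x))
  expect_length(f0a$loss, 0)
})

test_that("BPNN loss is non-increasing for a small step on separable data", {
  withr::with_seed(6, {
    x <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
               matrix(rnorm(30, 3, 0.3), 15, 2))
    y <- factor(rep(c("a", "b"), each = 15))
  })
  fit <- bpnn(x, y, n_hidden = 6, learning_rate = 0.01, epochs = 300, seed = 4)
  expect_true(all(diff(fit$loss) <= 1e-10))
})

test_that("RBF SVM separates clustered classes and accepts grid parameters", {
  withr::with_seed(12, {
    x <- rbind(matrix(rnorm(40, 0, 0.4), 20, 2),
               matrix(rnorm(40, 4, 0.4), 20, 2))
    y <- factor(rep(c("a", "b"), each = 20))
  })
  # parameters from the power-of-two search grid (2^5, 2^-5)
  fit <- svm_rbf(x, y, cost = 32, gamma = 0.0313)
  expect_equal(mean(predict(fit, x) == y), 1)
  fit2 <- svm_rbf(x, y, cost = 8, gamma = 0.0625)
  expect_equal(mean(predict(fit2, x) == y), 1)
  expect_error(svm_rbf(x, y, cost = -1), "positive")
})

test_that("train_classifier dispatches all five models interchangeably", {
  withr::with_seed(44, {
    x <- rbind(matrix(rnorm(160, 0, 0.5), 20, 8),
               matrix(rnorm(160, 3, 0.5), 20, 8))
    y <- factor(rep(c("a", "b"), each = 20))
  })
  args <- list(knn = list(k = 3),
               svm = list(cost = 10, gamma = 0.1),
               elm = list(n_hidden = 40, seed = 1),
               bpnn = list(n_hidden = 8, learning_rate = 0.5,
                           epochs = 400, seed = 1),
               cnn = list(architecture = small_arch(8, n_classes = 2),
                          control = cnn_control(epochs = 30, batch_size = 16,
                                                seed = 1)))
  for (m in names(args)) {
    fit <- do.call(train_classifier, c(list(method = m, x = x, y = y),
                                       args[[m]]))
    expect_s3_class(fit, "nir_model")
    res <- evaluate_model(fit, x, y)
    expect_gte(res$ner, 95)
  }
})
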