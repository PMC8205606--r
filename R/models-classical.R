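# The four classical baselines.  Every classifier follows one contract:
# a fitting function taking (x, y, ...) where x is the preprocessed spectra
# matrix and y a factor of class labels, returning a classed object with a
# predict() method that maps a matrix of new rows to a factor of labels.

#' Extreme learning machine classifier
#'
#' A single-hidden-layer feedforward network whose input weights and
#' hidden biases are drawn at random (seeded uniform on (-1, 1)) and never
#' trained; the output weights are the minimum-norm least-squares solution
#' obtained from the Moore-Penrose pseudo-inverse of the hidden-layer
#' output matrix against the one-hot class targets.  Prediction is the
#' argmax of the hidden activations times the output weights.
#'
#' @param x numeric matrix of training spectra (rows = samples).
#' @param y factor (or coercible) of class labels.
#' @param n_hidden number of hidden neurons (>= 1).
#' @param seed integer seed for the random input weights.
#' @return object of class `c("elm", "nir_model")`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- factor(rep(c("a", "b"), each = 10))
#' fit <- elm(x, y, n_hidden = 25, seed = 1)
#' predict(fit, x)
#' @export
elm <- function(x, y, n_hidden = 150, seed = 1) {
  y <- droplevels(as.factor(y))
  check(is.matrix(x) && nrow(x) == length(y), "x rows must match length(y)")
  check(n_hidden >= 1, "n_hidden must be >= 1")
  p <- ncol(x)
  # neurons are drawn one at a time (weights then bias) so that for a fixed
  # seed the first h neurons are identical for every n_hidden >= h; hidden
  # features are therefore nested and the least-squares training error is
  # non-increasing in capacity
  wb <- with_seed(seed, {
    W <- matrix(0, p, n_hidden)
    b <- numeric(n_hidden)
    for (j in seq_len(n_hidden)) {
      W[, j] <- stats::runif(p, -1, 1)
      b[j] <- stats::runif(1, -1, 1)
    }
    list(W = W, b = b)
  })
  H <- sigmoid(x %*% wb$W + matrix(wb$b, nrow(x), n_hidden, byrow = TRUE))
  beta <- MASS::ginv(H) %*% one_hot(y)
  structure(list(W = wb$W, b = wb$b, beta = beta, levels = levels(y),
                 n_hidden = n_hidden, seed = seed),
            class = c("elm", "nir_model"))
}

#' @param object fitted `elm` model.
#' @param newdata matrix of spectra to classify.
#' @param type `"class"` for labels, `"score"` for the raw output matrix.
#' @param ... unused.
#' @rdname elm
#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  H <- sigmoid(newdata %*% object$W +
                 matrix(object$b, nrow(newdata), object$n_hidden, byrow = TRUE))
  S <- H %*% object$beta
  if (type == "score") return(S)
  factor(object$levels[max.col(S, ties.method = "first")],
         levels = object$levels)
}

#' Inverse-distance-weighted k-nearest-neighbour classifier
#'
#' Lazy learner: prediction computes Euclidean or Mahalanobis distances
#' from each query to the training rows, takes the k nearest, and scores
#' each class by the sum of inverse distances `1 / (d + eps)` of its
#' neighbours (`eps = 1e-12` guards exact matches, which therefore
#' dominate).  The highest-scoring class wins.
#'
#' @param x training spectra matrix.
#' @param y factor of class labels.
#' @param k number of neighbours, `1 <= k <= nrow(x)`.
#' @param metric `"euclidean"` or `"mahalanobis"` (training covariance
#'   must be invertible).
#' @return object of class `c("knn_classifier", "nir_model")`.
#' @export
knn_classifier <- function(x, y, k = 5, metric = c("euclidean", "mahalanobis")) {
  metric <- match.arg(metric)
  y <- droplevels(as.factor(y))
  check(is.matrix(x) && nrow(x) == length(y), "x rows must match length(y)")
  check(k >= 1 && k <= nrow(x), "k must be in 1..n_train (%d), got %d", nrow(x), k)
  Sinv <- NULL
  if (metric == "mahalanobis") {
    S <- stats::cov(x)
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("training covariance is singular; Mahalanobis metric unavailable",
           call. = FALSE))
  }
  structure(list(x = x, y = y, k = k, metric = metric, Sinv = Sinv,
                 levels = levels(y)),
            class = c("knn_classifier", "nir_model"))
}

#' @param object fitted `knn_classifier`.
#' @param newdata matrix of query spectra.
#' @param ... unused.
#' @rdname knn_classifier
#' @export
predict.knn_classifier <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  d2 <- if (object$metric == "euclidean") {
    cross_dist2(newdata, object$x)
  } else {
    Z <- newdata %*% object$Sinv
    W <- object$x %*% object$Sinv
    outer(rowSums(Z * newdata), rowSums(W * object$x), "+") -
      2 * tcrossprod(Z, object$x)
  }
  d <- sqrt(pmax(d2, 0))
  yi <- as.integer(object$y)
  G <- length(object$levels)
  out <- integer(nrow(newdata))
  for (q in seq_len(nrow(newdata))) {
    ord <- order(d[q, ])[seq_len(object$k)]
    w <- 1 / (d[q, ord] + 1e-12)
    scores <- vapply(seq_len(G), function(g) sum(w[yi[ord] == g]), 0)
    out[q] <- which.max(scores)
  }
  factor(object$levels[out], levels = object$levels)
}

#' Backpropagation neural network (single hidden layer)
#'
#' A classic multilayer perceptron: one sigmoid hidden layer and a sigmoid
#' output layer, trained by full-batch gradient descent on the squared
#' error against one-hot targets.  Weights are initialised from a seeded
#' uniform distribution; with `epochs = 0` the model predicts from its
#' initial weights (useful as a determinism contract).
#'
#' @param x training spectra matrix.
#' @param y factor of class labels.
#' @param n_hidden hidden-layer width (>= 1).
#' @param learning_rate gradient-descent step size (default 1e-4).
#' @param epochs number of full-batch gradient steps.
#' @param seed integer seed for weight initialisation.
#' @return object of class `c("bpnn", "nir_model")` with the per-epoch
#'   loss trace in `$loss`.
#' @export
bpnn <- function(x, y, n_hidden = 20, learning_rate = 1e-4,
                 epochs = 500, seed = 1) {
  y <- droplevels(as.factor(y))
  check(is.matrix(x) && nrow(x) == length(y), "x rows must match length(y)")
  check(n_hidden >= 1, "n_hidden must be >= 1")
  check(epochs >= 0, "epochs must be >= 0")
  p <- ncol(x); G <- nlevels(y); n <- nrow(x)
  Y <- one_hot(y)
  init <- with_seed(seed, list(
    W1 = matrix(stats::runif(p * n_hidden, -0.5, 0.5), p, n_hidden) / sqrt(p),
    b1 = stats::runif(n_hidden, -0.1, 0.1),
    W2 = matrix(stats::runif(n_hidden * G, -0.5, 0.5), n_hidden, G) / sqrt(n_hidden),
    b2 = stats::runif(G, -0.1, 0.1)))
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    H <- sigmoid(x %*% W1 + matrix(b1, n, n_hidden, byrow = TRUE))
    O <- sigmoid(H %*% W2 + matrix(b2, n, G, byrow = TRUE))
    err <- O - Y
    loss[e] <- mean(err^2)
    if (!is.finite(loss[e]))
      stop("bpnn training diverged (non-finite loss); lower the learning rate",
           call. = FALSE)
    dO <- 2 * err * O * (1 - O) / n
    dW2 <- crossprod(H, dO);      db2 <- colSums(dO)
    dH <- (dO %*% t(W2)) * H * (1 - H)
    dW1 <- crossprod(x, dH);      db1 <- colSums(dH)
    W2 <- W2 - learning_rate * dW2; b2 <- b2 - learning_rate * db2
    W1 <- W1 - learning_rate * dW1; b1 <- b1 - learning_rate * db1
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = levels(y),
                 loss = loss, n_hidden = n_hidden,
                 learning_rate = learning_rate, epochs = epochs, seed = seed),
            class = c("bpnn", "nir_model"))
}

#' @param object fitted `bpnn` model.
#' @param newdata matrix of spectra to classify.
#' @param type `"class"` or `"score"` (sigmoid outputs).
#' @param ... unused.
#' @rdname bpnn
#' @export
predict.bpnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  H <- sigmoid(newdata %*% object$W1 +
                 matrix(object$b1, nrow(newdata), object$n_hidden, byrow = TRUE))
  O <- sigmoid(H %*% object$W2 +
                 matrix(object$b2, nrow(newdata), length(object$levels), byrow = TRUE))
  if (type == "score") return(O)
  factor(object$levels[max.col(O, ties.method = "first")],
         levels = object$levels)
}

#' RBF soft-margin support vector machine
#'
#' Multiclass (one-vs-one) C-classification with a radial basis kernel,
#' delegated to the libsvm solver in \pkg{e1071}; this baseline's contract
#' is the decision rule, not the optimiser.
#'
#' @param x training spectra matrix.
#' @param y factor of class labels.
#' @param cost penalty parameter C (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return object of class `c("svm_rbf", "nir_model")`.
#' @export
svm_rbf <- function(x, y, cost = 32, gamma = 1 / ncol(x)) {
  y <- droplevels(as.factor(y))
  check(cost > 0 && gamma > 0, "cost and gamma must be positive")
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, levels = levels(y), cost = cost, gamma = gamma),
            class = c("svm_rbf", "nir_model"))
}

#' @param object fitted `svm_rbf` model.
#' @param newdata matrix of spectra to classify.
#' @param ... unused.
#' @rdname svm_rbf
#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  factor(as.character(stats::predict(object$fit, newdata)),
         levels = object$levels)
}

#' @export
print.nir_model <- function(x, ...) {
  cat(sprintf("<%s> classes: %s\n", class(x)[1],
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Train any of the five classifiers through one interface
#'
#' Dispatcher used by the evaluation harness: all five models share the
#' train/predict contract and are interchangeable.
#'
#' @param method one of `"knn"`, `"bpnn"`, `"svm"`, `"elm"`, `"cnn"`.
#' @param x training spectra matrix.
#' @param y factor of class labels.
#' @param ... passed to the model's fitting function.
#' @return a fitted `nir_model`.
#' @export
train_classifier <- function(method = c("knn", "bpnn", "svm", "elm", "cnn"),
                             x, y, ...) {
  method <- match.arg(method)
  switch(method,
         knn = knn_classifier(x, y, ...),
         bpnn = bpnn(x, y, ...),
         svm = svm_rbf(x, y, ...),
         elm = elm(x, y, ...),
         cnn = cnn(x, y, ...))
}
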