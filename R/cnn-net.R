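# The 1D convolutional network: parameter initialisation, forward and
# backward passes, Adam training, prediction.  Convolutions are computed
# as im2col patch-matrix products so the heavy lifting is dense BLAS.
#
# Activation tensors are (n, length, channels) arrays; the im2col patch
# matrix has one row per (sample, output position) and one column per
# (kernel offset, input channel), offset-major.

im2col <- function(A, k, s) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  Lo <- conv_out_len(L, k, s)
  P <- matrix(0, n * Lo, k * C)
  for (i in seq_len(k)) {
    idx <- seq(i, by = s, length.out = Lo)
    block <- A[, idx, , drop = FALSE]
    dim(block) <- c(n * Lo, C)
    P[, ((i - 1) * C + 1):(i * C)] <- block
  }
  P
}

col2im <- function(dP, n, L, C, k, s) {
  Lo <- conv_out_len(L, k, s)
  dA <- array(0, c(n, L, C))
  for (i in seq_len(k)) {
    idx <- seq(i, by = s, length.out = Lo)
    block <- dP[, ((i - 1) * C + 1):(i * C), drop = FALSE]
    dim(block) <- c(n, Lo, C)
    dA[, idx, ] <- dA[, idx, , drop = FALSE] + block
  }
  dA
}

# max pool with argmax bookkeeping; A is (n, L, C)
pool_forward <- function(A, q, s, beta = 1, bias = 0) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  Lo <- pool_out_len(L, q, s)
  best <- array(-Inf, c(n, Lo, C))
  argj <- array(1L, c(n, Lo, C))
  for (j in seq_len(q)) {
    idx <- seq(j, by = s, length.out = Lo)
    cand <- A[, idx, , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    argj[upd] <- j
  }
  list(out = beta * best + bias, argj = argj, L_in = L)
}

pool_backward <- function(dOut, cache, q, s, beta = 1) {
  d <- dim(dOut); n <- d[1]; Lo <- d[2]; C <- d[3]
  dA <- array(0, c(n, cache$L_in, C))
  for (j in seq_len(q)) {
    idx <- seq(j, by = s, length.out = Lo)
    contrib <- dOut * beta * (cache$argj == j)
    dA[, idx, ] <- dA[, idx, , drop = FALSE] + contrib
  }
  dA
}

xavier_normal <- function(nr, nc, fan_in, fan_out) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (fan_in + fan_out))), nr, nc)
}

# Allocate all trainable parameters and batch-norm state (seed must be set
# by the caller).
cnn_init_params <- function(arch) {
  shapes <- cnn_output_shapes(arch)
  params <- list(blocks = list())
  C_in <- 1L
  for (i in seq_along(arch$blocks)) {
    b <- arch$blocks[[i]]
    k <- b$kernel_size; F_ <- b$n_filters
    params$blocks[[i]] <- list(
      W = xavier_normal(k * C_in, F_, fan_in = k * C_in, fan_out = k * F_),
      b = numeric(F_),
      gamma = rep(1, F_), beta = rep(0, F_),
      mov_mu = numeric(F_), mov_var = rep(1, F_))
    C_in <- F_
  }
  flat <- shapes$width[shapes$layer == "flatten"]
  params$Wd1 <- xavier_normal(flat, arch$dense_units, flat, arch$dense_units)
  params$bd1 <- numeric(arch$dense_units)
  params$Wd2 <- xavier_normal(arch$dense_units, arch$n_classes,
                              arch$dense_units, arch$n_classes)
  params$bd2 <- numeric(arch$n_classes)
  params
}

# Forward pass.  X is an (n x input_length) matrix.  Returns class
# probabilities plus (if training) the caches needed for the backward pass,
# and optionally the observed per-layer shapes.
cnn_forward <- function(params, arch, X, training = FALSE,
                        bn_momentum = 0.9, collect_shapes = FALSE) {
  n <- nrow(X)
  A <- array(X, c(n, ncol(X), 1L))
  shapes <- list(data.frame(layer = "input", length = ncol(X), channels = 1L))
  caches <- list()
  for (i in seq_along(arch$blocks)) {
    b <- arch$blocks[[i]]
    pb <- params$blocks[[i]]
    L_in <- dim(A)[2]; C_in <- dim(A)[3]
    P <- im2col(A, b$kernel_size, b$conv_stride)
    Z <- P %*% pb$W + matrix(pb$b, nrow(P), length(pb$b), byrow = TRUE)
    Lc <- conv_out_len(L_in, b$kernel_size, b$conv_stride)

    if (b$batch_norm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
        params$blocks[[i]]$mov_mu <- bn_momentum * pb$mov_mu + (1 - bn_momentum) * mu
        params$blocks[[i]]$mov_var <- bn_momentum * pb$mov_var + (1 - bn_momentum) * v
      } else {
        mu <- pb$mov_mu
        v <- pb$mov_var
      }
      inv_sd <- 1 / sqrt(v + 1e-5)
      Xhat <- (Z - matrix(mu, nrow(Z), ncol(Z), byrow = TRUE)) *
        matrix(inv_sd, nrow(Z), ncol(Z), byrow = TRUE)
      Zb <- Xhat * matrix(pb$gamma, nrow(Z), ncol(Z), byrow = TRUE) +
        matrix(pb$beta, nrow(Z), ncol(Z), byrow = TRUE)
    } else {
      Xhat <- NULL; inv_sd <- NULL; mu <- NULL
      Zb <- Z
    }
    R <- pmax(Zb, 0)
    Ra <- R; dim(Ra) <- c(n, Lc, b$n_filters)
    shapes <- c(shapes, list(data.frame(layer = sprintf("conv%d", i),
                                        length = Lc, channels = b$n_filters)))
    pf <- pool_forward(Ra, b$pool_size, b$pool_stride, b$pool_beta, b$pool_bias)
    shapes <- c(shapes, list(data.frame(layer = sprintf("pool%d", i),
                                        length = dim(pf$out)[2],
                                        channels = b$n_filters)))
    if (training) {
      caches[[i]] <- list(P = P, Z = Z, Xhat = Xhat, inv_sd = inv_sd,
                          Zb = Zb, pool = pf, L_in = L_in, C_in = C_in, Lc = Lc)
    }
    A <- pf$out
  }
  gcache <- NULL
  if (arch$global_max_pool) {
    gcache <- pool_forward(A, dim(A)[2], 1L)
    A <- gcache$out
    shapes <- c(shapes, list(data.frame(layer = "global_max_pool",
                                        length = 1L, channels = dim(A)[3])))
  }
  flat_dims <- dim(A)
  M <- A; dim(M) <- c(n, flat_dims[2] * flat_dims[3])
  shapes <- c(shapes, list(data.frame(layer = "flatten", length = ncol(M),
                                      channels = 1L)))
  H1 <- M %*% params$Wd1 + matrix(params$bd1, n, arch$dense_units, byrow = TRUE)
  A1 <- pmax(H1, 0)
  shapes <- c(shapes, list(data.frame(layer = "dense1",
                                      length = arch$dense_units, channels = 1L)))
  logits <- A1 %*% params$Wd2 + matrix(params$bd2, n, arch$n_classes, byrow = TRUE)
  shapes <- c(shapes, list(data.frame(layer = "dense2",
                                      length = arch$n_classes, channels = 1L)))
  lse <- logits - apply(logits, 1, max)
  expz <- exp(lse)
  probs <- expz / rowSums(expz)

  out <- list(probs = probs, params = params)
  if (training) {
    out$cache <- list(blocks = caches, gpool = gcache, flat_dims = flat_dims,
                      M = M, H1 = H1, A1 = A1)
  }
  if (collect_shapes) {
    sh <- do.call(rbind, shapes)
    sh$width <- sh$length * sh$channels
    out$shapes <- sh
  }
  out
}

# Backward pass; Y is the one-hot target matrix for the batch.
cnn_backward <- function(params, arch, fw, Y) {
  n <- nrow(Y)
  cache <- fw$cache
  grads <- list(blocks = vector("list", length(arch$blocks)))

  dlogits <- (fw$probs - Y) / n
  grads$Wd2 <- crossprod(cache$A1, dlogits)
  grads$bd2 <- colSums(dlogits)
  dA1 <- dlogits %*% t(params$Wd2)
  dH1 <- dA1 * (cache$H1 > 0)
  grads$Wd1 <- crossprod(cache$M, dH1)
  grads$bd1 <- colSums(dH1)
  dM <- dH1 %*% t(params$Wd1)
  dA <- dM; dim(dA) <- cache$flat_dims

  if (arch$global_max_pool) {
    dA <- pool_backward(dA, cache$gpool, cache$gpool$L_in, 1L)
  }
  for (i in rev(seq_along(arch$blocks))) {
    b <- arch$blocks[[i]]
    cb <- cache$blocks[[i]]
    dRa <- pool_backward(dA, cb$pool, b$pool_size, b$pool_stride, b$pool_beta)
    dR <- dRa; dim(dR) <- c(nrow(cb$Z), ncol(cb$Z))
    dZb <- dR * (cb$Zb > 0)
    if (b$batch_norm) {
      m <- nrow(cb$Z)
      gmat <- matrix(params$blocks[[i]]$gamma, m, ncol(cb$Z), byrow = TRUE)
      ivmat <- matrix(cb$inv_sd, m, ncol(cb$Z), byrow = TRUE)
      dXhat <- dZb * gmat
      grads$blocks[[i]]$gamma <- colSums(dZb * cb$Xhat)
      grads$blocks[[i]]$beta <- colSums(dZb)
      # standard batch-norm gradient, vectorised per column
      sum_dXhat <- colSums(dXhat)
      sum_dXhat_xhat <- colSums(dXhat * cb$Xhat)
      dZ <- ivmat * (dXhat -
                       matrix(sum_dXhat / m, m, ncol(cb$Z), byrow = TRUE) -
                       cb$Xhat * matrix(sum_dXhat_xhat / m, m, ncol(cb$Z), byrow = TRUE))
    } else {
      dZ <- dZb
      grads$blocks[[i]]$gamma <- numeric(b$n_filters)
      grads$blocks[[i]]$beta <- numeric(b$n_filters)
    }
    grads$blocks[[i]]$W <- crossprod(cb$P, dZ)
    grads$blocks[[i]]$b <- colSums(dZ)
    if (i > 1) {
      dP <- dZ %*% t(params$blocks[[i]]$W)
      dA <- col2im(dP, dim(dRa)[1], cb$L_in, cb$C_in,
                   b$kernel_size, b$conv_stride)
    }
  }
  grads
}

# flatten parameter list into a named list of arrays for the optimiser
param_leaves <- function(params, arch) {
  leaves <- list()
  for (i in seq_along(arch$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      leaves[[sprintf("blocks.%d.%s", i, nm)]] <- params$blocks[[i]][[nm]]
    }
  }
  for (nm in c("Wd1", "bd1", "Wd2", "bd2")) leaves[[nm]] <- params[[nm]]
  leaves
}

set_leaf <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "blocks") {
    params$blocks[[as.integer(parts[2])]][[parts[3]]] <- value
  } else {
    params[[name]] <- value
  }
  params
}

#' Fit the 1D convolutional maturity classifier
#'
#' Trains the [cnn_architecture()] network by mini-batch gradient descent
#' on the categorical cross-entropy of the softmax output, using the Adam
#' update rule.  Convolution kernels and dense weights are initialised by
#' the Xavier normal scheme; batch normalisation runs in training mode
#' (per-batch statistics) during fitting and uses exponential moving
#' statistics at prediction time.  All randomness (initialisation and
#' batch shuffling) is governed by `control$seed`, so a fixed seed gives
#' a bit-for-bit reproducible model.
#'
#' @param x numeric matrix of preprocessed training spectra; `ncol(x)`
#'   must equal `architecture$input_length`.
#' @param y factor of class labels (every class non-empty).
#' @param architecture a [cnn_architecture()]; defaults to the published
#'   two-block architecture sized to `ncol(x)` and `nlevels(y)`.
#' @param control a [cnn_control()]; additional arguments in `...` are
#'   forwarded to [cnn_control()] when `control` is not supplied.
#' @param ... convenience overrides for [cnn_control()].
#' @return object of class `c("cnn_model", "nir_model")` with the
#'   per-epoch mean training loss in `$loss`.
#' @examples
#' \donttest{
#' bench <- easy_benchmark(seed = 1)
#' X <- apply_pipeline(default_pipeline(), spectra_matrix(bench))
#' fit <- cnn(X, maturity_labels(bench), epochs = 10, seed = 1)
#' }
#' @export
cnn <- function(x, y, architecture = NULL, control = NULL, ...) {
  y <- droplevels(as.factor(y))
  check(is.matrix(x) && nrow(x) == length(y), "x rows must match length(y)")
  check(all(table(y) > 0), "every class must have at least one training sample")
  if (is.null(control)) control <- cnn_control(...)
  if (is.null(architecture)) {
    architecture <- cnn_architecture(input_length = ncol(x),
                                     n_classes = nlevels(y))
  }
  check(ncol(x) == architecture$input_length,
        "x has %d columns but the architecture expects %d",
        ncol(x), architecture$input_length)
  check(nlevels(y) == architecture$n_classes,
        "y has %d classes but the architecture expects %d",
        nlevels(y), architecture$n_classes)
  Y <- one_hot(y)
  n <- nrow(x)

  fitted <- with_seed(control$seed, {
    params <- cnn_init_params(architecture)
    leaves <- param_leaves(params, architecture)
    m1 <- lapply(leaves, function(z) z * 0)
    m2 <- m1
    t_step <- 0
    loss <- numeric(control$epochs)
    for (ep in seq_len(control$epochs)) {
      perm <- sample.int(n)
      batch_starts <- seq(1, n, by = control$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        rows <- perm[bs:min(bs + control$batch_size - 1, n)]
        fw <- cnn_forward(params, architecture, x[rows, , drop = FALSE],
                          training = TRUE, bn_momentum = control$bn_momentum)
        params <- fw$params  # moving BN statistics updated
        pb <- fw$probs[cbind(seq_along(rows), max.col(Y[rows, , drop = FALSE]))]
        ep_loss <- ep_loss + -sum(log(pmax(pb, 1e-12)))
        grads <- cnn_backward(params, architecture, fw, Y[rows, , drop = FALSE])
        gl <- param_leaves(grads, architecture)
        pl <- param_leaves(params, architecture)
        t_step <- t_step + 1
        for (nm in names(leaves)) {
          g <- gl[[nm]]
          m1[[nm]] <- control$beta1 * m1[[nm]] + (1 - control$beta1) * g
          m2[[nm]] <- control$beta2 * m2[[nm]] + (1 - control$beta2) * g^2
          mhat <- m1[[nm]] / (1 - control$beta1^t_step)
          vhat <- m2[[nm]] / (1 - control$beta2^t_step)
          upd <- pl[[nm]] -
            control$learning_rate * mhat / (sqrt(vhat) + control$epsilon)
          params <- set_leaf(params, nm, upd)
        }
      }
      loss[ep] <- ep_loss / n
      if (control$verbose > 0 && ep %% control$verbose == 0) {
        message(sprintf("epoch %d/%d: loss %.4f", ep, control$epochs, loss[ep]))
      }
    }
    list(params = params, loss = loss)
  })

  structure(list(params = fitted$params, architecture = architecture,
                 control = control, levels = levels(y), loss = fitted$loss),
            class = c("cnn_model", "nir_model"))
}

#' @param object fitted `cnn_model`.
#' @param newdata matrix of spectra to classify.
#' @param type `"class"` for labels or `"prob"` for the softmax matrix
#'   (rows sum to 1).
#' @rdname cnn
#' @export
predict.cnn_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  check(ncol(newdata) == object$architecture$input_length,
        "newdata has %d columns but the model expects %d",
        ncol(newdata), object$architecture$input_length)
  # predict in chunks to bound the im2col working set
  chunk <- 256L
  probs <- NULL
  for (start in seq(1, nrow(newdata), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(newdata))
    fw <- cnn_forward(object$params, object$architecture,
                      newdata[rows, , drop = FALSE], training = FALSE)
    probs <- rbind(probs, fw$probs)
  }
  colnames(probs) <- object$levels
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' Runtime tensor shapes of an instantiated network
#'
#' Instantiates the network (seeded weights), runs one forward pass on
#' random input, and reports the observed shape of every layer in the same
#' format as [cnn_output_shapes()].  Used to verify that the symbolic
#' shape calculator matches the actual tensors.
#'
#' @param arch a [cnn_architecture()].
#' @param n number of rows in the probe batch.
#' @param seed seed for the probe weights and input.
#' @return data frame with `layer`, `length`, `channels`, `width`.
#' @export
cnn_runtime_shapes <- function(arch, n = 2, seed = 1) {
  stopifnot(inherits(arch, "cnn_architecture"))
  with_seed(seed, {
    params <- cnn_init_params(arch)
    X <- matrix(stats::rnorm(n * arch$input_length), n, arch$input_length)
    fw <- cnn_forward(params, arch, X, training = FALSE, collect_shapes = TRUE)
    fw$shapes
  })
}
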