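# Internal helpers shared across the package.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves going up (away from
#' zero), the convention used in all printed report tables.  This differs
#' from [base::round()], which rounds halves to even.  A tiny guard of
#' 1e-9 absorbs binary floating-point representation error so that values
#' that are exact halves in decimal (e.g. 759.5 arising as 0.7 * 1085)
#' round upwards as intended.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(96.445, 2)  # 96.45
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  All stochastic entry points funnel through this so a
# fixed seed gives bit-identical results without clobbering the session RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# stopifnot with a formatted message
check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Row-wise sigmoid, numerically stable at both tails.
sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -500), 500)))

# One-hot encode a factor (n x nlevels matrix of 0/1).
one_hot <- function(y) {
  y <- as.factor(y)
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

# Squared Euclidean distances from each row of A to each row of B.
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}
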