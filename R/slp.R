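#' Single-layer perceptron (linear predictor) training
#'
#' The LMS-style update `W(n+1) = W(n) + mu * e(n) * X(n)` with
#' `e(n) = d(n) - y(n)` and linear activation `y(n) = W(n)' X(n)` -- no hard
#' threshold. Used as a linearity probe: if a linear predictor separates the
#' classes, nonlinear capacity is unnecessary. One weight vector is trained
#' per output class (two here: healthy, dying), sweeping the samples in a
#' seeded random order each epoch.
#'
#' @param X design matrix (samples x features), finite.
#' @param d targets: a two-column 0/1 matrix (one column per class) or a
#'   vector (single output).
#' @param mu learning rate (default 0.1).
#' @param epochs full passes over the data (default 10).
#' @param seed RNG seed for the sample order.
#' @param bias prepend an intercept input fixed at 1 (default TRUE).
#' @return object of class `slp_model` with fields `W` (features(+1) x
#'   outputs), `mu`, `bias`.
#' @export
slp_fit <- function(X, d, mu = 0.1, epochs = 10L, seed = 1L, bias = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("slp_fit: non-finite values in X", call. = FALSE)
  d <- as.matrix(d)
  if (nrow(d) != nrow(X)) stop("slp_fit: X and d disagree on sample count", call. = FALSE)
  if (bias) X <- cbind(1, X)
  W <- matrix(0, ncol(X), ncol(d))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    for (n in sample.int(nrow(X))) {
      x <- X[n, ]
      e <- d[n, ] - as.vector(crossprod(W, x))   # e = d - y, y = W'x
      W <- W + mu * outer(x, e)
    }
  }
  structure(list(W = W, mu = mu, bias = bias), class = "slp_model")
}

#' Predict linear scores from an SLP model
#' @param object an `slp_model`.
#' @param X design matrix with the training feature width.
#' @param ... unused.
#' @return samples x outputs matrix of linear scores (unbounded).
#' @export
predict.slp_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (object$bias) X <- cbind(1, X)
  if (ncol(X) != nrow(object$W))
    stop("predict.slp_model: feature width mismatch", call. = FALSE)
  X %*% object$W
}
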