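#' Hidden-layer sizing rule for the shallow MLP
#'
#' The halving rule: one hidden layer of `input/2` units, or two hidden
#' layers of `input/2` and `input/4`. For vectorised-GLCM inputs the widths
#' come out to the canonical powers of two (e.g. 4096 -> 2048 -> 1024);
#' inputs not divisible by 4 (e.g. the width-10 Haralick baseline) require
#' `allow_odd = TRUE`, which rounds the halves up (10 -> 5 -> 3).
#'
#' @param input_dim input-layer width.
#' @param n_hidden_layers 1 or 2.
#' @param allow_odd permit inputs whose halves are not integers.
#' @return integer vector of layer sizes, `input` first, 2 outputs last.
#' @export
mlp_architecture <- function(input_dim, n_hidden_layers = 1L,
                             allow_odd = FALSE) {
  if (!n_hidden_layers %in% 1:2)
    stop("mlp_architecture: n_hidden_layers must be 1 or 2", call. = FALSE)
  if (input_dim < 2 || input_dim != round(input_dim))
    stop("mlp_architecture: input_dim must be an integer >= 2", call. = FALSE)
  h <- input_dim / c(2, 4)[seq_len(n_hidden_layers)]
  if (any(h != round(h))) {
    if (!allow_odd)
      stop("mlp_architecture: input_dim not divisible by 2^layers; ",
           "set allow_odd = TRUE to round the halving rule up", call. = FALSE)
    h <- ceiling(h)
  }
  as.integer(c(input_dim, h, 2L))
}

#' Training configuration for [mlp_fit()]
#'
#' @param optimizer `"scg"` (scaled conjugate gradient, default) or
#'   `"backprop"` (plain per-sample gradient-descent weight updates).
#' @param learning_rate step size for the backprop optimizer.
#' @param max_epochs SCG iterations or backprop epochs.
#' @param max_validation_fails consecutive validation checks without
#'   improvement tolerated before early stopping (default 5).
#' @param validation_fraction share of the training data held out for the
#'   early-stopping check (default 0.2, an 80:20 split).
#' @param loss `"xent"` (cross-entropy, default) or `"mse"`; the MSE output
#'   delta is the textbook `y (1 - y) e` sigmoid-derivative form.
#' @param seed RNG seed for the split and the weight initialisation.
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = c("scg", "backprop"),
                         learning_rate = 0.1, max_epochs = 200L,
                         max_validation_fails = 5L,
                         validation_fraction = 0.2,
                         loss = c("xent", "mse"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  if (max_validation_fails < 1)
    stop("train_config: max_validation_fails must be >= 1", call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("train_config: validation_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 max_validation_fails = as.integer(max_validation_fails),
                 validation_fraction = validation_fraction,
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter vector <-> per-layer weight matrices -----------------------
# layer l weights: (sizes[l] + 1) x sizes[l+1], bias in the first row
.mlp_shapes <- function(sizes) {
  L <- length(sizes) - 1L
  lapply(seq_len(L), function(l) c(sizes[l] + 1L, sizes[l + 1L]))
}
.mlp_unflatten <- function(par, sizes) {
  shp <- .mlp_shapes(sizes)
  out <- vector("list", length(shp)); pos <- 0L
  for (l in seq_along(shp)) {
    n <- prod(shp[[l]])
    out[[l]] <- matrix(par[pos + seq_len(n)], shp[[l]][1], shp[[l]][2])
    pos <- pos + n
  }
  out
}
.mlp_flatten <- function(W) unlist(lapply(W, as.vector), use.names = FALSE)

.mlp_init <- function(sizes, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  W <- lapply(.mlp_shapes(sizes), function(s) {
    r <- 1 / sqrt(s[1])                       # symmetric uniform, fan-in scaled
    matrix(stats::runif(prod(s), -r, r), s[1], s[2])
  })
  .mlp_flatten(W)
}

.mlp_forward <- function(W, X) {
  A <- list(X)
  for (l in seq_along(W))
    A[[l + 1L]] <- .sigmoid(cbind(1, A[[l]]) %*% W[[l]])
  A
}

# loss and analytic gradient over the flattened parameter vector.
# xent: L = -mean_n sum_c [t log y + (1-t) log(1-y)]   (output delta y - t)
# mse:  L = mean_n 0.5 sum_c (y - t)^2                 (delta y(1-y)(y - t))
.mlp_loss_grad <- function(par, X, Y, sizes, loss = "xent",
                           grad = TRUE) {
  W <- .mlp_unflatten(par, sizes)
  A <- .mlp_forward(W, X)
  yhat <- A[[length(A)]]
  n <- nrow(X)
  eps <- 1e-12
  value <- if (loss == "xent")
    -sum(Y * log(yhat + eps) + (1 - Y) * log(1 - yhat + eps)) / n
  else sum((yhat - Y)^2) / (2 * n)
  if (!grad) return(list(value = value))
  L <- length(W)
  delta <- if (loss == "xent") (yhat - Y) / n
           else (yhat - Y) * yhat * (1 - yhat) / n
  G <- vector("list", L)
  for (l in L:1) {
    G[[l]] <- crossprod(cbind(1, A[[l]]), delta)
    if (l > 1) {
      back <- delta %*% t(W[[l]][-1, , drop = FALSE])
      delta <- back * A[[l]] * (1 - A[[l]])
    }
  }
  list(value = value, grad = .mlp_flatten(G))
}

# Scaled conjugate gradient (Moller 1993) with per-iteration early-stopping
# callback. fn(par) must return list(value, grad). Returns the par trace of
# the best validation point and the training-error curve.
.scg <- function(par, fn, max_iter, check = NULL) {
  sigma0 <- 1e-4; lambda <- 1e-6; lambda_bar <- 0
  fg <- fn(par)
  f_old <- fg$value; g <- fg$grad
  r <- -g; p <- r
  success <- TRUE
  n_par <- length(par)
  curve <- numeric(0)
  delta <- 0
  for (k in seq_len(max_iter)) {
    p2 <- sum(p * p)
    if (p2 < 1e-300) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      g_sig <- fn(par + sigma * p)$grad
      s <- (g_sig - g) / sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {                      # make the Hessian estimate p.d.
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    f_new <- fn(par + alpha * p)$value
    Delta <- 2 * delta * (f_old - f_new) / mu^2
    if (is.finite(Delta) && Delta >= 0) {  # successful step
      par <- par + alpha * p
      fg <- fn(par)
      f_old <- fg$value; g <- fg$grad
      r_new <- -g
      lambda_bar <- 0; success <- TRUE
      if (k %% n_par == 0) p <- r_new      # restart
      else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda; success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (!is.finite(lambda)) lambda <- 1e-6
    curve <- c(curve, f_old)
    if (!is.null(check)) {
      st <- check(par, k)
      if (st$stop) return(list(par = st$par, curve = curve,
                               epochs = k, stop_reason = st$reason))
    }
    if (sqrt(sum(r * r)) < 1e-8)
      return(list(par = par, curve = curve, epochs = k,
                  stop_reason = "gradient_converged"))
  }
  final <- if (!is.null(check)) check(par, max_iter, final = TRUE)$par else par
  list(par = final, curve = curve, epochs = max_iter,
       stop_reason = "max_epochs")
}

#' Train a multilayer perceptron
#'
#' Sigmoid hidden and output units, two output neurons (healthy, dying)
#' treated as a multi-label head. The default optimizer is batch scaled
#' conjugate gradient; `"backprop"` runs the textbook per-sample
#' steepest-descent weight updates instead. A `validation_fraction` share of
#' the supplied data is split off (seeded) for early stopping: training
#' halts after `max_validation_fails` consecutive checks without
#' improvement of the validation loss, returning the best-validation
#' weights.
#'
#' @param X design matrix, values ideally in `[0, 1]`.
#' @param Y two-column 0/1 target matrix.
#' @param config a [train_config()].
#' @param arch layer sizes from [mlp_architecture()] (or any integer vector
#'   starting at `ncol(X)` and ending in 2).
#' @return object of class `mlp_model`: `W` (list of weight matrices, bias
#'   row first), `sizes`, `loss`, `trained_epochs`, `stop_reason`,
#'   `error_curve` (training loss per epoch).
#' @export
mlp_fit <- function(X, Y, config = train_config(),
                    arch = mlp_architecture(ncol(X), 1L, allow_odd = TRUE)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (arch[1] != ncol(X))
    stop("mlp_fit: arch input width != ncol(X)", call. = FALSE)
  if (ncol(Y) != arch[length(arch)])
    stop("mlp_fit: Y width != output layer size", call. = FALSE)
  if (!all(is.finite(X))) stop("mlp_fit: non-finite values in X", call. = FALSE)
  sizes <- as.integer(arch)
  par <- .mlp_init(sizes, config$seed)

  if (config$max_epochs == 0L)
    return(structure(list(W = .mlp_unflatten(par, sizes), sizes = sizes,
                          loss = config$loss, trained_epochs = 0L,
                          stop_reason = "max_epochs", error_curve = numeric(0)),
                     class = "mlp_model"))

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- nrow(X)
  n_val <- max(1L, round(config$validation_fraction * n))
  val_idx <- if (n > 1) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) { tr_idx <- seq_len(n); val_idx <- integer(0) }
  Xt <- X[tr_idx, , drop = FALSE]; Yt <- Y[tr_idx, , drop = FALSE]
  Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]

  best <- list(par = par, val = Inf); fails <- 0L
  check <- function(par, k, final = FALSE) {
    if (!nrow(Xv)) return(list(stop = FALSE, par = par))
    v <- .mlp_loss_grad(par, Xv, Yv, sizes, config$loss, grad = FALSE)$value
    if (v < best$val - 1e-12) { best <<- list(par = par, val = v); fails <<- 0L }
    else fails <<- fails + 1L
    if (fails >= config$max_validation_fails)
      list(stop = TRUE, par = best$par, reason = "validation_fails")
    else list(stop = FALSE, par = if (final) best$par else par)
  }

  if (config$optimizer == "scg") {
    fn <- function(p) .mlp_loss_grad(p, Xt, Yt, sizes, config$loss)
    res <- .scg(par, fn, config$max_epochs, check)
    if (!is.finite(.mlp_loss_grad(res$par, Xt, Yt, sizes, config$loss,
                                  grad = FALSE)$value))
      stop("mlp_fit: training diverged (non-finite loss) at epoch ",
           res$epochs, call. = FALSE)
    W <- .mlp_unflatten(res$par, sizes)
    curve <- res$curve; epochs <- res$epochs; reason <- res$stop_reason
  } else {
    # per-sample steepest descent: w_new = w_old + eta * delta * y_prev
    curve <- numeric(0); reason <- "max_epochs"; epochs <- config$max_epochs
    for (ep in seq_len(config$max_epochs)) {
      for (i in sample.int(nrow(Xt))) {
        g <- .mlp_loss_grad(par, Xt[i, , drop = FALSE], Yt[i, , drop = FALSE],
                            sizes, config$loss)
        par <- par - config$learning_rate * g$grad
      }
      tr <- .mlp_loss_grad(par, Xt, Yt, sizes, config$loss, grad = FALSE)$value
      if (!is.finite(tr))
        stop("mlp_fit: training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      curve <- c(curve, tr)
      st <- check(par, ep, final = ep == config$max_epochs)
      if (st$stop) { par <- st$par; reason <- st$reason; epochs <- ep; break }
      if (ep == config$max_epochs) par <- st$par
    }
    W <- .mlp_unflatten(par, sizes)
  }
  structure(list(W = W, sizes = sizes, loss = config$loss,
                 trained_epochs = epochs, stop_reason = reason,
                 error_curve = curve),
            class = "mlp_model")
}

#' Forward-pass scores from an MLP model
#' @param object an `mlp_model`.
#' @param X design matrix with the trained input width.
#' @param ... unused.
#' @return samples x 2 matrix of sigmoid scores in `[0, 1]`.
#' @export
predict.mlp_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$sizes[1])
    stop("predict.mlp_model: feature width mismatch", call. = FALSE)
  A <- .mlp_forward(object$W, X)
  A[[length(A)]]
}

#' Average per-sample scores within cells
#'
#' Each cell contributes several GLCM samples; this pools their scores by
#' the mean, yielding one score row per cell for per-cell evaluation.
#'
#' @param scores samples x classes score matrix.
#' @param cell_id character vector, one id per sample row.
#' @return list with `scores` (cells x classes), `cell_id`.
#' @export
aggregate_by_cell <- function(scores, cell_id) {
  ids <- unique(cell_id)
  agg <- t(vapply(ids, function(id)
    colMeans(scores[cell_id == id, , drop = FALSE]),
    numeric(ncol(scores))))
  list(scores = agg, cell_id = ids)
}
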