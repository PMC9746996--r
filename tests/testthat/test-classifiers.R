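test_that("slp_fit performs the textbook single-step update", {
  # W = (0,0), X = (1,1), d = 1, mu = 0.1: e = 1, W -> (0.1, 0.1)
  m <- slp_fit(matrix(c(1, 1), 1, 2), matrix(1), mu = 0.1, epochs = 1,
               bias = FALSE)
  expect_equal(as.vector(m$W), c(0.1, 0.1))
})

test_that("the SLP separates linear data but not XOR", {
  set.seed(1)
  n <- 100
  X <- rbind(cbind(rnorm(n, -3), rnorm(n, -3)), cbind(rnorm(n, 3), rnorm(n, 3)))
  y <- rep(c(0, 1), each = n)
  m <- slp_fit(X, matrix(y), mu = 0.01, epochs = 50, seed = 2)
  acc <- mean((predict(m, X) > 0.5) == y)
  expect_gte(acc, 0.99)

  Xx <- cbind(rep(c(0, 1), each = 2), rep(c(0, 1), 2))
  Xx <- Xx[rep(1:4, 25), ] + matrix(rnorm(200, 0, 0.05), 100, 2)
  yx <- as.numeric(xor(Xx[, 1] > 0.5, Xx[, 2] > 0.5))
  mx <- slp_fit(Xx, matrix(yx), mu = 0.05, epochs = 50, seed = 3)
  expect_lte(mean((predict(mx, Xx) > 0.5) == yx), 0.60)
})

test_that("slp_fit is deterministic given the seed and rejects bad input", {
  X <- matrix(runif(40), 10, 4); y <- matrix(rep(0:1, 5))
  expect_identical(slp_fit(X, y, seed = 9)$W, slp_fit(X, y, seed = 9)$W)
  Xb <- X; Xb[1] <- NA
  expect_error(slp_fit(Xb, y), "finite")
})

test_that("mlp_architecture implements the halving rule", {
  expect_equal(mlp_architecture(4096, 2), c(4096L, 2048L, 1024L, 2L))
  expect_equal(mlp_architecture(64, 2), c(64L, 32L, 16L, 2L))
  expect_equal(mlp_architecture(256, 1), c(256L, 128L, 2L))
  expect_equal(mlp_architecture(1024, 2), c(1024L, 512L, 256L, 2L))
  expect_error(mlp_architecture(10, 2), "allow_odd")
  expect_equal(mlp_architecture(10, 2, allow_odd = TRUE), c(10L, 5L, 3L, 2L))
  expect_error(mlp_architecture(64, 3), "hidden")
})

test_that("analytic backprop gradients match the numerical oracle", {
  set.seed(8)
  X <- matrix(runif(12), 3, 4)
  Y <- matrix(c(1, 0, 1, 0, 1, 0), 3, 2)
  for (sizes in list(c(4L, 3L, 2L), c(4L, 3L, 2L, 2L))) {
    for (loss in c("xent", "mse")) {
      par <- gdglcm:::.mlp_init(sizes, seed = 5)
      got <- gdglcm:::.mlp_loss_grad(par, X, Y, sizes, loss)$grad
      num <- oracle_num_grad(function(p)
        gdglcm:::.mlp_loss_grad(p, X, Y, sizes, loss, grad = FALSE)$value, par)
      denom <- pmax(abs(num), 1e-4)
      expect_lt(max(abs(got - num) / denom), 1e-6)
    }
  }
})

test_that("the MLP solves XOR for most seeds", {
  Xx <- cbind(rep(c(0, 1), each = 2), rep(c(0, 1), 2))[rep(1:4, 25), ]
  set.seed(99)
  Xx <- Xx + matrix(rnorm(200, 0, 0.02), 100, 2)
  yx <- as.numeric(xor(Xx[, 1] > 0.5, Xx[, 2] > 0.5))
  Y <- cbind(1 - yx, yx)
  wins <- 0
  for (s in 1:10) {
    m <- mlp_fit(Xx, Y, train_config(max_epochs = 2000, seed = s,
                                     max_validation_fails = 50),
                 arch = c(2L, 4L, 2L))
    acc <- mean((predict(m, Xx)[, 2] > 0.5) == yx)
    if (acc >= 0.99) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("forward pass matches hand evaluation and degenerate configs", {
  sig <- function(x) 1 / (1 + exp(-x))
  W1 <- matrix(c(0.1, 0.3, -0.2, 0.2, -0.1, 0.4), 3, 2)  # bias row first
  W2 <- matrix(c(-0.3, 0.5, 0.2, 0.1, 0.2, -0.4), 3, 2)
  model <- structure(list(W = list(W1, W2), sizes = c(2L, 2L, 2L),
                          loss = "xent"), class = "mlp_model")
  x <- c(0.7, -0.4)
  h <- sig(c(1, x) %*% W1)
  want <- sig(cbind(1, h) %*% W2)
  expect_equal(predict(model, matrix(x, 1, 2)), want, tolerance = 1e-12)

  # all-zero weights: sigma(0) = 0.5 everywhere
  z <- structure(list(W = list(matrix(0, 3, 2), matrix(0, 3, 2)),
                      sizes = c(2L, 2L, 2L), loss = "xent"),
                 class = "mlp_model")
  expect_equal(as.vector(predict(z, matrix(1, 1, 2))), c(0.5, 0.5))
  expect_error(predict(z, matrix(1, 1, 3)), "width")

  # zero-epoch fit returns the initialised model with near-0.5 scores
  X <- matrix(runif(20), 10, 2); Y <- cbind(rep(1, 10), rep(0, 10))
  m0 <- mlp_fit(X, Y, train_config(max_epochs = 0, seed = 1),
                arch = c(2L, 4L, 2L))
  expect_equal(m0$trained_epochs, 0L)
  expect_true(all(abs(predict(m0, X) - 0.5) < 0.2))
})

test_that("monotone weight paths and seeded determinism hold", {
  base <- structure(list(W = list(matrix(0, 3, 2), matrix(0, 3, 2)),
                         sizes = c(2L, 2L, 2L), loss = "xent"),
                    class = "mlp_model")
  x <- matrix(c(1, 1), 1, 2)
  s_prev <- -Inf
  for (w in c(0.5, 1, 2)) {
    m <- base; m$W[[2]][2, 1] <- w     # strengthen one positive path
    s <- predict(m, x)[1, 1]
    expect_gt(s, s_prev); s_prev <- s
  }
  X <- matrix(runif(60), 20, 3)
  Y <- cbind(rep(c(1, 0), 10), rep(c(0, 1), 10))
  cfg <- train_config(max_epochs = 30, seed = 4)
  m1 <- mlp_fit(X, Y, cfg, arch = c(3L, 4L, 2L))
  m2 <- mlp_fit(X, Y, cfg, arch = c(3L, 4L, 2L))
  expect_identical(m1$W, m2$W)
})

test_that("early stopping fires on pure-noise labels", {
  set.seed(12)
  X <- matrix(runif(600), 200, 3)
  y <- sample(0:1, 200, replace = TRUE)
  m <- mlp_fit(X, cbind(1 - y, y),
               train_config(max_epochs = 5000, seed = 2),
               arch = c(3L, 8L, 2L))
  expect_equal(m$stop_reason, "validation_fails")
  expect_lt(m$trained_epochs, 5000L)
})

test_that("the backprop optimizer trains and stops deterministically", {
  set.seed(6)
  X <- rbind(matrix(runif(60, 0, 0.4), 30, 2), matrix(runif(60, 0.6, 1), 30, 2))
  y <- rep(0:1, each = 30)
  cfg <- train_config(optimizer = "backprop", learning_rate = 0.5,
                      max_epochs = 200, seed = 3)
  m <- mlp_fit(X, cbind(1 - y, y), cfg, arch = c(2L, 4L, 2L))
  expect_gte(mean((predict(m, X)[, 2] > 0.5) == y), 0.95)
  expect_identical(m$W, mlp_fit(X, cbind(1 - y, y), cfg,
                                arch = c(2L, 4L, 2L))$W)
})

test_that("aggregate_by_cell pools sample scores by mean", {
  sc <- matrix(c(0.2, 0.4, 0.9, 0.8, 0.6, 0.1), 3, 2)
  ag <- aggregate_by_cell(sc, c("a", "a", "b"))
  expect_equal(ag$cell_id, c("a", "b"))
  expect_equal(unname(ag$scores[1, ]), c(0.3, 0.7))
  expect_equal(unname(ag$scores[2, ]), c(0.9, 0.1))
})
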