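# Backward passes of every layer primitive are validated against central
# finite differences. Inputs and biases are drawn away from the ReLU kink
# so the numerical gradient is well defined.

numGrad <- function(lossFn, p, eps = 1e-6, sample = 10L) {
  idx <- sample(seq_along(p), min(sample, length(p)))
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    p1 <- p; p1[idx[k]] <- p[idx[k]] + eps
    p2 <- p; p2[idx[k]] <- p[idx[k]] - eps
    g[k] <- (lossFn(p1) - lossFn(p2)) / (2 * eps)
  }
  list(idx = idx, grad = g)
}

test_that("dense layer gradients match finite differences", {
  set.seed(1)
  X <- matrix(rnorm(4 * 5), 4, 5)
  W <- matrix(rnorm(5 * 3), 5, 3)
  b <- rnorm(3)
  dY <- matrix(rnorm(4 * 3), 4, 3)
  g <- respaug:::.denseB(X, W, dY)
  nW <- numGrad(function(p) sum(respaug:::.denseF(X, matrix(p, 5, 3), b) * dY), W)
  expect_equal(g$dW[nW$idx], nW$grad, tolerance = 1e-6)
  nX <- numGrad(function(p) sum(respaug:::.denseF(matrix(p, 4, 5), W, b) * dY), X)
  expect_equal(g$dX[nX$idx], nX$grad, tolerance = 1e-6)
})

test_that("convolution gradients match finite differences (strided, same padding)", {
  set.seed(2)
  X <- array(rnorm(5 * 6 * 2 * 3), c(5, 6, 2, 3))
  K <- respaug:::.heConv(3, 3, 2, 4)
  b <- rnorm(4)
  f <- respaug:::.convF(X, K, b, 2L, "same")
  dY <- array(rnorm(length(f$Y)), dim(f$Y))
  g <- respaug:::.convB(f$cache, K, dY)
  loss <- function(Kp) sum(respaug:::.convF(X, array(Kp, dim(K)), b, 2L, "same")$Y * dY)
  nK <- numGrad(loss, K)
  expect_equal(g$dK[nK$idx], nK$grad, tolerance = 1e-5)
  lossX <- function(Xp) sum(respaug:::.convF(array(Xp, dim(X)), K, b, 2L, "same")$Y * dY)
  nX <- numGrad(lossX, X)
  expect_equal(g$dX[nX$idx], nX$grad, tolerance = 1e-5)
  nb <- numGrad(function(bp) sum(respaug:::.convF(X, K, bp, 2L, "same")$Y * dY), b,
                sample = 4L)
  expect_equal(g$db[nb$idx], nb$grad, tolerance = 1e-5)
})

test_that("transposed convolution doubles spatial size and back-propagates exactly", {
  set.seed(3)
  X <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  K <- respaug:::.heConv(3, 3, 3, 2)
  b <- rnorm(2)
  f <- respaug:::.convtF(X, K, b, 2L)
  expect_equal(dim(f$Y), c(8, 10, 2, 2))
  dY <- array(rnorm(length(f$Y)), dim(f$Y))
  g <- respaug:::.convtB(f$cache, K, dY)
  lossX <- function(Xp) sum(respaug:::.convtF(array(Xp, dim(X)), K, b, 2L)$Y * dY)
  nX <- numGrad(lossX, X)
  expect_equal(g$dX[nX$idx], nX$grad, tolerance = 1e-5)
  lossK <- function(Kp) sum(respaug:::.convtF(X, array(Kp, dim(K)), b, 2L)$Y * dY)
  nK <- numGrad(lossK, K)
  expect_equal(g$dK[nK$idx], nK$grad, tolerance = 1e-5)
})

test_that("max pooling routes gradients to the argmax entries", {
  set.seed(4)
  X <- array(rnorm(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  f <- respaug:::.pool2F(X)
  expect_equal(dim(f$Y), c(3, 4, 2, 2))
  dY <- array(rnorm(length(f$Y)), dim(f$Y))
  g <- respaug:::.pool2B(f$cache, dY)
  nX <- numGrad(function(Xp) sum(respaug:::.pool2F(array(Xp, dim(X)))$Y * dY), X,
                sample = 20L)
  expect_equal(g[nX$idx], nX$grad, tolerance = 1e-5)
})

test_that("LSTM backward-through-time matches finite differences", {
  set.seed(5)
  n <- 2; Tn <- 4; d <- 3; h <- 5
  X <- array(rnorm(n * Tn * d), c(n, Tn, d))
  Wx <- respaug:::.heDense(d, 4 * h)
  Wh <- respaug:::.heDense(h, 4 * h)
  b <- rnorm(4 * h, 0, 0.1)
  fwd <- respaug:::.lstmF(X, Wx, Wh, b)
  dH <- array(rnorm(n * Tn * h), c(n, Tn, h))
  g <- respaug:::.lstmB(X, Wx, Wh, b, fwd, dH)
  for (nm in c("Wx", "Wh", "b", "X")) {
    ref <- switch(nm, Wx = Wx, Wh = Wh, b = b, X = X)
    lossFn <- function(p) {
      a <- list(X = X, Wx = Wx, Wh = Wh, b = b)
      a[[nm]] <- if (is.null(dim(ref))) p else array(p, dim(ref))
      sum(respaug:::.lstmF(a$X, a$Wx, a$Wh, a$b)$H * dH)
    }
    nG <- numGrad(lossFn, ref)
    got <- switch(nm, Wx = g$dWx, Wh = g$dWh, b = g$db, X = g$dX)
    expect_equal(got[nG$idx], nG$grad, tolerance = 1e-5,
                 label = paste("LSTM grad", nm))
  }
})

test_that("softmax cross-entropy gives valid probabilities and exact gradients", {
  set.seed(6)
  Z <- matrix(rnorm(4 * 3), 4, 3)
  y <- c(1L, 3L, 2L, 1L)
  sm <- respaug:::.softmaxXent(Z, y)
  expect_equal(rowSums(sm$P), rep(1, 4), tolerance = 1e-12)
  nZ <- numGrad(function(p) respaug:::.softmaxXent(matrix(p, 4, 3), y)$loss, Z,
                sample = 12L)
  expect_equal(sm$dZ[nZ$idx], nZ$grad, tolerance = 1e-6)
})

test_that("Adam and RMSprop minimise a simple quadratic", {
  target <- c(2, -3)
  for (opt in c("adam", "rmsprop")) {
    p <- list(w = c(0, 0))
    st <- respaug:::.optimInit(p)
    for (i in 1:800) {
      g <- list(w = 2 * (p$w - target))
      upd <- respaug:::.optimStep(opt, p, g, st, 0.02)
      p <- upd$params; st <- upd$state
    }
    expect_equal(p$w, target, tolerance = 1e-2, label = opt)
  }
})
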