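# Minimal vectorized neural-network primitives (base R + BLAS).
#
# Conventions: dense activations are n x d matrices (rows = samples);
# convolutional activations are H x W x C x n arrays. Convolution is
# implemented by batched im2col so the inner loop is a single matrix
# multiplication. All backward passes are validated against numerical
# differentiation in the test suite.

.reluF <- function(x) pmax(x, 0)
.reluB <- function(x, dy) dy * (x > 0)
.sigmoidF <- function(x) 1 / (1 + exp(-x))
.sigmoidB <- function(y, dy) dy * y * (1 - y)   # y = sigmoid(x)
.tanhB <- function(y, dy) dy * (1 - y^2)        # y = tanh(x)

.denseF <- function(X, W, b) sweep(X %*% W, 2, b, "+")
.denseB <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# ---- convolution -----------------------------------------------------------

# Padding amounts (top, bottom, left, right) for a given mode.
.convPad <- function(H, W, kh, kw, stride, padding) {
  if (padding == "valid") return(c(0L, 0L, 0L, 0L))
  outH <- ceiling(H / stride)
  outW <- ceiling(W / stride)
  ph <- max((outH - 1L) * stride + kh - H, 0L)
  pw <- max((outW - 1L) * stride + kw - W, 0L)
  c(ph %/% 2L, ph - ph %/% 2L, pw %/% 2L, pw - pw %/% 2L)
}

.padArray <- function(X, pad) {
  if (all(pad == 0L)) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + pad[1] + pad[2], d[2] + pad[3] + pad[4], d[3], d[4]))
  Xp[(pad[1] + 1L):(pad[1] + d[1]), (pad[3] + 1L):(pad[3] + d[2]), , ] <- X
  Xp
}

# im2col index matrix: P x L linear indices into an (Hp, Wp, C) volume.
.im2colIndex <- function(Hp, Wp, C, kh, kw, stride) {
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  off <- as.vector(outer(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, "+"),
                         (0:(C - 1L)) * Hp * Wp, "+"))
  base <- as.vector(outer((0:(Ho - 1L)) * stride + 1L,
                          (0:(Wo - 1L)) * stride * Hp, "+"))
  list(idx = outer(off, base, "+"), Ho = Ho, Wo = Wo)
}

# Forward convolution. X: H x W x Cin x n, K: kh x kw x Cin x Cout.
# Returns Y (Ho x Wo x Cout x n) plus a cache for the backward pass.
.convF <- function(X, K, b, stride = 1L, padding = "valid") {
  d <- dim(X); kd <- dim(K)
  pad <- .convPad(d[1], d[2], kd[1], kd[2], stride, padding)
  Xp <- .padArray(X, pad)
  dp <- dim(Xp)
  ii <- .im2colIndex(dp[1], dp[2], dp[3], kd[1], kd[2], stride)
  P <- nrow(ii$idx); L <- ncol(ii$idx); n <- d[4]
  Mp <- matrix(Xp, ncol = n)
  Xcol <- Mp[as.vector(ii$idx), , drop = FALSE]           # (P*L) x n
  Xcol <- matrix(aperm(array(Xcol, c(P, L, n)), c(2, 3, 1)), L * n, P)
  Kmat <- matrix(K, P, kd[4])
  Ymat <- sweep(Xcol %*% Kmat, 2, b, "+")                  # (L*n) x Cout
  Y <- aperm(array(Ymat, c(ii$Ho, ii$Wo, n, kd[4])), c(1, 2, 4, 3))
  list(Y = Y, cache = list(Xcol = Xcol, idx = ii$idx, pad = pad,
                           dimXp = dp, dimX = d, Ho = ii$Ho, Wo = ii$Wo))
}

.convB <- function(cache, K, dY) {
  kd <- dim(K)
  P <- nrow(cache$idx); L <- ncol(cache$idx)
  n <- cache$dimX[4]
  dYmat <- matrix(aperm(dY, c(1, 2, 4, 3)), L * n, kd[4])
  db <- colSums(dYmat)
  dK <- array(crossprod(cache$Xcol, dYmat), kd)
  dXcol <- dYmat %*% t(matrix(K, P, kd[4]))                # (L*n) x P
  dXcol <- matrix(aperm(array(dXcol, c(L, n, P)), c(3, 1, 2)), P * L, n)
  idxVec <- as.vector(cache$idx)
  rs <- rowsum(dXcol, idxVec)
  dMp <- matrix(0, prod(cache$dimXp[1:3]), n)
  dMp[as.integer(rownames(rs)), ] <- rs
  dXp <- array(dMp, cache$dimXp)
  pad <- cache$pad; d <- cache$dimX
  dX <- dXp[(pad[1] + 1L):(pad[1] + d[1]),
            (pad[3] + 1L):(pad[3] + d[2]), , , drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dK = dK, db = db)
}

# ---- fractionally-strided (transposed) convolution -------------------------
# Implemented as zero-insertion upsampling followed by a stride-1 'same'
# convolution, which doubles each spatial dimension for stride 2.

.zeroInsert <- function(X, stride) {
  d <- dim(X)
  Z <- array(0, c(d[1] * stride, d[2] * stride, d[3], d[4]))
  Z[seq(1L, d[1] * stride, stride), seq(1L, d[2] * stride, stride), , ] <- X
  Z
}

.convtF <- function(X, K, b, stride = 2L) {
  Z <- .zeroInsert(X, stride)
  out <- .convF(Z, K, b, 1L, "same")
  out$cache$stride <- stride
  out$cache$dimXorig <- dim(X)
  out
}

.convtB <- function(cache, K, dY) {
  g <- .convB(cache, K, dY)
  s <- cache$stride
  d <- cache$dimXorig
  dX <- g$dX[seq(1L, d[1] * s, s), seq(1L, d[2] * s, s), , , drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dK = g$dK, db = g$db)
}

# ---- max pooling (size = stride = 2, valid) --------------------------------

.pool2F <- function(X) {
  d <- dim(X)
  Ho <- (d[1] - 2L) %/% 2L + 1L
  Wo <- (d[2] - 2L) %/% 2L + 1L
  r <- seq(1L, by = 2L, length.out = Ho)
  cc <- seq(1L, by = 2L, length.out = Wo)
  A <- list(X[r, cc, , , drop = FALSE],     X[r + 1L, cc, , , drop = FALSE],
            X[r, cc + 1L, , , drop = FALSE], X[r + 1L, cc + 1L, , , drop = FALSE])
  Y <- pmax(A[[1]], A[[2]], A[[3]], A[[4]])
  take <- vector("list", 4)
  left <- array(TRUE, dim(Y))
  for (k in 1:4) {
    take[[k]] <- left & (A[[k]] == Y)
    left <- left & !take[[k]]
  }
  list(Y = Y, cache = list(take = take, r = r, cc = cc, dimX = d))
}

.pool2B <- function(cache, dY) {
  dX <- array(0, cache$dimX)
  r <- cache$r; cc <- cache$cc; tk <- cache$take
  dX[r, cc, , ]           <- dY * tk[[1]]
  dX[r + 1L, cc, , ]      <- dX[r + 1L, cc, , ] + dY * tk[[2]]
  dX[r, cc + 1L, , ]      <- dX[r, cc + 1L, , ] + dY * tk[[3]]
  dX[r + 1L, cc + 1L, , ] <- dX[r + 1L, cc + 1L, , ] + dY * tk[[4]]
  dX
}

# ---- LSTM ------------------------------------------------------------------
# X: n x T x d. Gate order in the 4h-wide weight blocks: input, forget,
# cell, output. Returns all hidden states (n x T x h).

.lstmF <- function(X, Wx, Wh, b) {
  d <- dim(X); n <- d[1]; Tn <- d[2]
  h <- nrow(Wh)
  Hout <- array(0, c(n, Tn, h))
  Hprev <- matrix(0, n, h); Cprev <- matrix(0, n, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], n)
    A <- sweep(Xt %*% Wx + Hprev %*% Wh, 2, b, "+")
    i <- .sigmoidF(A[, 1:h, drop = FALSE])
    f <- .sigmoidF(A[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- .sigmoidF(A[, (3 * h + 1):(4 * h), drop = FALSE])
    Cc <- f * Cprev + i * g
    tc <- tanh(Cc)
    Ht <- o * tc
    Hout[, t, ] <- Ht
    cache[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                       Cprev = Cprev, tc = tc, Hprev = Hprev)
    Hprev <- Ht; Cprev <- Cc
  }
  list(H = Hout, cache = cache)
}

.lstmB <- function(X, Wx, Wh, b, fwd, dH) {
  d <- dim(X); n <- d[1]; Tn <- d[2]
  h <- nrow(Wh)
  dWx <- Wx * 0; dWh <- Wh * 0; db <- b * 0
  dX <- array(0, d)
  dHnext <- matrix(0, n, h); dCnext <- matrix(0, n, h)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dHt <- matrix(dH[, t, ], n) + dHnext
    dO <- dHt * cc$tc
    dC <- dHt * cc$o * (1 - cc$tc^2) + dCnext
    dI <- dC * cc$g
    dG <- dC * cc$i
    dF <- dC * cc$Cprev
    dCnext <- dC * cc$f
    dA <- cbind(.sigmoidB(cc$i, dI), .sigmoidB(cc$f, dF),
                .tanhB(cc$g, dG), .sigmoidB(cc$o, dO))
    dWx <- dWx + crossprod(cc$Xt, dA)
    dWh <- dWh + crossprod(cc$Hprev, dA)
    db <- db + colSums(dA)
    dHnext <- dA %*% t(Wh)
    dX[, t, ] <- dA %*% t(Wx)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- losses ----------------------------------------------------------------

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Categorical cross-entropy with integer class targets (1-based).
.softmaxXent <- function(Z, y) {
  P <- .softmax(Z)
  n <- nrow(Z)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  list(loss = loss, dZ = dZ / n, P = P)
}

# ---- parameter initialisation and optimisers -------------------------------

.heDense <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

.heConv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

.optimInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

.rmspropStep <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + eps)
  }
  list(params = params, state = state)
}

.optimStep <- function(optimizer, params, grads, state, lr) {
  if (optimizer == "adam") .adamStep(params, grads, state, lr)
  else .rmspropStep(params, grads, state, lr)
}

# Inverted dropout mask drawn from the current RNG.
.dropoutMask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((stats::runif(prod(dims)) >= rate) / (1 - rate), dims)
}
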