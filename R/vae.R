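# Three variational-autoencoder variants over normalized log-mel
# spectrograms: a dense (MLP) VAE and a convolutional VAE, each trained
# per minority class, and a class-conditional convolutional VAE trained on
# all minority classes jointly. Decoders end in a sigmoid, which is why the
# spectrograms are min-max normalized to [0, 1].

#' VAE configuration
#'
#' @param variant `"mlp"`, `"cnn"` or `"conditional"`.
#' @param latentDim Latent dimensionality (default 2).
#' @param intermediateDim Width of the dense layers in the MLP variant
#'   (default 512).
#' @param convFilters Encoder filter counts for the two stride-2
#'   convolutions (default `c(16, 32)`).
#' @param deconvFilters Decoder transposed-convolution filter counts
#'   (default `c(32, 16, 1)`; the last must be 1).
#' @param encDense Widths of the dense stack between the convolutional
#'   encoder and the latent heads.
#' @param kernel Convolution kernel size (default 3).
#' @param optimizer `"adam"` or `"rmsprop"`; defaults to Adam for the MLP
#'   variant and RMSprop for the convolutional variants.
#' @param learningRate Optimizer step size (default 1e-3).
#' @param beta Weight of the KL term in the objective (default 1).
#' @param epochs Training epochs.
#' @param batchSize Minibatch size.
#' @param seed Integer seed fixing initialisation, shuffling and latent
#'   noise.
#' @param nClasses Number of classes for the conditional variant (default 6
#'   minority classes).
#' @param inputDim Spectrogram dimensions `c(nMels, frames)`; both must be
#'   divisible by 8 for the convolutional variants.
#' @return A list of class `"vaeConfig"`.
#' @export
vaeConfig <- function(variant = c("mlp", "cnn", "conditional"),
                      latentDim = 2L, intermediateDim = 512L,
                      convFilters = c(16L, 32L),
                      deconvFilters = c(32L, 16L, 1L),
                      encDense = c(256L, 128L, 64L),
                      kernel = 3L, optimizer = NULL, learningRate = 1e-3,
                      beta = 1, epochs = 100L, batchSize = 32L, seed = 1L,
                      nClasses = 6L, inputDim = c(128L, 256L)) {
  variant <- match.arg(variant)
  if (is.null(optimizer)) {
    optimizer <- if (variant == "mlp") "adam" else "rmsprop"
  }
  stopifnot(latentDim >= 1, beta >= 0, learningRate > 0,
            deconvFilters[length(deconvFilters)] == 1L)
  if (variant != "mlp" && any(inputDim %% 8L != 0L)) {
    stop("convolutional variants need inputDim divisible by 8")
  }
  structure(list(variant = variant, latentDim = as.integer(latentDim),
                 intermediateDim = as.integer(intermediateDim),
                 convFilters = as.integer(convFilters),
                 deconvFilters = as.integer(deconvFilters),
                 encDense = as.integer(encDense), kernel = as.integer(kernel),
                 optimizer = optimizer, learningRate = learningRate,
                 beta = beta, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 nClasses = as.integer(nClasses),
                 inputDim = as.integer(inputDim)),
            class = "vaeConfig")
}

#' Initialise an untrained VAE
#'
#' Builds the weight arrays for the configured variant. The MLP variant is
#' two 512-wide ReLU dense layers to the latent heads and a mirrored
#' decoder ending in a sigmoid output; the convolutional variants use two
#' stride-2 encoder convolutions (16 then 32 filters), a dense stack to the
#' heads, and a decoder that reshapes a dense layer to a
#' `(nMels/8, frames/8, 32)` grid followed by three stride-2
#' fractionally-strided convolutions (32, 16, 1 filters) so the output is
#' exactly `nMels x frames` in `[0, 1]`. The conditional variant appends a
#' one-hot class label as constant channels at the encoder input and
#' concatenates it to the latent vector at the decoder input.
#'
#' @param config A [vaeConfig()].
#' @return A list with `params` (named weight list) and `config`.
#' @export
buildVae <- function(config) {
  stopifnot(inherits(config, "vaeConfig"))
  H <- config$inputDim[1]; W <- config$inputDim[2]
  ld <- config$latentDim
  p <- list()
  if (config$variant == "mlp") {
    d <- H * W
    id <- config$intermediateDim
    p$encW1 <- .heDense(d, id);  p$encB1 <- numeric(id)
    p$encW2 <- .heDense(id, id); p$encB2 <- numeric(id)
    p$muW <- .heDense(id, ld);   p$muB <- numeric(ld)
    p$lvW <- .heDense(id, ld);   p$lvB <- numeric(ld)
    p$decW1 <- .heDense(ld, id); p$decB1 <- numeric(id)
    p$decW2 <- .heDense(id, id); p$decB2 <- numeric(id)
    p$outW <- .heDense(id, d);   p$outB <- numeric(d)
  } else {
    cin <- if (config$variant == "conditional") 1L + config$nClasses else 1L
    k <- config$kernel
    f <- config$convFilters
    p$convK1 <- .heConv(k, k, cin, f[1]);  p$convB1 <- numeric(f[1])
    p$convK2 <- .heConv(k, k, f[1], f[2]); p$convB2 <- numeric(f[2])
    flat <- (H %/% 4L) * (W %/% 4L) * f[2]
    prev <- flat
    for (i in seq_along(config$encDense)) {
      p[[paste0("encW", i)]] <- .heDense(prev, config$encDense[i])
      p[[paste0("encB", i)]] <- numeric(config$encDense[i])
      prev <- config$encDense[i]
    }
    p$muW <- .heDense(prev, ld); p$muB <- numeric(ld)
    p$lvW <- .heDense(prev, ld); p$lvB <- numeric(ld)
    zin <- if (config$variant == "conditional") ld + config$nClasses else ld
    gh <- H %/% 8L; gw <- W %/% 8L
    df <- config$deconvFilters
    p$decW <- .heDense(zin, gh * gw * 32L); p$decB <- numeric(gh * gw * 32L)
    p$dcK1 <- .heConv(k, k, 32L, df[1]);    p$dcB1 <- numeric(df[1])
    p$dcK2 <- .heConv(k, k, df[1], df[2]);  p$dcB2 <- numeric(df[2])
    p$dcK3 <- .heConv(k, k, df[2], df[3]);  p$dcB3 <- numeric(df[3])
  }
  list(params = p, config = config)
}

# One-hot matrix (n x nClasses) from integer labels.
.oneHot <- function(y, nClasses) {
  M <- matrix(0, length(y), nClasses)
  M[cbind(seq_along(y), y)] <- 1
  M
}

# ---- encoder / decoder forward & backward ----------------------------------

.vaeEncodeF <- function(p, config, X, labels1h = NULL) {
  if (config$variant == "mlp") {
    H1 <- .reluF(.denseF(X, p$encW1, p$encB1))
    H2 <- .reluF(.denseF(H1, p$encW2, p$encB2))
    mu <- .denseF(H2, p$muW, p$muB)
    lv <- .denseF(H2, p$lvW, p$lvB)
    list(mu = mu, logvar = lv, cache = list(X = X, H1 = H1, H2 = H2))
  } else {
    d <- dim(X)                                   # H x W x C x n
    if (config$variant == "conditional") {
      n <- d[4]
      Xc <- array(0, c(d[1], d[2], 1L + config$nClasses, n))
      Xc[, , 1L, ] <- X[, , 1L, ]
      for (k in seq_len(config$nClasses)) {
        Xc[, , 1L + k, ] <- rep(labels1h[, k], each = d[1] * d[2])
      }
      X <- Xc
    }
    c1 <- .convF(X, p$convK1, p$convB1, 2L, "same")
    a1 <- .reluF(c1$Y)
    c2 <- .convF(a1, p$convK2, p$convB2, 2L, "same")
    a2 <- .reluF(c2$Y)
    n <- dim(a2)[4]
    flat <- t(matrix(a2, ncol = n))
    hs <- list(); Hprev <- flat
    for (i in seq_along(config$encDense)) {
      hs[[i]] <- .reluF(.denseF(Hprev, p[[paste0("encW", i)]],
                                p[[paste0("encB", i)]]))
      Hprev <- hs[[i]]
    }
    mu <- .denseF(Hprev, p$muW, p$muB)
    lv <- .denseF(Hprev, p$lvW, p$lvB)
    list(mu = mu, logvar = lv,
         cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, flat = flat,
                      hs = hs, Xin = X))
  }
}

.vaeDecodeF <- function(p, config, Z, labels1h = NULL) {
  if (config$variant == "mlp") {
    D1 <- .reluF(.denseF(Z, p$decW1, p$decB1))
    D2 <- .reluF(.denseF(D1, p$decW2, p$decB2))
    Xh <- .sigmoidF(.denseF(D2, p$outW, p$outB))
    list(Xhat = Xh, cache = list(Z = Z, D1 = D1, D2 = D2))
  } else {
    Zin <- if (config$variant == "conditional") cbind(Z, labels1h) else Z
    G <- .reluF(.denseF(Zin, p$decW, p$decB))
    gh <- config$inputDim[1] %/% 8L; gw <- config$inputDim[2] %/% 8L
    n <- nrow(Zin)
    Garr <- array(t(G), c(gh, gw, 32L, n))
    t1 <- .convtF(Garr, p$dcK1, p$dcB1, 2L); a1 <- .reluF(t1$Y)
    t2 <- .convtF(a1, p$dcK2, p$dcB2, 2L);   a2 <- .reluF(t2$Y)
    t3 <- .convtF(a2, p$dcK3, p$dcB3, 2L)
    Xh <- .sigmoidF(t3$Y)
    list(Xhat = Xh,
         cache = list(Zin = Zin, G = G, Garr = Garr, t1 = t1, a1 = a1,
                      t2 = t2, a2 = a2, t3 = t3, n = n))
  }
}

# Backward pass; dXhat has the shape of Xhat. Returns gradient list plus dZ.
.vaeDecodeB <- function(p, config, fwd, dXhat) {
  g <- list()
  if (config$variant == "mlp") {
    dZ3 <- .sigmoidB(fwd$Xhat, dXhat)
    b3 <- .denseB(fwd$cache$D2, p$outW, dZ3)
    g$outW <- b3$dW; g$outB <- b3$db
    dD2 <- .reluB(fwd$cache$D2, b3$dX)
    b2 <- .denseB(fwd$cache$D1, p$decW2, dD2)
    g$decW2 <- b2$dW; g$decB2 <- b2$db
    dD1 <- .reluB(fwd$cache$D1, b2$dX)
    b1 <- .denseB(fwd$cache$Z, p$decW1, dD1)
    g$decW1 <- b1$dW; g$decB1 <- b1$db
    list(grads = g, dZ = b1$dX)
  } else {
    cc <- fwd$cache
    dT3 <- .sigmoidB(fwd$Xhat, dXhat)
    b3 <- .convtB(cc$t3$cache, p$dcK3, dT3)
    g$dcK3 <- b3$dK; g$dcB3 <- b3$db
    dA2 <- .reluB(cc$a2, b3$dX)
    b2 <- .convtB(cc$t2$cache, p$dcK2, dA2)
    g$dcK2 <- b2$dK; g$dcB2 <- b2$db
    dA1 <- .reluB(cc$a1, b2$dX)
    b1 <- .convtB(cc$t1$cache, p$dcK1, dA1)
    g$dcK1 <- b1$dK; g$dcB1 <- b1$db
    dG <- .reluB(cc$G, t(matrix(b1$dX, ncol = cc$n)))
    bd <- .denseB(cc$Zin, p$decW, dG)
    g$decW <- bd$dW; g$decB <- bd$db
    dZ <- bd$dX[, seq_len(config$latentDim), drop = FALSE]
    list(grads = g, dZ = dZ)
  }
}

.vaeEncodeB <- function(p, config, fwd, dMu, dLv) {
  g <- list()
  cc <- fwd$cache
  if (config$variant == "mlp") {
    bm <- .denseB(cc$H2, p$muW, dMu)
    bl <- .denseB(cc$H2, p$lvW, dLv)
    g$muW <- bm$dW; g$muB <- bm$db
    g$lvW <- bl$dW; g$lvB <- bl$db
    dH2 <- .reluB(cc$H2, bm$dX + bl$dX)
    b2 <- .denseB(cc$H1, p$encW2, dH2)
    g$encW2 <- b2$dW; g$encB2 <- b2$db
    dH1 <- .reluB(cc$H1, b2$dX)
    b1 <- .denseB(cc$X, p$encW1, dH1)
    g$encW1 <- b1$dW; g$encB1 <- b1$db
  } else {
    nd <- length(config$encDense)
    top <- if (nd > 0) cc$hs[[nd]] else cc$flat
    bm <- .denseB(top, p$muW, dMu)
    bl <- .denseB(top, p$lvW, dLv)
    g$muW <- bm$dW; g$muB <- bm$db
    g$lvW <- bl$dW; g$lvB <- bl$db
    dH <- bm$dX + bl$dX
    for (i in rev(seq_len(nd))) {
      dH <- .reluB(cc$hs[[i]], dH)
      below <- if (i > 1) cc$hs[[i - 1]] else cc$flat
      bi <- .denseB(below, p[[paste0("encW", i)]], dH)
      g[[paste0("encW", i)]] <- bi$dW
      g[[paste0("encB", i)]] <- bi$db
      dH <- bi$dX
    }
    dA2 <- array(t(dH), dim(cc$a2))
    dC2 <- .reluB(cc$c2$Y, dA2)
    b2 <- .convB(cc$c2$cache, p$convK2, dC2)
    g$convK2 <- b2$dK; g$convB2 <- b2$db
    dC1 <- .reluB(cc$c1$Y, b2$dX)
    b1 <- .convB(cc$c1$cache, p$convK1, dC1)
    g$convK1 <- b1$dK; g$convB1 <- b1$db
  }
  g
}

# ---- public operations -----------------------------------------------------

#' Reparameterization trick
#'
#' Draws `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)` from the
#' current R RNG, keeping the latent draw differentiable in `mu` and
#' `logvar`.
#'
#' @param mu,logvar Numeric vectors or matrices (rows = samples) of equal
#'   shape.
#' @return Latent draw of the same shape.
#' @export
reparameterize <- function(mu, logvar) {
  stopifnot(all(dim(as.matrix(mu)) == dim(as.matrix(logvar))))
  eps <- stats::rnorm(length(mu))
  mu + exp(logvar / 2) * (if (is.matrix(mu)) matrix(eps, nrow(mu)) else eps)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' `0.5 * sum_i(mu_i^2 + exp(logvar_i) - 1 - logvar_i)`, which is zero
#' exactly when the encoder output is the standard normal. For matrix
#' input the per-sample divergences are averaged.
#'
#' @param mu,logvar Numeric vectors, or matrices with rows = samples.
#' @return Non-negative scalar.
#' @export
klDivergence <- function(mu, logvar) {
  if (is.null(dim(mu))) mu <- matrix(mu, 1)          # one sample, dim d
  if (is.null(dim(logvar))) logvar <- matrix(logvar, 1)
  per <- 0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  mean(per)
}

#' Negative evidence lower bound for a spectrogram batch
#'
#' Reconstruction error (squared error summed over pixels, averaged over
#' the batch) plus `beta` times the KL divergence of the encoder output.
#'
#' @param x Input spectrogram(s): matrix or array; `xhat` must match.
#' @param xhat Reconstruction.
#' @param mu,logvar Encoder outputs (rows = samples for batches).
#' @param beta KL weight (default 1).
#' @return Scalar loss.
#' @export
vaeLoss <- function(x, xhat, mu, logvar, beta = 1) {
  if (!identical(dim(x), dim(xhat)) && length(x) != length(xhat)) {
    stop("x and xhat shapes differ")
  }
  n <- if (is.matrix(mu)) nrow(mu) else 1L
  recon <- sum((x - xhat)^2) / n
  recon + beta * klDivergence(mu, logvar)
}

# Stack a MelSpecSet into the tensor a variant consumes.
.stackSpecs <- function(specSet, variant) {
  specs <- specMatrices(specSet)
  n <- length(specs)
  p <- specParams(specSet)
  if (variant == "mlp") {
    t(vapply(specs, as.vector, numeric(p$nMels * p$frames)))
  } else {
    X <- array(0, c(p$nMels, p$frames, 1L, n))
    for (i in seq_len(n)) X[, , 1L, i] <- specs[[i]]
    X
  }
}

.vaeForwardLoss <- function(p, config, Xb, labels1h = NULL) {
  enc <- .vaeEncodeF(p, config, Xb, labels1h)
  Z <- reparameterize(enc$mu, enc$logvar)
  dec <- .vaeDecodeF(p, config, Z, labels1h)
  n <- nrow(enc$mu)
  recon <- sum((Xb - dec$Xhat)^2) / n
  kl <- klDivergence(enc$mu, enc$logvar)
  list(enc = enc, Z = Z, dec = dec,
       loss = recon + config$beta * kl, recon = recon, kl = kl)
}

.vaeBackward <- function(p, config, Xb, fwd, labels1h = NULL) {
  n <- nrow(fwd$enc$mu)
  dXhat <- 2 * (fwd$dec$Xhat - Xb) / n
  decB <- .vaeDecodeB(p, config, fwd$dec, dXhat)
  eps <- (fwd$Z - fwd$enc$mu) / exp(fwd$enc$logvar / 2)
  dMu <- decB$dZ + config$beta * fwd$enc$mu / n
  dLv <- decB$dZ * eps * 0.5 * exp(fwd$enc$logvar / 2) +
    config$beta * 0.5 * (exp(fwd$enc$logvar) - 1) / n
  encB <- .vaeEncodeB(p, config, fwd$enc, dMu, dLv)
  c(decB$grads, encB)
}

#' Train a variational autoencoder
#'
#' Unconditional variants (`mlp`, `cnn`) must be given spectrograms of a
#' single minority class — one model instance is trained per class, so an
#' instance never sees or emits another class. The conditional variant is
#' trained on all minority classes jointly, with the class supplied as a
#' one-hot condition. Training minimises the negative evidence lower
#' bound ([vaeLoss()]) by minibatch gradient descent with the configured
#' optimizer; given a seed the run is fully deterministic.
#'
#' @param specSet A [MelSpecSet-class] of training spectrograms.
#' @param config A [vaeConfig()] whose `inputDim` matches the spectrograms.
#' @param classLevels For the conditional variant, the label vocabulary in
#'   one-hot order (default [minorityLabels()]).
#' @param verbose Print the loss every 10 epochs.
#' @return A [TrainedVAE-class] object.
#' @export
trainVae <- function(specSet, config, classLevels = minorityLabels(),
                     verbose = FALSE) {
  stopifnot(inherits(config, "vaeConfig"))
  if (nSpecs(specSet) == 0) stop("empty training set")
  sp <- specParams(specSet)
  if (!all(config$inputDim == c(sp$nMels, sp$frames))) {
    stop("config inputDim (", paste(config$inputDim, collapse = "x"),
         ") does not match spectrograms (", sp$nMels, "x", sp$frames, ")")
  }
  labels <- specLabels(specSet)
  if (config$variant %in% c("mlp", "cnn")) {
    uni <- unique(labels)
    if (length(uni) > 1) {
      stop("unconditional VAE requires a single class; got: ",
           paste(uni, collapse = ", "))
    }
    if (uni == "COPD") {
      stop("unconditional VAE instances model minority classes; ",
           "majority class COPD rejected")
    }
    classLabel <- uni
    labels1hAll <- NULL
  } else {
    if (length(unique(labels)) < 2) {
      warning("conditional VAE trained on a single class")
    }
    bad <- setdiff(unique(labels), classLevels)
    if (length(bad) > 0) stop("labels outside classLevels: ",
                              paste(bad, collapse = ", "))
    classLabel <- NA_character_
    labels1hAll <- .oneHot(match(labels, classLevels), config$nClasses)
  }

  set.seed(config$seed)
  model <- buildVae(config)
  p <- model$params
  state <- .optimInit(p)
  Xall <- .stackSpecs(specSet, config$variant)
  n <- nSpecs(specSet)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    for (start in seq(1L, n, config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      Xb <- if (config$variant == "mlp") {
        Xall[idx, , drop = FALSE]
      } else {
        Xall[, , , idx, drop = FALSE]
      }
      l1h <- if (!is.null(labels1hAll)) {
        labels1hAll[idx, , drop = FALSE]
      } else NULL
      fwd <- .vaeForwardLoss(p, config, Xb, l1h)
      grads <- .vaeBackward(p, config, Xb, fwd, l1h)
      upd <- .optimStep(config$optimizer, p, grads, state,
                        config$learningRate)
      p <- upd$params; state <- upd$state
      epochLoss <- epochLoss + fwd$loss * length(idx)
    }
    history[ep] <- epochLoss / n
    if (verbose && ep %% 10L == 0L) {
      message("epoch ", ep, " loss ", signif(history[ep], 5))
    }
  }
  new("TrainedVAE", variant = config$variant, config = unclass(config),
      params = p, history = history, classLabel = classLabel)
}

#' Reconstruct spectrograms with a trained VAE
#' @param vae A [TrainedVAE-class].
#' @param specSet Input [MelSpecSet-class].
#' @param classLevels One-hot vocabulary for the conditional variant.
#' @return List of reconstructed matrices in `[0, 1]`.
#' @export
vaeReconstruct <- function(vae, specSet, classLevels = minorityLabels()) {
  config <- structure(vae@config, class = "vaeConfig")
  Xb <- .stackSpecs(specSet, config$variant)
  l1h <- if (config$variant == "conditional") {
    .oneHot(match(specLabels(specSet), classLevels), config$nClasses)
  } else NULL
  enc <- .vaeEncodeF(vae@params, config, Xb, l1h)
  dec <- .vaeDecodeF(vae@params, config, enc$mu, l1h)
  .unstackSpecs(dec$Xhat, config, nSpecs(specSet))
}

.unstackSpecs <- function(Xhat, config, n) {
  H <- config$inputDim[1]; W <- config$inputDim[2]
  if (config$variant == "mlp") {
    lapply(seq_len(n), function(i) matrix(Xhat[i, ], H, W))
  } else {
    lapply(seq_len(n), function(i) matrix(Xhat[, , 1L, i], H, W))
  }
}

#' Sample synthetic spectrograms from a trained VAE
#'
#' Draws latent vectors from the standard normal prior and decodes them.
#' For the conditional variant a class label selects the one-hot condition;
#' unconditional instances emit their own training class.
#'
#' @param vae A [TrainedVAE-class].
#' @param n Number of samples (> 0).
#' @param classLabel Class to generate (required for the conditional
#'   variant; must be absent or equal to the instance class otherwise).
#' @param classLevels One-hot vocabulary for the conditional variant.
#' @param params Mel front-end parameter list to attach to the output set.
#' @return A [MelSpecSet-class] with `n` spectrograms labeled `classLabel`.
#' @export
generateSamples <- function(vae, n, classLabel = NULL,
                            classLevels = minorityLabels(),
                            params) {
  if (n <= 0) stop("n must be positive")
  config <- structure(vae@config, class = "vaeConfig")
  if (config$variant == "conditional") {
    if (is.null(classLabel)) stop("conditional VAE needs a classLabel")
    l1h <- .oneHot(rep(match(classLabel, classLevels), n), config$nClasses)
  } else {
    if (!is.null(classLabel) && classLabel != vae@classLabel) {
      stop("unconditional instance models class ", vae@classLabel)
    }
    classLabel <- vae@classLabel
    l1h <- NULL
  }
  Z <- matrix(stats::rnorm(n * config$latentDim), n)
  dec <- .vaeDecodeF(vae@params, config, Z, l1h)
  specs <- .unstackSpecs(dec$Xhat, config, n)
  specs <- lapply(specs, function(s) pmin(pmax(s, 0), 1))
  params$nMels <- config$inputDim[1]
  params$frames <- config$inputDim[2]
  MelSpecSet(specs, rep(classLabel, n), params)
}

#' Downscale every spectrogram in a set by block averaging
#' @param specSet A [MelSpecSet-class].
#' @param rowFactor,colFactor Integer block sizes.
#' @return A [MelSpecSet-class] at the reduced resolution.
#' @export
downscaleSpecSet <- function(specSet, rowFactor, colFactor) {
  p <- specParams(specSet)
  p$nMels <- p$nMels %/% rowFactor
  p$frames <- p$frames %/% colFactor
  MelSpecSet(lapply(specMatrices(specSet), downscaleSpec, rowFactor,
                    colFactor),
             specLabels(specSet), p)
}

#' Upscale every spectrogram in a set by nearest-neighbour replication
#' @param specSet A [MelSpecSet-class].
#' @param rowFactor,colFactor Integer replication factors.
#' @return A [MelSpecSet-class] at the enlarged resolution.
#' @export
upscaleSpecSet <- function(specSet, rowFactor, colFactor) {
  p <- specParams(specSet)
  p$nMels <- p$nMels * rowFactor
  p$frames <- p$frames * colFactor
  MelSpecSet(lapply(specMatrices(specSet), upscaleSpec, rowFactor,
                    colFactor),
             specLabels(specSet), p)
}
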