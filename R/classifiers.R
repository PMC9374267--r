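# Five MFCC-based classifiers: a deep MLP, a small CNN, a two-layer LSTM,
# and two transfer-learning-style models whose convolutional backbones are
# frozen feature extractors with trainable dense heads. Without pretrained
# weights the backbones are randomly initialised (deterministically from the
# configuration seed) and kept frozen, acting as fixed random-feature
# extractors; only the heads are trained.

#' Classifier configuration
#'
#' Defaults follow the study configuration: seven output classes, softmax
#' output, categorical cross-entropy, Adam with learning rate 1e-4, 100
#' epochs, three trials. Layer widths are configurable so a reduced preset
#' can be used for fast experiments.
#'
#' @param arch One of `"mlp"`, `"cnn"`, `"lstm"`, `"resnet50"`,
#'   `"efficientnetb0"`.
#' @param nClasses Number of output classes (default 7).
#' @param classLevels Label vocabulary in output order.
#' @param learningRate Adam step size (default 1e-4).
#' @param epochs Training epochs per trial (default 100).
#' @param batchSize Minibatch size.
#' @param nTrials Independent trainings with seeds `seed + trial`.
#' @param seed Base seed.
#' @param mlpHidden,mlpDropout MLP hidden widths (7 layers, default
#'   512/512/512/1024/512/512/512) and per-layer dropout rates (10-40%).
#' @param cnnFilters,cnnKernels,cnnDense CNN convolution filters (2 layers),
#'   kernel sizes, and dense widths (64/128/128/64).
#' @param lstmUnits,lstmDense,timeStride LSTM layer widths (64/128), dense
#'   widths (64/256/128), and a frame-subsampling stride for the sequence.
#' @param resnetChannels,resnetOut,resnetDense,resnetDropout Residual
#'   backbone stage channels, output feature width (2048), head widths
#'   (256/128/64/512/512/512) and dropout rates (10-30%).
#' @param effnetChannels,effnetDense,effnetDropout Efficient-style backbone
#'   stage channels (five stride-2 stages ending at 1280 channels, so a
#'   13 x 130 input flattens to 6400), head widths (256/128/64), dropout.
#' @return A list of class `"clfConfig"`.
#' @export
clfConfig <- function(arch = c("mlp", "cnn", "lstm", "resnet50",
                               "efficientnetb0"),
                      nClasses = 7L, classLevels = classifierLabels(),
                      learningRate = 1e-4, epochs = 100L, batchSize = 32L,
                      nTrials = 3L, seed = 1L,
                      mlpHidden = c(512L, 512L, 512L, 1024L, 512L, 512L, 512L),
                      mlpDropout = c(0.1, 0.2, 0.3, 0.4, 0.3, 0.2, 0.1),
                      cnnFilters = c(32L, 32L), cnnKernels = c(3L, 2L),
                      cnnDense = c(64L, 128L, 128L, 64L),
                      lstmUnits = c(64L, 128L),
                      lstmDense = c(64L, 256L, 128L), timeStride = 1L,
                      resnetChannels = c(32L, 64L, 128L, 256L),
                      resnetOut = 2048L,
                      resnetDense = c(256L, 128L, 64L, 512L, 512L, 512L),
                      resnetDropout = c(0.1, 0.15, 0.2, 0.25, 0.3, 0.3),
                      effnetChannels = c(16L, 24L, 40L, 112L, 1280L),
                      effnetDense = c(256L, 128L, 64L),
                      effnetDropout = 0.5) {
  arch <- match.arg(arch)
  stopifnot(learningRate > 0, nClasses >= 2, length(classLevels) == nClasses)
  structure(as.list(environment()), class = "clfConfig")
}

# ---- dense stack shared by all heads ---------------------------------------

.stackInit <- function(nin, hidden, nout) {
  p <- list()
  prev <- nin
  for (i in seq_along(hidden)) {
    p[[paste0("W", i)]] <- .heDense(prev, hidden[i])
    p[[paste0("b", i)]] <- numeric(hidden[i])
    prev <- hidden[i]
  }
  p$Wout <- .heDense(prev, nout)
  p$bout <- numeric(nout)
  p
}

.stackF <- function(p, X, nHidden, dropout = NULL, train = FALSE) {
  hs <- vector("list", nHidden)
  masks <- vector("list", nHidden)
  H <- X
  for (i in seq_len(nHidden)) {
    H <- .reluF(.denseF(H, p[[paste0("W", i)]], p[[paste0("b", i)]]))
    if (train && !is.null(dropout) && dropout[i] > 0) {
      masks[[i]] <- .dropoutMask(dim(H), dropout[i])
      H <- H * masks[[i]]
    }
    hs[[i]] <- H
  }
  list(logits = .denseF(H, p$Wout, p$bout), hs = hs, masks = masks, X = X)
}

.stackB <- function(p, fwd, dLogits, nHidden) {
  g <- list()
  top <- if (nHidden > 0) fwd$hs[[nHidden]] else fwd$X
  bo <- .denseB(top, p$Wout, dLogits)
  g$Wout <- bo$dW; g$bout <- bo$db
  dH <- bo$dX
  for (i in rev(seq_len(nHidden))) {
    if (!is.null(fwd$masks[[i]])) dH <- dH * fwd$masks[[i]]
    # relu backward against the pre-dropout activation sign: activation is
    # zero exactly where the pre-activation was negative, so hs works here
    act <- fwd$hs[[i]]
    dH <- .reluB(act, dH)
    below <- if (i > 1) fwd$hs[[i - 1]] else fwd$X
    bi <- .denseB(below, p[[paste0("W", i)]], dH)
    g[[paste0("W", i)]] <- bi$dW
    g[[paste0("b", i)]] <- bi$db
    dH <- bi$dX
  }
  list(grads = g, dX = dH)
}

# ---- frozen backbones ------------------------------------------------------

.resnetBackboneInit <- function(config) {
  ch <- config$resnetChannels
  p <- list()
  cin <- 1L
  for (s in seq_along(ch)) {
    p[[paste0("downK", s)]] <- .heConv(3L, 3L, cin, ch[s])
    p[[paste0("downB", s)]] <- numeric(ch[s])
    p[[paste0("resK", s)]] <- .heConv(3L, 3L, ch[s], ch[s])
    p[[paste0("resB", s)]] <- numeric(ch[s])
    cin <- ch[s]
  }
  p$projK <- .heConv(1L, 1L, cin, config$resnetOut)
  p$projB <- numeric(config$resnetOut)
  p
}

.resnetBackboneF <- function(p, config, X) {
  A <- X
  for (s in seq_along(config$resnetChannels)) {
    A <- .reluF(.convF(A, p[[paste0("downK", s)]], p[[paste0("downB", s)]],
                       2L, "same")$Y)
    R <- .convF(A, p[[paste0("resK", s)]], p[[paste0("resB", s)]],
                1L, "same")$Y
    A <- .reluF(A + R)                                   # identity shortcut
  }
  A <- .reluF(.convF(A, p$projK, p$projB, 1L, "same")$Y)
  d <- dim(A)
  t(vapply(seq_len(d[4]), function(i) {       # global average pool
    colMeans(matrix(A[, , , i], d[1] * d[2], d[3]))
  }, numeric(d[3])))
}

.effnetBackboneInit <- function(config) {
  ch <- config$effnetChannels
  p <- list()
  cin <- 1L
  for (s in seq_along(ch)) {
    p[[paste0("K", s)]] <- .heConv(3L, 3L, cin, ch[s])
    p[[paste0("B", s)]] <- numeric(ch[s])
    cin <- ch[s]
  }
  p
}

.effnetBackboneF <- function(p, config, X) {
  A <- X
  for (s in seq_along(config$effnetChannels)) {
    A <- .reluF(.convF(A, p[[paste0("K", s)]], p[[paste0("B", s)]],
                       2L, "same")$Y)
  }
  d <- dim(A)
  t(matrix(A, d[1] * d[2] * d[3], d[4]))                 # flatten
}

# Run a frozen backbone over a dataset in chunks to bound memory.
.backboneFeatures <- function(arch, p, config, Xarr, chunk = 64L) {
  n <- dim(Xarr)[4]
  out <- NULL
  for (start in seq(1L, n, chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Xi <- Xarr[, , , idx, drop = FALSE]
    Fi <- if (arch == "resnet50") .resnetBackboneF(p, config, Xi)
          else .effnetBackboneF(p, config, Xi)
    out <- rbind(out, Fi)
  }
  out
}

# ---- input preparation -----------------------------------------------------

# Per-coefficient standardization statistics over a training set of MFCCs.
# Networks receive coefficients spanning orders of magnitude (c0 dominates);
# a fitted normalization layer puts them on a common scale, playing the role
# of the batch-normalization layers of the reference architectures.
.mfccRowStats <- function(mfccs) {
  M <- do.call(cbind, mfccs)
  list(mean = rowMeans(M), sd = pmax(apply(M, 1, stats::sd), 1e-6))
}

.applyRowStd <- function(mfccs, std) {
  lapply(mfccs, function(m) (m - std$mean) / std$sd)
}

.mfccTensor <- function(mfccs) {
  d <- dim(mfccs[[1]])
  n <- length(mfccs)
  X <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) X[, , 1L, i] <- mfccs[[i]]
  X
}

.mfccSeq <- function(mfccs, timeStride = 1L) {
  d <- dim(mfccs[[1]])
  tIdx <- seq(1L, d[2], timeStride)
  n <- length(mfccs)
  X <- array(0, c(n, length(tIdx), d[1]))
  for (i in seq_len(n)) X[i, , ] <- t(mfccs[[i]][, tIdx, drop = FALSE])
  X
}

.mfccFlat <- function(mfccs) {
  t(vapply(mfccs, as.vector, numeric(length(mfccs[[1]]))))
}

#' Build an untrained classifier
#'
#' Initialises the architecture for the configured variant. For the two
#' backbone architectures the (frozen) backbone weights are drawn
#' deterministically from the configuration seed.
#'
#' @param config A [clfConfig()].
#' @param inputDim MFCC dimensions `c(nCoef, nFrames)` (default
#'   `c(13, 130)`).
#' @param initSeed Seed for weight initialisation (defaults to the
#'   configuration seed; trials use `seed + trial`).
#' @return A list with `config`, `inputDim`, trainable `params`, and for
#'   backbone variants `backbone` weights.
#' @export
buildClassifier <- function(config, inputDim = c(13L, 130L),
                            initSeed = config$seed) {
  stopifnot(inherits(config, "clfConfig"))
  set.seed(initSeed)
  K <- config$nClasses
  model <- list(config = config, inputDim = inputDim)
  if (config$arch == "mlp") {
    model$params <- .stackInit(prod(inputDim), config$mlpHidden, K)
  } else if (config$arch == "cnn") {
    f <- config$cnnFilters; k <- config$cnnKernels
    p <- list(cK1 = .heConv(k[1], k[1], 1L, f[1]), cb1 = numeric(f[1]),
              cK2 = .heConv(k[2], k[2], f[1], f[2]), cb2 = numeric(f[2]))
    h1 <- inputDim[1] - k[1] + 1L; w1 <- inputDim[2] - k[1] + 1L
    h1 <- (h1 - 2L) %/% 2L + 1L;   w1 <- (w1 - 2L) %/% 2L + 1L
    h2 <- h1 - k[2] + 1L;          w2 <- w1 - k[2] + 1L
    h2 <- (h2 - 2L) %/% 2L + 1L;   w2 <- (w2 - 2L) %/% 2L + 1L
    model$flatDim <- h2 * w2 * f[2]
    model$params <- c(p, .stackInit(model$flatDim, config$cnnDense, K))
  } else if (config$arch == "lstm") {
    u <- config$lstmUnits
    d <- inputDim[1]
    p <- list(Wx1 = .heDense(d, 4L * u[1]), Wh1 = .heDense(u[1], 4L * u[1]),
              bl1 = numeric(4L * u[1]),
              Wx2 = .heDense(u[1], 4L * u[2]),
              Wh2 = .heDense(u[2], 4L * u[2]), bl2 = numeric(4L * u[2]))
    model$params <- c(p, .stackInit(u[2], config$lstmDense, K))
  } else if (config$arch == "resnet50") {
    model$backbone <- .resnetBackboneInit(config)
    model$params <- .stackInit(config$resnetOut, config$resnetDense, K)
  } else {
    model$backbone <- .effnetBackboneInit(config)
    nStages <- length(config$effnetChannels)
    oh <- inputDim[1]; ow <- inputDim[2]
    for (s in seq_len(nStages)) { oh <- ceiling(oh / 2); ow <- ceiling(ow / 2) }
    model$flatDim <- oh * ow * utils::tail(config$effnetChannels, 1)
    model$params <- .stackInit(model$flatDim, config$effnetDense, K)
  }
  model
}

# Forward pass to logits for prepared input `prep`; train toggles dropout.
.clfForward <- function(model, p, prep, train = FALSE) {
  cfg <- model$config
  arch <- cfg$arch
  if (arch == "mlp") {
    .stackF(p, prep, length(cfg$mlpHidden),
            if (train) cfg$mlpDropout else NULL, train)
  } else if (arch == "cnn") {
    c1 <- .convF(prep, p$cK1, p$cb1, 1L, "valid"); a1 <- .reluF(c1$Y)
    p1 <- .pool2F(a1)
    c2 <- .convF(p1$Y, p$cK2, p$cb2, 1L, "valid"); a2 <- .reluF(c2$Y)
    p2 <- .pool2F(a2)
    n <- dim(prep)[4]
    flat <- t(matrix(p2$Y, ncol = n))
    st <- .stackF(p, flat, length(cfg$cnnDense), NULL, train)
    c(st, list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2))
  } else if (arch == "lstm") {
    l1 <- .lstmF(prep, p$Wx1, p$Wh1, p$bl1)
    l2 <- .lstmF(l1$H, p$Wx2, p$Wh2, p$bl2)
    Tn <- dim(prep)[2]
    last <- matrix(l2$H[, Tn, ], dim(prep)[1])
    st <- .stackF(p, last, length(cfg$lstmDense), NULL, train)
    c(st, list(l1 = l1, l2 = l2, Tn = Tn, Xin = prep))
  } else {
    # prep is the (standardized) frozen-backbone feature matrix
    hidden <- if (arch == "resnet50") cfg$resnetDense else cfg$effnetDense
    drop <- if (arch == "resnet50") cfg$resnetDropout
            else rep(0, length(cfg$effnetDense))
    X <- prep
    inMask <- NULL
    if (train && arch == "efficientnetb0" && cfg$effnetDropout > 0) {
      inMask <- .dropoutMask(dim(X), cfg$effnetDropout)
      X <- X * inMask
    }
    st <- .stackF(p, X, length(hidden), if (train) drop else NULL, train)
    c(st, list(inMask = inMask))
  }
}

.clfBackward <- function(model, p, fwd, dLogits) {
  cfg <- model$config
  arch <- cfg$arch
  if (arch == "mlp") {
    .stackB(p, fwd, dLogits, length(cfg$mlpHidden))$grads
  } else if (arch == "cnn") {
    sb <- .stackB(p, fwd, dLogits, length(cfg$cnnDense))
    n <- nrow(dLogits)
    dP2 <- array(t(sb$dX), dim(fwd$p2$Y))
    dA2 <- .pool2B(fwd$p2$cache, dP2)
    dC2 <- .reluB(fwd$c2$Y, dA2)
    b2 <- .convB(fwd$c2$cache, p$cK2, dC2)
    dA1 <- .pool2B(fwd$p1$cache, b2$dX)
    dC1 <- .reluB(fwd$c1$Y, dA1)
    b1 <- .convB(fwd$c1$cache, p$cK1, dC1)
    c(sb$grads, list(cK1 = b1$dK, cb1 = b1$db, cK2 = b2$dK, cb2 = b2$db))
  } else if (arch == "lstm") {
    sb <- .stackB(p, fwd, dLogits, length(cfg$lstmDense))
    dH2 <- array(0, dim(fwd$l2$H))
    dH2[, fwd$Tn, ] <- sb$dX
    b2 <- .lstmB(fwd$l1$H, p$Wx2, p$Wh2, p$bl2, fwd$l2, dH2)
    b1 <- .lstmB(fwd$Xin, p$Wx1, p$Wh1, p$bl1, fwd$l1, b2$dX)
    c(sb$grads, list(Wx1 = b1$dWx, Wh1 = b1$dWh, bl1 = b1$db,
                     Wx2 = b2$dWx, Wh2 = b2$dWh, bl2 = b2$db))
  } else {
    hidden <- if (arch == "resnet50") cfg$resnetDense else cfg$effnetDense
    .stackB(p, fwd, dLogits, length(hidden))$grads
  }
}

# Prepare the model-specific input representation for a list of MFCCs.
.clfPrep <- function(model, mfccs, standardize = NULL, inputStd = NULL) {
  cfg <- model$config
  arch <- cfg$arch
  if (!is.null(inputStd)) mfccs <- .applyRowStd(mfccs, inputStd)
  if (arch == "mlp") {
    .mfccFlat(mfccs)
  } else if (arch == "cnn") {
    .mfccTensor(mfccs)
  } else if (arch == "lstm") {
    .mfccSeq(mfccs, cfg$timeStride)
  } else {
    Feat <- .backboneFeatures(arch, model$backbone, cfg, .mfccTensor(mfccs))
    if (!is.null(standardize)) {
      Feat <- sweep(sweep(Feat, 2, standardize$mean), 2, standardize$sd, "/")
    }
    Feat
  }
}

#' Train a classifier on labeled MFCC matrices
#'
#' Runs `nTrials` independent trainings (seeds `seed + trial`) of the
#' configured architecture with minibatch Adam and categorical
#' cross-entropy. For the backbone architectures the frozen features are
#' standardized with statistics of the training set (the batch-normalization
#' surrogate) before entering the trainable head.
#'
#' @param mfccs List of MFCC matrices (all the same shape).
#' @param labels Character labels, one per matrix; every class in
#'   `config$classLevels` must be present.
#' @param config A [clfConfig()].
#' @param verbose Print the loss each 5 epochs.
#' @return A [TrainedClassifier-class].
#' @export
trainClassifier <- function(mfccs, labels, config, verbose = FALSE) {
  stopifnot(inherits(config, "clfConfig"), length(mfccs) == length(labels))
  missing <- setdiff(config$classLevels, unique(labels))
  if (length(missing) > 0) {
    stop("class(es) absent from training data: ",
         paste(missing, collapse = ", "))
  }
  y <- match(labels, config$classLevels)
  if (anyNA(y)) stop("labels outside classLevels")
  model <- buildClassifier(config, dim(mfccs[[1]]))
  isBackbone <- config$arch %in% c("resnet50", "efficientnetb0")
  std <- NULL
  inputStd <- .mfccRowStats(mfccs)
  prepRaw <- .clfPrep(model, mfccs, inputStd = inputStd)
  if (isBackbone) {
    std <- list(mean = colMeans(prepRaw),
                sd = pmax(apply(prepRaw, 2, stats::sd), 1e-6))
    prepRaw <- sweep(sweep(prepRaw, 2, std$mean), 2, std$sd, "/")
  }
  n <- length(mfccs)
  trials <- vector("list", config$nTrials)
  for (tr in seq_len(config$nTrials)) {
    m <- buildClassifier(config, dim(mfccs[[1]]),
                         initSeed = config$seed + tr)
    p <- m$params
    state <- .optimInit(p)
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epLoss <- 0
      for (start in seq(1L, n, config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1L, n)]
        Xb <- .subsetPrep(prepRaw, idx, config$arch)
        fwd <- .clfForward(model, p, Xb, train = TRUE)
        sm <- .softmaxXent(fwd$logits, y[idx])
        grads <- .clfBackward(model, p, fwd, sm$dZ)
        upd <- .adamStep(p, grads, state, config$learningRate)
        p <- upd$params; state <- upd$state
        epLoss <- epLoss + sm$loss * length(idx)
      }
      history[ep] <- epLoss / n
      if (verbose && ep %% 5L == 0L) {
        message(config$arch, " trial ", tr, " epoch ", ep, " loss ",
                signif(history[ep], 4))
      }
    }
    trials[[tr]] <- list(params = p, history = history, standardize = std)
  }
  out <- new("TrainedClassifier", arch = config$arch,
             config = unclass(config), trials = trials,
             labels = config$classLevels)
  attr(out, "backbone") <- model$backbone
  attr(out, "inputDim") <- dim(mfccs[[1]])
  attr(out, "inputStd") <- inputStd
  out
}

.subsetPrep <- function(prep, idx, arch) {
  if (arch %in% c("mlp", "resnet50", "efficientnetb0")) {
    prep[idx, , drop = FALSE]
  } else if (arch == "cnn") {
    prep[, , , idx, drop = FALSE]
  } else {
    prep[idx, , , drop = FALSE]
  }
}

#' Predict class probabilities for MFCC matrices
#'
#' @param clf A [TrainedClassifier-class].
#' @param mfccs List of MFCC matrices.
#' @param trial Which trial's weights to use (default 1).
#' @return A list with `prob` (n x nClasses matrix, rows sum to 1) and
#'   `labels` (argmax class per row).
#' @export
predictClassifier <- function(clf, mfccs, trial = 1L) {
  config <- structure(clf@config, class = "clfConfig")
  model <- list(config = config, inputDim = attr(clf, "inputDim"),
                backbone = attr(clf, "backbone"))
  trialFit <- clf@trials[[trial]]
  prep <- .clfPrep(model, mfccs, standardize = trialFit$standardize,
                   inputStd = attr(clf, "inputStd"))
  fwd <- .clfForward(model, trialFit$params, prep, train = FALSE)
  P <- .softmax(fwd$logits)
  list(prob = P, labels = clf@labels[max.col(P, ties.method = "first")])
}

#' Count trainable parameters of a classifier
#' @param model Result of [buildClassifier()].
#' @return Integer number of trainable weights (frozen backbones excluded).
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
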