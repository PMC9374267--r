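# Quality metrics for synthetic audio: Frechet audio distance over pluggable
# embedders, normalized cross-correlation at lag zero, and mel cepstral
# distortion after dynamic-time-warping alignment.

# ---- embedder registry -----------------------------------------------------

.embedderRegistry <- new.env(parent = emptyenv())

#' Register an audio embedder
#'
#' An embedder maps a waveform to a fixed-length numeric vector; the
#' Frechet audio distance compares Gaussian fits to such embeddings. The
#' built-in `"melstats"` embedder is self-contained and deterministic:
#' per-mel-band log-energy mean and standard deviation over 0.96-s windows
#' (output length `2 * nMels`). External embedding models (e.g. a VGGish
#' network) can be plugged in behind the same interface.
#'
#' @param name Embedder name.
#' @param fn Function `(waveform, sampleRate) -> numeric vector`.
#' @return `name`, invisibly.
#' @export
registerEmbedder <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .embedderRegistry)
  invisible(name)
}

#' List registered embedders
#' @return Character vector of names.
#' @export
listEmbedders <- function() ls(.embedderRegistry)

.melstatsEmbedder <- function(nMels = 32L) {
  function(wave, sampleRate) {
    win <- round(0.96 * sampleRate)
    hop <- win %/% 2L
    if (length(wave) < win) wave <- c(wave, numeric(win - length(wave)))
    nWin <- 1L + (length(wave) - win) %/% hop
    fb <- melFilterbank(nMels, 2048L, sampleRate)
    E <- matrix(0, nMels, nWin)
    for (k in seq_len(nWin)) {
      seg <- wave[((k - 1L) * hop + 1L):((k - 1L) * hop + win)]
      p <- Mod(stats::fft(c(seg * .hann(win))[seq_len(win)]))^2
      # fold the periodogram onto the 2048-bin grid by linear interpolation
      fr <- (0:(win %/% 2L)) * sampleRate / win
      grid <- (0:1024) * sampleRate / 2048
      p2 <- stats::approx(fr, p[seq_len(win %/% 2L + 1L)], grid,
                          rule = 2)$y
      E[, k] <- log(pmax(fb %*% p2, 1e-10))
    }
    c(rowMeans(E), apply(E, 1, function(r) {
      if (length(r) > 1) stats::sd(r) else 0
    }))
  }
}

#' Embed a waveform
#'
#' @param wave Numeric waveform of at least one second.
#' @param sampleRate Sample rate in Hz.
#' @param embedder Registered embedder name (default `"melstats"`).
#' @return Numeric embedding vector.
#' @export
embedAudio <- function(wave, sampleRate = 22050L, embedder = "melstats") {
  if (!exists(embedder, envir = .embedderRegistry)) {
    stop("unknown embedder '", embedder, "'; registered: ",
         paste(listEmbedders(), collapse = ", "))
  }
  if (length(wave) < sampleRate) stop("need at least 1 s of audio to embed")
  get(embedder, envir = .embedderRegistry)(wave, sampleRate)
}

# the default self-contained embedder is registered at load time
registerEmbedder("melstats", .melstatsEmbedder())

#' Gaussian statistics of a set of embeddings
#' @param E Matrix, rows = embeddings (at least 2).
#' @return List with `mu` (mean vector), `sigma` (covariance), `n`.
#' @export
embeddingStats <- function(E) {
  stopifnot(is.matrix(E), nrow(E) >= 2)
  list(mu = colMeans(E), sigma = stats::cov(E), n = nrow(E))
}

# Symmetric PSD matrix square root via eigendecomposition; small negative
# eigenvalues (numerical) are clipped at zero.
.sqrtmPsd <- function(M, tol = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values), 1))) {
    warning("matrix has significantly negative eigenvalues; clipping")
  }
  v <- sqrt(pmax(e$values, 0))
  e$vectors %*% (v * t(e$vectors))
}

#' Frechet distance between two Gaussians
#'
#' `||mu_r - mu_g||^2 + tr(S_r + S_g - 2 (S_r S_g)^{1/2})`, the 2-Wasserstein
#' distance between Gaussian fits; zero iff the two Gaussians coincide.
#'
#' @param real,gen Lists with `mu` and `sigma` (see [embeddingStats()]).
#' @return Non-negative scalar.
#' @export
frechetDistance <- function(real, gen) {
  if (length(real$mu) != length(gen$mu)) stop("embedding dimensions differ")
  Sr <- as.matrix(real$sigma); Sg <- as.matrix(gen$sigma)
  A <- .sqrtmPsd(Sr)
  covTerm <- sum(diag(Sr)) + sum(diag(Sg)) -
    2 * sum(diag(.sqrtmPsd(A %*% Sg %*% A)))
  max(sum((real$mu - gen$mu)^2) + covTerm, 0)
}

#' Frechet audio distance per class
#'
#' Embeds real and synthetic segments of each class, fits Gaussians, and
#' reports the per-class Frechet distance plus the unweighted mean over
#' classes.
#'
#' @param real,synthetic [AudioSegments-class] objects (>= 2 segments per
#'   class on each side).
#' @param embedder Registered embedder name.
#' @param classes Classes to evaluate (default: classes present in
#'   `synthetic`).
#' @return List with `perClass` (named numeric) and `mean`.
#' @export
fadPerClass <- function(real, synthetic, embedder = "melstats",
                        classes = sort(unique(segmentLabels(synthetic)))) {
  rl <- segmentLabels(real); sl <- segmentLabels(synthetic)
  out <- numeric(length(classes))
  names(out) <- classes
  embedAll <- function(waves, sr) {
    t(vapply(waves, embedAudio,
             embedAudio(waves[[1]], sr, embedder),
             sampleRate = sr, embedder = embedder))
  }
  for (cls in classes) {
    ri <- which(rl == cls); si <- which(sl == cls)
    if (length(ri) < 2 || length(si) < 2) {
      stop("class ", cls, " needs >= 2 segments on both sides")
    }
    Er <- embedAll(segmentWaves(real)[ri], real@sampleRate)
    Eg <- embedAll(segmentWaves(synthetic)[si], synthetic@sampleRate)
    out[cls] <- frechetDistance(embeddingStats(Er), embeddingStats(Eg))
  }
  list(perClass = out, mean = mean(out))
}

#' Normalized cross-correlation at lag zero
#'
#' Pearson correlation of two equal-length signals after mean removal:
#' `sum(x y) / sqrt(sum(x^2) sum(y^2))`, in `[-1, 1]`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`; zero-energy input gives 0 with a warning.
#' @export
ncc <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- x - mean(x); y <- y - mean(y)
  ex <- sum(x^2); ey <- sum(y^2)
  if (ex == 0 || ey == 0) {
    warning("zero-energy signal in cross-correlation; returning 0")
    return(0)
  }
  sum(x * y) / sqrt(ex * ey)
}

#' Cross-correlation summary between synthetic and real classes
#'
#' Samples up to `nPerClass` synthetic and real segments per class; for
#' each sampled synthetic segment the maximum correlation over the sampled
#' real segments of a class is taken, and the per-(synthetic class, real
#' class) mean and standard deviation of these maxima are reported.
#'
#' @param real,synthetic [AudioSegments-class] objects.
#' @param nPerClass Sample size per class and side (default 50; classes
#'   with fewer segments contribute all of them).
#' @param seed Integer seed for the sampling.
#' @param classes Classes to evaluate.
#' @return List of matrices `mean` and `sd` (rows = synthetic class,
#'   columns = real class), plus `n` used per class.
#' @export
ccMatrix <- function(real, synthetic, nPerClass = 50L, seed = 1L,
                     classes = sort(unique(segmentLabels(synthetic)))) {
  rl <- segmentLabels(real); sl <- segmentLabels(synthetic)
  set.seed(seed)
  sampleIdx <- function(idx) {
    if (length(idx) == 0) stop("empty class in cross-correlation sampling")
    if (length(idx) > nPerClass) sort(sample(idx, nPerClass)) else idx
  }
  synIdx <- lapply(classes, function(cl) sampleIdx(which(sl == cl)))
  realIdx <- lapply(classes, function(cl) sampleIdx(which(rl == cl)))
  names(synIdx) <- names(realIdx) <- classes
  M <- S <- matrix(NA_real_, length(classes), length(classes),
                   dimnames = list(synthetic = classes, real = classes))
  for (sc in classes) {
    for (rc in classes) {
      best <- vapply(synIdx[[sc]], function(i) {
        max(vapply(realIdx[[rc]], function(j) {
          ncc(segmentWaves(synthetic)[[i]], segmentWaves(real)[[j]])
        }, numeric(1)))
      }, numeric(1))
      M[sc, rc] <- mean(best)
      S[sc, rc] <- stats::sd(best)
    }
  }
  list(mean = M, sd = S,
       n = vapply(synIdx, length, integer(1)))
}

#' Dynamic time warping alignment cost
#'
#' Full-window dynamic programming with the symmetric step pattern
#' (diagonal, up, left) under Euclidean frame distance.
#'
#' @param A,B Matrices, columns = frames.
#' @return List with `path` (2-column matrix of aligned frame indices) and
#'   `dist` (total accumulated distance along the path).
#' @export
dtwAlign <- function(A, B) {
  n <- ncol(A); m <- ncol(B)
  # local distance matrix, vectorized: d[i,j] = ||A[,i] - B[,j]||
  aa <- colSums(A^2); bb <- colSums(B^2)
  D2 <- outer(aa, bb, "+") - 2 * crossprod(A, B)
  D <- sqrt(pmax(D2, 0))
  C <- matrix(Inf, n + 1L, m + 1L)
  C[1, 1] <- 0
  for (i in seq_len(n)) {
    C[i + 1L, 2L:(m + 1L)] <- D[i, ] +
      pmin(C[i, 1L:m], C[i, 2L:(m + 1L)], Inf)
    # left moves within the row must be done sequentially
    for (j in seq_len(m)) {
      C[i + 1L, j + 1L] <- min(C[i + 1L, j + 1L], C[i + 1L, j] + D[i, j])
    }
  }
  # backtrack
  path <- matrix(0L, 0L, 2L)
  i <- n; j <- m
  repeat {
    path <- rbind(c(i, j), path)
    if (i == 1L && j == 1L) break
    choices <- c(if (i > 1 && j > 1) C[i, j] else Inf,
                 if (i > 1) C[i, j + 1L] else Inf,
                 if (j > 1) C[i + 1L, j] else Inf)
    k <- which.min(choices)
    if (k == 1L) { i <- i - 1L; j <- j - 1L }
    else if (k == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(path = path, dist = C[n + 1L, m + 1L])
}

#' Mel cepstral distortion with DTW alignment
#'
#' Aligns the two cepstral sequences by dynamic time warping (Euclidean
#' distance on coefficients 2..13, excluding the energy coefficient by
#' default) and averages the scaled per-pair distances:
#' `(10 sqrt(2) / ln 10) * mean_t ||C_t - Chat_t||`.
#'
#' @param realMfcc,synMfcc MFCC matrices (coefficients x frames, >= 2
#'   frames).
#' @param excludeC0 Drop the first (energy) coefficient (default TRUE).
#' @param align Use DTW alignment (default TRUE); otherwise frames are
#'   paired in order (sequences must then have equal length).
#' @return Non-negative scalar.
#' @export
mcd <- function(realMfcc, synMfcc, excludeC0 = TRUE, align = TRUE) {
  stopifnot(ncol(realMfcc) >= 2, ncol(synMfcc) >= 2)
  A <- if (excludeC0) realMfcc[-1, , drop = FALSE] else realMfcc
  B <- if (excludeC0) synMfcc[-1, , drop = FALSE] else synMfcc
  const <- 10 * sqrt(2) / log(10)
  if (align) {
    al <- dtwAlign(A, B)
    d <- sqrt(colSums((A[, al$path[, 1], drop = FALSE] -
                       B[, al$path[, 2], drop = FALSE])^2))
  } else {
    stopifnot(ncol(A) == ncol(B))
    d <- sqrt(colSums((A - B)^2))
  }
  const * mean(d)
}

#' Per-class mel cepstral distortion summary
#'
#' Samples up to `nPerClass` synthetic and real segments per class and
#' reports the mean and standard deviation of the DTW-aligned MCD over all
#' (synthetic, real) pairs within each class.
#'
#' @param realMfccs,synMfccs Lists of MFCC matrices with a `"labels"`
#'   attribute (see [mfccSet()]), or plain lists plus explicit labels.
#' @param realLabels,synLabels Labels (default taken from attributes).
#' @param nPerClass Per-class sample size (default 50).
#' @param seed Sampling seed.
#' @param classes Classes to evaluate.
#' @return Data frame with columns `class`, `mean`, `sd`, `nPairs`.
#' @export
mcdSummary <- function(realMfccs, synMfccs,
                       realLabels = attr(realMfccs, "labels"),
                       synLabels = attr(synMfccs, "labels"),
                       nPerClass = 50L, seed = 1L,
                       classes = sort(unique(synLabels))) {
  set.seed(seed)
  rows <- lapply(classes, function(cls) {
    ri <- which(realLabels == cls); si <- which(synLabels == cls)
    if (length(ri) == 0 || length(si) == 0) stop("empty class: ", cls)
    if (length(ri) > nPerClass) ri <- sort(sample(ri, nPerClass))
    if (length(si) > nPerClass) si <- sort(sample(si, nPerClass))
    vals <- as.vector(vapply(si, function(i) {
      vapply(ri, function(j) mcd(realMfccs[[j]], synMfccs[[i]]), numeric(1))
    }, numeric(length(ri))))
    data.frame(class = cls, mean = mean(vals), sd = stats::sd(vals),
               nPairs = length(vals))
  })
  do.call(rbind, rows)
}
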