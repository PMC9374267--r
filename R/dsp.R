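# Signal-processing primitives shared by the feature and evaluation modules.
# All transforms are deterministic; randomness (Griffin-Lim phase init) is
# drawn from the caller-controlled R RNG.

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

.reflectPad <- function(x, pad) {
  n <- length(x)
  if (pad >= n) {  # degenerate short signal: fall back to zero padding
    return(c(numeric(pad), x, numeric(pad)))
  }
  c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
}

#' Short-time Fourier transform
#'
#' Centered STFT with a Hann window and reflection padding, matching the
#' framing convention `nFrames = 1 + floor(length(x) / hop)`.
#'
#' @param x Numeric waveform.
#' @param nFft FFT size (window length).
#' @param hop Hop length in samples.
#' @return Complex matrix of dimension `(nFft/2 + 1) x nFrames`.
#' @export
stft <- function(x, nFft = 2048L, hop = 512L) {
  nFrames <- 1L + floor(length(x) / hop)
  xp <- .reflectPad(x, nFft %/% 2L)
  idx <- outer(seq_len(nFft), (seq_len(nFrames) - 1L) * hop, "+")
  frames <- matrix(xp[idx], nrow = nFft) * .hann(nFft)
  S <- stats::mvfft(frames)
  S[seq_len(nFft %/% 2L + 1L), , drop = FALSE]
}

#' Inverse short-time Fourier transform
#'
#' Overlap-add inversion of a half-spectrum produced by [stft()], with
#' squared-window normalization.
#'
#' @param S Complex matrix `(nFft/2 + 1) x nFrames`.
#' @param hop Hop length in samples.
#' @param length Output length in samples (the original waveform length).
#' @return Numeric waveform of `length` samples.
#' @export
istft <- function(S, hop = 512L, length) {
  nFft <- (nrow(S) - 1L) * 2L
  nFrames <- ncol(S)
  full <- rbind(S, Conj(S[(nFft %/% 2L):2L, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / nFft
  w <- .hann(nFft)
  frames <- frames * w
  outLen <- (nFrames - 1L) * hop + nFft
  y <- numeric(outLen)
  wsum <- numeric(outLen)
  w2 <- w^2
  for (t in seq_len(nFrames)) {
    at <- (t - 1L) * hop
    rng <- (at + 1L):(at + nFft)
    y[rng] <- y[rng] + frames[, t]
    wsum[rng] <- wsum[rng] + w2
  }
  y <- y / pmax(wsum, 1e-8)
  pad <- nFft %/% 2L
  y <- y[(pad + 1L):(pad + length)]
  y
}

#' Mel filterbank matrix
#'
#' Triangular filters on an HTK-style mel axis
#' (`mel = 2595 log10(1 + f/700)`), spanning 0 Hz to `fmax`.
#'
#' @param nMels Number of mel bands.
#' @param nFft FFT size the filterbank applies to.
#' @param sampleRate Sample rate in Hz.
#' @param fmax Upper frequency edge (default Nyquist).
#' @return Matrix `nMels x (nFft/2 + 1)`.
#' @export
melFilterbank <- function(nMels = 128L, nFft = 2048L, sampleRate = 22050L,
                          fmax = sampleRate / 2) {
  hzToMel <- function(f) 2595 * log10(1 + f / 700)
  melToHz <- function(m) 700 * (10^(m / 2595) - 1)
  nBins <- nFft %/% 2L + 1L
  freqs <- (seq_len(nBins) - 1L) * sampleRate / nFft
  edges <- melToHz(seq(hzToMel(0), hzToMel(fmax), length.out = nMels + 2L))
  fb <- matrix(0, nMels, nBins)
  for (m in seq_len(nMels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / max(ce - lo, 1e-12)
    down <- (hi - freqs) / max(hi - ce, 1e-12)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Center frequencies of the mel filterbank bands
#' @inheritParams melFilterbank
#' @return Numeric vector of `nMels` band-center frequencies in Hz.
#' @export
melCenterFrequencies <- function(nMels = 128L, sampleRate = 22050L,
                                 fmax = sampleRate / 2) {
  hzToMel <- function(f) 2595 * log10(1 + f / 700)
  melToHz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- melToHz(seq(hzToMel(0), hzToMel(fmax), length.out = nMels + 2L))
  edges[2:(nMels + 1L)]
}

#' Mel power spectrogram
#'
#' STFT power routed through a mel filterbank; no log or normalization.
#'
#' @inheritParams stft
#' @param nMels Number of mel bands.
#' @param sampleRate Sample rate in Hz.
#' @return Matrix `nMels x nFrames` of non-negative band powers.
#' @export
melPower <- function(x, nFft = 2048L, hop = 512L, nMels = 128L,
                     sampleRate = 22050L) {
  S <- stft(x, nFft, hop)
  p <- Mod(S)^2
  melFilterbank(nMels, nFft, sampleRate) %*% p
}

#' Griffin-Lim phase reconstruction
#'
#' Iteratively estimates a phase consistent with a magnitude spectrogram and
#' returns the time-domain signal. Phase is initialised uniformly at random
#' from the current RNG; call `set.seed()` for reproducibility.
#'
#' @param mag Magnitude spectrogram `(nFft/2 + 1) x nFrames`.
#' @param hop Hop length in samples.
#' @param length Output length in samples.
#' @param nIter Number of Griffin-Lim iterations (default 32).
#' @return Numeric waveform of `length` samples.
#' @export
griffinLim <- function(mag, hop = 512L, length, nIter = 32L) {
  phase <- matrix(stats::runif(base::length(mag), -pi, pi),
                  nrow(mag), ncol(mag))
  S <- mag * exp(1i * phase)
  for (k in seq_len(nIter)) {
    x <- istft(S, hop, length)
    Sx <- stft(x, (nrow(mag) - 1L) * 2L, hop)
    if (ncol(Sx) > ncol(mag)) Sx <- Sx[, seq_len(ncol(mag)), drop = FALSE]
    ang <- Sx / pmax(Mod(Sx), 1e-12)
    S <- mag * ang
  }
  istft(S, hop, length)
}

# Batched Griffin-Lim over a list of equal-sized magnitude spectrograms.
# The per-iteration STFT/ISTFT work is shared across the batch so the R
# overhead (framing, overlap-add, allocation) is amortized.
.griffinLimBatch <- function(mags, hop, length, nIter = 32L) {
  B <- base::length(mags)
  half <- nrow(mags[[1]]); Tf <- ncol(mags[[1]])
  nFft <- (half - 1L) * 2L
  pad <- nFft %/% 2L
  w <- .hann(nFft); w2 <- w^2
  magMat <- matrix(unlist(mags), half, Tf * B)
  mirror <- (nFft %/% 2L):2L
  outFull <- (Tf - 1L) * hop + nFft
  wsum <- numeric(outFull)
  for (t in seq_len(Tf)) {
    at <- (t - 1L) * hop
    wsum[(at + 1L):(at + nFft)] <- wsum[(at + 1L):(at + nFft)] + w2
  }
  wsum <- pmax(wsum, 1e-8)
  plen <- length + nFft
  Tf2 <- 1L + floor(length / hop)
  idx <- outer(seq_len(nFft), (seq_len(min(Tf2, Tf)) - 1L) * hop, "+")
  idxVec <- as.vector(idx)

  # overlap-add grouping: frames whose start offsets differ by a multiple
  # of nFft do not overlap, so when hop divides nFft the add reduces to
  # nFft/hop shifted block assignments
  fastOla <- nFft %% hop == 0L
  olaK <- if (fastOla) nFft %/% hop else 0L
  istftAll <- function(S) {           # S: half x (Tf*B) complex
    Ffull <- matrix(0i, nFft, Tf * B)
    Ffull[seq_len(half), ] <- S
    Ffull[(half + 1L):nFft, ] <- Conj(S[mirror, , drop = FALSE])
    fr <- Re(stats::mvfft(Ffull, inverse = TRUE)) / nFft * w
    Y <- matrix(0, outFull, B)
    if (fastOla) {
      arr <- array(fr, c(nFft, Tf, B))
      for (r in seq_len(olaK)) {
        sel <- seq(r, Tf, olaK)
        off <- (r - 1L) * hop
        len <- nFft * base::length(sel)
        blk <- matrix(arr[, sel, ], len, B)
        Y[(off + 1L):(off + len), ] <- Y[(off + 1L):(off + len), ] + blk
      }
    } else {
      arr <- array(fr, c(nFft, Tf, B))
      for (t in seq_len(Tf)) {
        rng <- ((t - 1L) * hop + 1L):((t - 1L) * hop + nFft)
        Y[rng, ] <- Y[rng, ] + arr[, t, ]
      }
    }
    Y <- Y / wsum
    Y[(pad + 1L):(pad + length), , drop = FALSE]
  }
  Tf2 <- ncol(idx)
  keepCols <- as.vector(outer(seq_len(Tf), (seq_len(B) - 1L) * Tf2, "+"))
  stftAll <- function(Ymat) {         # Ymat: length x B
    top <- Ymat[(pad + 1L):2L, , drop = FALSE]
    bot <- Ymat[(length - 1L):(length - pad), , drop = FALSE]
    Xp <- rbind(top, Ymat, bot)
    FR <- matrix(Xp[idxVec, ], nFft) * w
    S <- stats::mvfft(FR)
    S[seq_len(half), keepCols, drop = FALSE]
  }

  phase <- matrix(stats::runif(half * Tf * B, -pi, pi), half)
  S <- magMat * exp(1i * phase)
  for (k in seq_len(nIter)) {
    y <- istftAll(S)
    Sx <- stftAll(y)
    S <- magMat * (Sx / pmax(Mod(Sx), 1e-12))
  }
  y <- istftAll(S)
  lapply(seq_len(B), function(i) y[, i])
}

#' Orthonormal DCT-II matrix
#' @param nOut Number of output coefficients (rows).
#' @param nIn Input length (columns).
#' @return Matrix `nOut x nIn`; rows are orthonormal DCT-II basis functions.
#' @export
dctMatrix <- function(nOut, nIn) {
  k <- 0:(nOut - 1)
  n <- 0:(nIn - 1)
  D <- sqrt(2 / nIn) * cos(pi * outer(k, (2 * n + 1) / (2 * nIn)))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Welch power spectral density estimate
#'
#' Averaged Hann-windowed periodograms over 50%-overlapping segments.
#'
#' @param x Numeric waveform.
#' @param sampleRate Sample rate in Hz.
#' @param nFft Segment/FFT length.
#' @return List with `freq` (Hz) and `psd` (linear power), length
#'   `nFft/2 + 1`.
#' @export
welchPsd <- function(x, sampleRate, nFft = 1024L) {
  hop <- nFft %/% 2L
  nSeg <- max(1L, 1L + (length(x) - nFft) %/% hop)
  w <- .hann(nFft)
  acc <- numeric(nFft %/% 2L + 1L)
  for (s in seq_len(nSeg)) {
    seg <- x[((s - 1L) * hop + 1L):((s - 1L) * hop + nFft)]
    seg[is.na(seg)] <- 0
    X <- stats::fft(seg * w)
    acc <- acc + Mod(X[seq_len(nFft %/% 2L + 1L)])^2
  }
  list(freq = (0:(nFft %/% 2L)) * sampleRate / nFft, psd = acc / nSeg)
}

# Moore-Penrose pseudo-inverse via SVD (used for mel inversion).
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
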