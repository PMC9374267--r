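#' Mel-spectrogram front-end parameters
#'
#' Defaults follow the analysis configuration: 2048-sample windows hopped by
#' 512, 128 mel bins, 22050 Hz. A 6-s segment yields `1 + floor(132300/512)
#' = 259` raw frames, trimmed to 256 trailing-first so the spectrogram is
#' divisible by 8 for the stride-2 convolutional stacks. `normMin`/`normMax`
#' are dataset-level log-power bounds fitted on the VAE training set only
#' ([fitMelNormalization()]).
#'
#' @param nFft FFT/window size.
#' @param hop Hop length in samples.
#' @param nMels Number of mel bins.
#' @param sampleRate Sample rate in Hz.
#' @param frames Frame count after trimming.
#' @param logFloor Power floor applied before the log (silence padding
#'   produces exact zeros).
#' @param normMin,normMax Dataset-level normalization bounds (`NA` until
#'   fitted).
#' @return A named list of parameters.
#' @export
melSpecParams <- function(nFft = 2048L, hop = 512L, nMels = 128L,
                          sampleRate = 22050L, frames = 256L,
                          logFloor = 1e-10, normMin = NA_real_,
                          normMax = NA_real_) {
  list(nFft = as.integer(nFft), hop = as.integer(hop),
       nMels = as.integer(nMels), sampleRate = as.integer(sampleRate),
       frames = as.integer(frames), logFloor = logFloor,
       normMin = normMin, normMax = normMax)
}

# Raw (un-normalized) log-power mel matrix, trimmed to params$frames.
.logMelRaw <- function(wave, params) {
  p <- melPower(wave, params$nFft, params$hop, params$nMels,
                params$sampleRate)
  p <- log(pmax(p, params$logFloor))
  if (ncol(p) < params$frames) {
    stop("waveform too short: ", ncol(p), " frames < ", params$frames)
  }
  p[, seq_len(params$frames), drop = FALSE]
}

#' Fit dataset-level mel normalization bounds
#'
#' Computes the global minimum and maximum of the log-power mel values over
#' a training set and stores them in the parameter list. Normalization is
#' fitted on the VAE training set only and reused for every later
#' transform, so no test-set information leaks into the generative models.
#'
#' @param segments An [AudioSegments-class] training set.
#' @param params A [melSpecParams()] list.
#' @return `params` with `normMin` and `normMax` filled in.
#' @export
fitMelNormalization <- function(segments, params = melSpecParams()) {
  stopifnot(nSegments(segments) > 0)
  lo <- Inf; hi <- -Inf
  for (w in segmentWaves(segments)) {
    m <- .logMelRaw(w, params)
    lo <- min(lo, min(m)); hi <- max(hi, max(m))
  }
  if (hi <= lo) stop("degenerate dataset: zero normalization range")
  params$normMin <- lo
  params$normMax <- hi
  params
}

#' Normalized log-mel spectrogram of one segment
#'
#' STFT power, mel filterbank, floored log, then min-max scaling into
#' `[0, 1]` with the dataset-level bounds; values outside the fitted range
#' are clipped.
#'
#' @param wave Numeric waveform of at least `frames * hop` samples.
#' @param params A [melSpecParams()] list with fitted `normMin`/`normMax`.
#' @return Matrix `nMels x frames` with entries in `[0, 1]`.
#' @export
melSpectrogram <- function(wave, params) {
  if (is.na(params$normMin) || is.na(params$normMax)) {
    stop("normalization bounds not fitted; call fitMelNormalization() first")
  }
  m <- .logMelRaw(wave, params)
  m <- (m - params$normMin) / (params$normMax - params$normMin)
  pmin(pmax(m, 0), 1)
}

#' Mel spectrograms for a whole segment set
#'
#' @param segments An [AudioSegments-class] object.
#' @param params Fitted [melSpecParams()].
#' @return A [MelSpecSet-class].
#' @export
melSpectrogramSet <- function(segments, params) {
  specs <- lapply(segmentWaves(segments), melSpectrogram, params = params)
  MelSpecSet(specs, segmentLabels(segments), params)
}

#' Invert a normalized mel spectrogram to audio
#'
#' De-normalizes, exponentiates, maps mel power back to the linear-frequency
#' STFT grid through the filterbank pseudo-inverse (clipped at zero), and
#' runs Griffin-Lim phase estimation. The inverted signal covers
#' `frames * hop` samples and is zero-padded to `targetLength` so it can
#' re-enter the segment pipeline.
#'
#' @param spec Matrix `nMels x frames` in `[0, 1]`.
#' @param params Fitted [melSpecParams()].
#' @param nIter Griffin-Lim iterations (default 32).
#' @param targetLength Output length in samples (default 6 s worth).
#' @return Numeric waveform of `targetLength` samples.
#' @export
invertMelSpec <- function(spec, params, nIter = 32L,
                          targetLength = 6L * params$sampleRate) {
  stopifnot(nrow(spec) == params$nMels, ncol(spec) == params$frames)
  L <- spec * (params$normMax - params$normMin) + params$normMin
  P <- exp(L)
  fb <- melFilterbank(params$nMels, params$nFft, params$sampleRate)
  stftPower <- pmax(.pinv(fb) %*% P, 0)
  mag <- sqrt(stftPower)
  n <- params$frames * params$hop
  x <- griffinLim(mag, params$hop, length = n, nIter = nIter)
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  if (targetLength > n) x <- c(x, numeric(targetLength - n))
  x[seq_len(targetLength)]
}

#' Invert a whole set of mel spectrograms to audio segments
#'
#' Batched counterpart of [invertMelSpec()]: spectrograms are inverted in
#' chunks with a shared Griffin-Lim loop, which is substantially faster
#' than one-at-a-time inversion.
#'
#' @param specSet A [MelSpecSet-class] at the full front-end resolution.
#' @param nIter Griffin-Lim iterations.
#' @param targetLength Output samples per segment (default 6 s worth).
#' @param chunk Spectrograms per Griffin-Lim batch.
#' @return An [AudioSegments-class] with one waveform per spectrogram.
#' @export
invertMelSpecSet <- function(specSet, nIter = 32L,
                             targetLength = NULL, chunk = 8L) {
  params <- specParams(specSet)
  if (is.null(targetLength)) targetLength <- 6L * params$sampleRate
  fb <- melFilterbank(params$nMels, params$nFft, params$sampleRate)
  fbPinv <- .pinv(fb)
  specs <- specMatrices(specSet)
  n <- length(specs)
  glLen <- params$frames * params$hop
  waves <- vector("list", n)
  for (start in seq(1L, n, chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    mags <- lapply(specs[idx], function(s) {
      L <- s * (params$normMax - params$normMin) + params$normMin
      sqrt(pmax(fbPinv %*% exp(L), 0))
    })
    ys <- .griffinLimBatch(mags, params$hop, glLen, nIter)
    for (k in seq_along(idx)) {
      x <- ys[[k]]
      peak <- max(abs(x))
      if (peak > 1) x <- x / peak
      if (targetLength > glLen) x <- c(x, numeric(targetLength - glLen))
      waves[[idx[k]]] <- x[seq_len(targetLength)]
    }
  }
  AudioSegments(waves, specLabels(specSet), sampleRate = params$sampleRate)
}

#' MFCC matrix of one segment
#'
#' 13 mel-frequency cepstral coefficients per frame: floored log of
#' 128-band mel power followed by an orthonormal DCT-II. The 1024-sample hop
#' makes a 6-s segment yield exactly 130 frames, so the classifier input is
#' 13 x 130.
#'
#' @param wave Numeric waveform (132300 samples for the standard segment).
#' @param sampleRate Sample rate in Hz.
#' @param nMfcc Number of cepstral coefficients (default 13).
#' @param nFft FFT size (default 2048).
#' @param hop Hop length (default 1024).
#' @param nMels Mel bands for the intermediate filterbank (default 128).
#' @param logFloor Power floor before the log.
#' @return Matrix `nMfcc x nFrames`.
#' @export
mfcc <- function(wave, sampleRate = 22050L, nMfcc = 13L, nFft = 2048L,
                 hop = 1024L, nMels = 128L, logFloor = 1e-10) {
  p <- melPower(wave, nFft, hop, nMels, sampleRate)
  lm <- log(pmax(p, logFloor))
  dctMatrix(nMfcc, nMels) %*% lm
}

#' MFCC matrices for a segment set
#' @param segments An [AudioSegments-class] object.
#' @param ... Passed to [mfcc()].
#' @return List of `13 x 130` matrices, with labels as the `"labels"`
#'   attribute.
#' @export
mfccSet <- function(segments, ...) {
  out <- lapply(segmentWaves(segments), mfcc,
                sampleRate = segments@sampleRate, ...)
  attr(out, "labels") <- segmentLabels(segments)
  out
}

#' 39-dimensional MFCC summary feature
#'
#' Concatenates, in order, the per-coefficient mean, per-coefficient
#' standard deviation, and per-coefficient mean frame-to-frame first
#' difference of an MFCC matrix: `13 + 13 + 13 = 39` values.
#'
#' @param m An MFCC matrix (coefficients x frames, at least 2 frames).
#' @return Numeric vector of length `3 * nrow(m)`.
#' @export
summary39 <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  c(rowMeans(m), apply(m, 1, stats::sd), rowMeans(d))
}

#' PCA projection of summary features
#'
#' Mean-centered principal component analysis (no scaling) of a feature
#' matrix, as used to visualise real against synthetic audio in 2-D.
#'
#' @param features Numeric matrix, rows = observations (at least 3).
#' @param nComponents Number of components to keep (default 2).
#' @return List with `scores` (n x nComponents), `explainedVariance`
#'   (eigenvalues of the sample covariance, all components), `rotation`,
#'   and `center`.
#' @export
pcaProject <- function(features, nComponents = 2L) {
  stopifnot(is.matrix(features), nrow(features) >= 3)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explainedVariance = pc$sdev^2,
       rotation = pc$rotation, center = pc$center)
}

#' Reconstruct features from a PCA projection
#' @param pca Result of [pcaProject()].
#' @param nComponents Number of components to use.
#' @return Reconstructed feature matrix.
#' @export
pcaReconstruct <- function(pca, nComponents) {
  k <- nComponents
  pc <- pca$scores[, seq_len(min(k, ncol(pca$scores))), drop = FALSE]
  rot <- pca$rotation[, seq_len(ncol(pc)), drop = FALSE]
  sweep(pc %*% t(rot), 2, pca$center, "+")
}

#' Block-average downscaling of a spectrogram
#' @param m Matrix whose dimensions are divisible by the factors.
#' @param rowFactor,colFactor Integer block sizes.
#' @return Matrix `nrow(m)/rowFactor x ncol(m)/colFactor` of block means.
#' @export
downscaleSpec <- function(m, rowFactor, colFactor) {
  stopifnot(nrow(m) %% rowFactor == 0, ncol(m) %% colFactor == 0)
  nr <- nrow(m) %/% rowFactor
  nc <- ncol(m) %/% colFactor
  out <- matrix(0, nr, nc)
  for (i in seq_len(rowFactor)) {
    for (j in seq_len(colFactor)) {
      out <- out + m[seq(i, nrow(m), rowFactor), seq(j, ncol(m), colFactor)]
    }
  }
  out / (rowFactor * colFactor)
}

#' Nearest-neighbour upscaling of a spectrogram
#' @param m Matrix.
#' @param rowFactor,colFactor Integer replication factors.
#' @return Matrix `nrow(m)*rowFactor x ncol(m)*colFactor`.
#' @export
upscaleSpec <- function(m, rowFactor, colFactor) {
  m[rep(seq_len(nrow(m)), each = rowFactor),
    rep(seq_len(ncol(m)), each = colFactor)]
}
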