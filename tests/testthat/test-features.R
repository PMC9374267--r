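# Fitted parameters shared across the spectrogram tests.
toneSegs <- AudioSegments(list(sixSecondSegment(440), sixSecondSegment(880)),
                          c("URTI", "URTI"))
fittedParams <- fitMelNormalization(toneSegs, melSpecParams())

test_that("the mel front end yields 259 raw frames trimmed to 256", {
  w <- sixSecondSegment(440)
  expect_equal(ncol(stft(w)), 259)               # 1 + floor(132300/512)
  spec <- melSpectrogram(w, fittedParams)
  expect_equal(dim(spec), c(128, 256))
  expect_gte(min(spec), 0)
  expect_lte(max(spec), 1)
})

test_that("a pure tone concentrates mel energy in its band", {
  spec <- melSpectrogram(sixSecondSegment(440), fittedParams)
  centers <- melCenterFrequencies()
  expectBin <- which.min(abs(centers - 440))
  expect_lte(abs(which.max(rowMeans(spec)) - expectBin), 1)
})

test_that("silence maps to a constant spectrogram at the normalized floor", {
  spec <- melSpectrogram(numeric(132300), fittedParams)
  expect_equal(max(spec) - min(spec), 0)
  expect_equal(spec[1, 1], 0)    # log floor clips to the lower bound
})

test_that("normalization must be fitted and non-degenerate", {
  expect_error(melSpectrogram(sixSecondSegment(440), melSpecParams()),
               "not fitted")
  silent <- AudioSegments(list(numeric(132300)), "URTI")
  expect_error(fitMelNormalization(silent, melSpecParams()), "degenerate")
})

test_that("mel inversion restores the dominant frequency of a tone", {
  spec <- melSpectrogram(sixSecondSegment(440), fittedParams)
  set.seed(2)
  x <- invertMelSpec(spec, fittedParams, nIter = 16)
  expect_length(x, 132300)
  ps <- welchPsd(x[1:131072], 22050, nFft = 2048)
  peak <- ps$freq[which.max(ps$psd)]
  centers <- melCenterFrequencies()
  binWidth <- diff(centers)[which.min(abs(centers - 440))]
  expect_lt(abs(peak - 440), binWidth + 22050 / 2048)
})

test_that("an all-floor spectrogram inverts to near-silence", {
  spec <- matrix(0, 128, 256)
  set.seed(3)
  x <- invertMelSpec(spec, fittedParams, nIter = 4)
  rms <- sqrt(mean(x[1:131072]^2))
  expect_lt(20 * log10(max(rms, 1e-12)), -40)
})

test_that("mel round-trip error is small and stable", {
  spec <- melSpectrogram(sixSecondSegment(440), fittedParams)
  set.seed(4)
  x <- invertMelSpec(spec, fittedParams, nIter = 16)
  spec2 <- melSpectrogram(x, fittedParams)
  expect_lt(mean(abs(spec2 - spec)), 0.08)
})

test_that("batched and single mel inversion agree on spectral content", {
  ms <- melSpectrogramSet(toneSegs, fittedParams)
  set.seed(5)
  segs <- invertMelSpecSet(ms, nIter = 8)
  expect_equal(nSegments(segs), 2)
  ps <- welchPsd(segmentWaves(segs)[[2]][1:131072], 22050, nFft = 2048)
  expect_lt(abs(ps$freq[which.max(ps$psd)] - 880), 60)
})

test_that("MFCC matrices are 13 x 130 and constant inputs give zero higher coefficients", {
  m <- mfcc(sixSecondSegment(440))
  expect_equal(dim(m), c(13, 130))
  ms <- mfcc(numeric(132300))
  expect_lt(max(abs(ms[2:13, ])), 1e-9)          # DCT of a constant
})

test_that("MFCC agrees with a naive per-frame reference implementation", {
  sr <- 22050L; nFft <- 256L; hop <- 256L; nMels <- 16L; nMfcc <- 5L
  set.seed(8)
  x <- stats::rnorm(1024) * 0.2
  got <- mfcc(x, sr, nMfcc, nFft, hop, nMels)

  # reference: explicit framing, DFT by matrix product, hand-built mel
  # triangles, log, and an explicit cosine-sum DCT
  pad <- nFft %/% 2
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  nFrames <- 1 + floor(length(x) / hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(nFft - 1)) / nFft)
  W <- exp(-2i * pi * outer(0:(nFft - 1), 0:(nFft - 1)) / nFft)
  hzToMel <- function(f) 2595 * log10(1 + f / 700)
  melToHz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- melToHz(seq(0, hzToMel(sr / 2), length.out = nMels + 2))
  freqs <- (0:(nFft / 2)) * sr / nFft
  ref <- matrix(0, nMfcc, nFrames)
  for (t in seq_len(nFrames)) {
    frame <- xp[((t - 1) * hop + 1):((t - 1) * hop + nFft)] * hann
    spec <- as.vector(W %*% frame)
    p <- Mod(spec[1:(nFft / 2 + 1)])^2
    melE <- numeric(nMels)
    for (m in seq_len(nMels)) {
      wts <- pmax(0, pmin((freqs - edges[m]) / (edges[m + 1] - edges[m]),
                          (edges[m + 2] - freqs) /
                            (edges[m + 2] - edges[m + 1])))
      melE[m] <- sum(wts * p)
    }
    lm <- log(pmax(melE, 1e-10))
    for (k in 0:(nMfcc - 1)) {
      sk <- if (k == 0) sqrt(1 / nMels) else sqrt(2 / nMels)
      ref[k + 1, t] <- sk * sum(lm * cos(pi * k * (2 * (0:(nMels - 1)) + 1) /
                                           (2 * nMels)))
    }
  }
  expect_lt(max(abs(got - ref)), 1e-6)
})

test_that("39-d summaries concatenate mean, sd and mean first difference", {
  m <- matrix(3, 13, 10)
  s <- summary39(m)
  expect_length(s, 39)
  expect_equal(s[1:13], rep(3, 13))
  expect_equal(s[14:26], rep(0, 13))
  expect_equal(s[27:39], rep(0, 13))

  m2 <- matrix(0, 13, 11)
  m2[5, ] <- seq(0, 5, by = 0.5)                  # ramps 0.5 per frame
  s2 <- summary39(m2)
  expect_equal(s2[26 + 5], 0.5)
  expect_true(all(s2[14:26] >= 0))
})

test_that("PCA projection matches a brute-force eigendecomposition", {
  set.seed(21)
  X <- matrix(rnorm(30 * 5), 30, 5) %*% diag(c(3, 2, 1, 0.5, 0.1))
  p <- pcaProject(X, 2)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(sort(p$explainedVariance, decreasing = TRUE), sort(ev, decreasing = TRUE),
               tolerance = 1e-8)
  expect_gte(p$explainedVariance[1], p$explainedVariance[2])

  # collinear points have zero second-component variance
  line <- cbind(1:10, 2 * (1:10) + 3)
  pl <- pcaProject(line, 2)
  expect_lt(pl$explainedVariance[2], 1e-20)

  # reconstruction error decreases monotonically with components
  errs <- vapply(1:3, function(k) {
    pk <- pcaProject(X, k)
    sqrt(sum((pcaReconstruct(pk, k) - X)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-10))
})

test_that("spectrogram scaling helpers invert block structure", {
  m <- matrix(1:24, 4, 6)
  d <- downscaleSpec(m, 2, 2)
  expect_equal(dim(d), c(2, 3))
  expect_equal(d[1, 1], mean(m[1:2, 1:2]))
  u <- upscaleSpec(d, 2, 2)
  expect_equal(dim(u), dim(m))
  expect_equal(downscaleSpec(u, 2, 2), d)
})
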