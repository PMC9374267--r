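# Shared helpers for the test suite: small waveform constructors and a
# writer for multi-channel WAV fixtures (the package writer is mono-only).

toneWave <- function(freq, duration = 1, sampleRate = 22050, amp = 0.5) {
  amp * sin(2 * pi * freq * (seq_len(round(duration * sampleRate)) - 1) /
              sampleRate)
}

sixSecondSegment <- function(freq = 440, sampleRate = 22050) {
  toneWave(freq, 6, sampleRate)
}

# Interleaved 16-bit PCM stereo WAV writer for fixtures.
writeStereoWav <- function(path, left, right, sampleRate) {
  stopifnot(length(left) == length(right))
  inter <- as.vector(rbind(left, right))
  q <- as.integer(pmax(-32768, pmin(32767, round(inter * 32767))))
  dataSize <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + dataSize, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

# A tiny on-disk synthetic corpus shared by IO/preprocess tests.
tinyCorpus <- function(dir = tempfile("corpus"), seed = 11L) {
  cfg <- synthConfig(
    recordings = c(COPD = 3, Healthy = 2, URTI = 1, LRTI = 1,
                   Bronchiectasis = 1, Bronchiolitis = 1, Pneumonia = 1),
    cyclesPerClass = c(COPD = 12, Healthy = 6, URTI = 4, LRTI = 4,
                       Bronchiectasis = 4, Bronchiolitis = 4,
                       Pneumonia = 4),
    seed = seed)
  gen <- generateCorpus(cfg, dir)
  list(dir = dir, config = cfg, gen = gen)
}

# Nearest-centroid classification accuracy on 39-d MFCC summaries.
nearestCentroidAccuracy <- function(trainFeat, trainLab, testFeat, testLab) {
  classes <- sort(unique(trainLab))
  centroids <- t(vapply(classes, function(cl) {
    colMeans(trainFeat[trainLab == cl, , drop = FALSE])
  }, numeric(ncol(trainFeat))))
  pred <- classes[apply(testFeat, 1, function(v) {
    which.min(colSums((t(centroids) - v)^2))
  })]
  mean(pred == testLab)
}
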