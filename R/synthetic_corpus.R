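# Seeded generator for an ICBHI-format synthetic corpus. The generator does
# not aim for clinical realism; it reproduces the statistical structure the
# pipeline assumes: a heavily dominant majority class, cycle durations
# peaking near 2.5 s with a small tail past 6 s, and class-distinct acoustic
# content (tonal wheezes, transient crackles, band-limited breath noise).

#' Per-class acoustic profiles
#'
#' Each class is given a distinct combination of wheeze probability and tonal
#' band (within the 250-800 Hz wheeze range), crackle probability and burst
#' rate, breath-noise band, and breathing-envelope shape, so that classes are
#' statistically distinguishable by spectral-envelope features.
#'
#' @return Named list of profiles, one per label in [diagnosisLabels()].
#'   Fields per profile: `wheezeProb`, `wheezeBand` (Hz), `nHarmonics`,
#'   `crackleProb`, `crackleRate` (bursts/s), `noiseBand` (Hz), `noiseAmp`,
#'   `toneSnr`, `burstSnr`, `envExponent`.
#' @export
classAcousticProfiles <- function() {
  p <- function(wp, wband, nh, cp, crate, nband, envExp) {
    list(wheezeProb = wp, wheezeBand = wband, nHarmonics = nh,
         crackleProb = cp, crackleRate = crate, noiseBand = nband,
         noiseAmp = 0.25, toneSnr = 3.0, burstSnr = 4.0, envExponent = envExp)
  }
  list(
    COPD           = p(0.45, c(380, 520), 2, 0.70, 5, c(100, 500), 1.0),
    Healthy        = p(0.00, c(250, 800), 1, 0.00, 0, c(200, 900), 2.0),
    URTI           = p(0.80, c(600, 800), 1, 0.15, 2, c(500, 1400), 1.5),
    LRTI           = p(0.70, c(250, 400), 3, 0.25, 3, c(150, 600), 0.8),
    Bronchiectasis = p(0.10, c(300, 450), 1, 0.90, 9, c(80, 400), 1.2),
    Bronchiolitis  = p(0.50, c(480, 680), 2, 0.50, 6, c(400, 1100), 1.8),
    Pneumonia      = p(0.20, c(520, 640), 1, 0.80, 12, c(250, 800), 1.0),
    Asthma         = p(0.95, c(300, 700), 3, 0.30, 3, c(300, 1000), 1.4)
  )
}

.bandNoise <- function(n, sampleRate, band) {
  # filter at a power-of-two length (arbitrary-length FFTs can be slow)
  m <- 2^ceiling(log2(n))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  freqs <- (seq_len(m) - 1) * (sampleRate / m)
  freqs <- pmin(freqs, sampleRate - freqs)       # mirror for negative bins
  X[freqs < band[1] | freqs > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Synthesize one respiratory cycle
#'
#' Draws a single cycle waveform from a class acoustic profile: band-limited
#' breath noise amplitude-modulated by an inhale/exhale envelope, a tonal
#' wheeze (with probability `wheezeProb`; 1-3 vibrato harmonics inside the
#' profile's band), and transient crackle bursts (5-15 ms exponentially
#' decaying noise, with probability `crackleProb`). Randomness comes from the
#' current R RNG; seed it for reproducibility.
#'
#' @param profile One element of [classAcousticProfiles()].
#' @param duration Cycle duration in seconds (0.3 to 10).
#' @param sampleRate Sample rate in Hz.
#' @return Numeric waveform in `[-1, 1]` of `round(duration * sampleRate)`
#'   samples. A list with elements `wave`, `hasWheeze`, `hasCrackle`.
#' @export
synthCycle <- function(profile, duration, sampleRate = 22050L) {
  stopifnot(duration >= 0.3, duration <= 10)
  n <- round(duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  # two-hump inhale/exhale envelope; exponent shapes the duty cycle
  env <- (0.15 + 0.85 * abs(sin(pi * t / duration))^profile$envExponent)

  wave <- numeric(n)
  if (profile$noiseAmp > 0) {
    wave <- wave + profile$noiseAmp * .bandNoise(n, sampleRate,
                                                 profile$noiseBand) * env
  }

  hasWheeze <- stats::runif(1) < profile$wheezeProb
  if (hasWheeze) {
    f0 <- stats::runif(1, profile$wheezeBand[1], profile$wheezeBand[2])
    vibRate <- stats::runif(1, 3, 6)
    vibDepth <- stats::runif(1, 0.005, 0.02)
    tone <- numeric(n)
    for (h in seq_len(profile$nHarmonics)) {
      fh <- h * f0 * (1 + vibDepth * sin(2 * pi * vibRate * t))
      phase <- 2 * pi * cumsum(fh) / sampleRate
      tone <- tone + (0.6^(h - 1)) * sin(phase)
    }
    tone <- tone / max(abs(tone))
    wave <- wave + profile$noiseAmp * profile$toneSnr * tone * env
  }

  hasCrackle <- stats::runif(1) < profile$crackleProb
  if (hasCrackle) {
    nBursts <- max(1L, stats::rpois(1, profile$crackleRate * duration))
    burstAmp <- max(profile$noiseAmp, 0.05) * profile$burstSnr
    for (b in seq_len(nBursts)) {
      bd <- stats::runif(1, 0.005, 0.015)            # 5-15 ms
      bn <- max(2L, round(bd * sampleRate))
      at <- sample.int(max(1L, n - bn), 1L)
      burst <- stats::rnorm(bn) * exp(-seq_len(bn) / (bn / 4))
      idx <- at:(at + bn - 1L)
      wave[idx] <- wave[idx] + burstAmp * burst
    }
  }

  peak <- max(abs(wave))
  if (peak > 0.95) wave <- wave * (0.95 / peak)
  list(wave = wave, hasWheeze = hasWheeze, hasCrackle = hasCrackle)
}

#' Synthetic-corpus configuration
#'
#' @param recordings Named integer vector: recordings per class (names from
#'   [diagnosisLabels()]).
#' @param cyclesPerClass Optional named integer vector of exact per-class
#'   cycle totals; when given, cycles are distributed over the class's
#'   recordings and counts are exact by construction. When `NULL`, each
#'   recording draws its cycle count from `cyclesPerRecording`.
#' @param cyclesPerRecording Integer range `c(lo, hi)` of cycles drawn per
#'   recording.
#' @param durationMode Mode of the log-normal cycle-duration distribution (s).
#' @param durationSigma Log-scale spread; the default puts about 2% of mass
#'   above 6 s, exercising the discard rule.
#' @param durationMax Hard upper clip for durations (s).
#' @param sampleRate Sample rate in Hz.
#' @param seed Integer seed fixing all randomness of the corpus.
#' @return A list of class `"synthConfig"`.
#' @export
synthConfig <- function(recordings = c(COPD = 8, Healthy = 3, URTI = 2,
                                       LRTI = 2, Bronchiectasis = 2,
                                       Bronchiolitis = 2, Pneumonia = 2),
                        cyclesPerClass = NULL,
                        cyclesPerRecording = c(4L, 8L),
                        durationMode = 2.5, durationSigma = 0.35,
                        durationMax = 10, sampleRate = 22050L, seed = 1L) {
  stopifnot(all(recordings >= 0), durationMode < durationMax,
            all(names(recordings) %in% diagnosisLabels()))
  if (!is.null(cyclesPerClass)) {
    stopifnot(all(names(cyclesPerClass) %in% names(recordings)),
              all(cyclesPerClass[names(recordings)] >= recordings))
  }
  structure(list(recordings = recordings, cyclesPerClass = cyclesPerClass,
                 cyclesPerRecording = as.integer(cyclesPerRecording),
                 durationMode = durationMode, durationSigma = durationSigma,
                 durationMax = durationMax,
                 sampleRate = as.integer(sampleRate), seed = as.integer(seed)),
            class = "synthConfig")
}

#' Corpus preset reproducing the study's class imbalance
#'
#' Exact per-class cycle totals scaled down 20-fold from a corpus of 6898
#' cycles of which 5641 are COPD, preserving the majority fraction of about
#' 82%.
#'
#' @param seed Integer seed.
#' @param scale Divisor applied to the full-corpus cycle counts (default 20).
#' @return A `synthConfig`.
#' @export
imbalancedPreset <- function(seed = 1L, scale = 20) {
  cycles <- round(c(COPD = 5641, Healthy = 322, URTI = 243, Pneumonia = 285,
                    Bronchiolitis = 160, Bronchiectasis = 104, LRTI = 63,
                    Asthma = 10) / scale)
  cycles <- pmax(cycles, 4L)
  recs <- pmax(round(cycles / 6), 1L)
  synthConfig(recordings = recs, cyclesPerClass = cycles, seed = seed)
}

#' Draw cycle durations
#'
#' Log-normal with the configured mode and spread, clipped to
#' `[0.5, durationMax]`.
#' @param n Number of durations.
#' @param config A `synthConfig`.
#' @return Numeric vector of durations in seconds.
#' @export
drawCycleDurations <- function(n, config) {
  mu <- log(config$durationMode) + config$durationSigma^2
  d <- stats::rlnorm(n, mu, config$durationSigma)
  pmin(pmax(d, 0.5), config$durationMax)
}

#' Generate an on-disk ICBHI-format synthetic corpus
#'
#' Writes one WAV plus one annotation text file per synthetic recording, a
#' `diagnosis.csv`, and a `manifest.json` recording the seed and per-class
#' cycle counts. The full corpus is a pure function of the configuration.
#'
#' @param config A [synthConfig()].
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `cycles` (data frame: class, stem,
#'   cycle index, duration, wheeze/crackle flags), `perClassCycles`, and
#'   `nOverSixSeconds`.
#' @export
generateCorpus <- function(config, outDir) {
  stopifnot(inherits(config, "synthConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  profiles <- classAcousticProfiles()
  sr <- config$sampleRate

  diagnosis <- character(0)
  allCycles <- list()
  pid <- 100L
  for (cls in names(config$recordings)) {
    nRec <- config$recordings[[cls]]
    if (nRec == 0) next
    # per-recording cycle counts: exact class totals when configured
    if (!is.null(config$cyclesPerClass)) {
      total <- config$cyclesPerClass[[cls]]
      counts <- rep(total %/% nRec, nRec)
      extra <- total - sum(counts)
      if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    } else {
      counts <- sample(config$cyclesPerRecording[1]:config$cyclesPerRecording[2],
                       nRec, replace = TRUE)
    }
    for (r in seq_len(nRec)) {
      pid <- pid + 1L
      stem <- sprintf("%d_1b1_Al_sc_Synth", pid)
      durs <- drawCycleDurations(counts[r], config)
      waves <- vector("list", counts[r])
      flags <- matrix(0L, counts[r], 2)
      for (k in seq_len(counts[r])) {
        cyc <- synthCycle(profiles[[cls]], durs[k], sr)
        waves[[k]] <- cyc$wave
        flags[k, ] <- c(as.integer(cyc$hasCrackle), as.integer(cyc$hasWheeze))
      }
      rec <- unlist(waves)
      # truncate to the annotation file's 4-decimal precision so written
      # end times never exceed the waveform duration
      ends <- floor(cumsum(lengths(waves)) / sr * 1e4) / 1e4
      starts <- c(0, ends[-length(ends)])
      ann <- data.frame(start = starts, end = ends,
                        crackle = flags[, 1], wheeze = flags[, 2])
      writeWav(file.path(outDir, paste0(stem, ".wav")), rec, sr)
      writeCycleAnnotations(file.path(outDir, paste0(stem, ".txt")), ann)
      diagnosis[as.character(pid)] <- cls
      allCycles[[stem]] <- data.frame(
        class = cls, stem = stem, cycle = seq_len(counts[r]),
        duration = durs, crackle = flags[, 1], wheeze = flags[, 2])
    }
  }
  writeDiagnosisTable(file.path(outDir, "diagnosis.csv"), diagnosis)
  cycles <- do.call(rbind, allCycles)
  rownames(cycles) <- NULL
  perClass <- table(cycles$class)
  over6 <- sum(cycles$duration > 6)
  manifest <- c(
    "{",
    sprintf('  "seed": %d,', config$seed),
    sprintf('  "sample_rate": %d,', sr),
    sprintf('  "n_recordings": %d,', length(diagnosis)),
    sprintf('  "n_cycles": %d,', nrow(cycles)),
    sprintf('  "n_cycles_over_6s": %d,', over6),
    '  "cycles_per_class": {',
    paste0(sprintf('    "%s": %d', names(perClass), as.integer(perClass)),
           collapse = ",\n"),
    "  }",
    "}")
  writeLines(manifest, file.path(outDir, "manifest.json"))
  invisible(list(dir = outDir, cycles = cycles,
                 perClassCycles = perClass, nOverSixSeconds = over6))
}
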