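#' Slice a recording into annotated respiratory cycles
#'
#' One slice per annotation row: samples
#' `[round(start * sr) + 1, round(end * sr)]`, labeled with the recording's
#' diagnosis.
#'
#' @param rec An `AnnotatedRecording` from [readRecording()].
#' @return A list of slices, each a list with `wave`, `label`, `duration`,
#'   `stem`, `cycle`. Zero annotations give an empty list with a warning.
#' @export
segmentRecording <- function(rec) {
  stopifnot(inherits(rec, "AnnotatedRecording"))
  if (nrow(rec$cycles) == 0) {
    warning("recording ", rec$stem, " has no annotations; nothing to segment")
    return(list())
  }
  sr <- rec$sampleRate
  lapply(seq_len(nrow(rec$cycles)), function(k) {
    a <- round(rec$cycles$start[k] * sr)
    b <- round(rec$cycles$end[k] * sr)
    b <- min(b, length(rec$samples))
    list(wave = rec$samples[(a + 1L):b], label = rec$diagnosis,
         duration = (b - a) / sr, stem = rec$stem, cycle = k)
  })
}

#' Pad short cycles with silence, discard cycles longer than six seconds
#'
#' Cycles strictly longer than `maxSeconds` are dropped; all remaining
#' cycles are zero-padded at the end to exactly
#' `maxSeconds * sampleRate` samples (132300 at 22050 Hz). A cycle of
#' exactly `maxSeconds` is kept unpadded.
#'
#' @param slices List of slices from [segmentRecording()] (possibly
#'   concatenated over recordings).
#' @param sampleRate Sample rate in Hz.
#' @param maxSeconds Target segment length in seconds (default 6).
#' @return An [AudioSegments-class] object. The number of discarded cycles is
#'   attached as attribute `"nDiscarded"`.
#' @export
padOrDiscard <- function(slices, sampleRate = 22050L, maxSeconds = 6) {
  target <- round(maxSeconds * sampleRate)
  keep <- vapply(slices, function(s) length(s$wave) <= target, logical(1))
  nDiscarded <- sum(!keep)
  kept <- slices[keep]
  waves <- lapply(kept, function(s) {
    w <- s$wave
    if (length(w) < target) w <- c(w, numeric(target - length(w)))
    w
  })
  out <- AudioSegments(
    waves = waves,
    labels = vapply(kept, `[[`, character(1), "label"),
    source = data.frame(
      stem = vapply(kept, `[[`, character(1), "stem"),
      cycle = vapply(kept, function(s) as.integer(s$cycle), integer(1))),
    origDuration = vapply(kept, `[[`, numeric(1), "duration"),
    sampleRate = sampleRate)
  attr(out, "nDiscarded") <- nDiscarded
  out
}

#' Drop Asthma segments before classification
#'
#' The classifiers distinguish seven classes; Asthma recordings are removed
#' with a message stating the count.
#'
#' @param segments An [AudioSegments-class] object.
#' @return The segments without Asthma entries.
#' @export
dropAsthma <- function(segments) {
  drop <- segmentLabels(segments) == "Asthma"
  if (any(drop)) {
    message("dropping ", sum(drop), " Asthma segment(s) (7-class problem)")
  }
  segments[!drop]
}

#' Stratified train/test split
#'
#' Shuffles each class independently with the given seed and assigns
#' `max(1, floor(n_c * fraction))` segments per class to the training set.
#' With `unit = "recording"` whole recordings are assigned to one side, so
#' no recording contributes cycles to both sets.
#'
#' @param segments An [AudioSegments-class] object.
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed controlling the shuffle.
#' @param unit `"segment"` (default) or `"recording"`.
#' @return A list with `train` and `test` (both `AudioSegments`), plus
#'   `fraction` and `seed`.
#' @export
stratifiedSplit <- function(segments, fraction = 0.7, seed = 1L,
                            unit = c("segment", "recording")) {
  unit <- match.arg(unit)
  labels <- segmentLabels(segments)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 segments cannot be split: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  set.seed(seed)
  trainIdx <- integer(0)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (unit == "segment") {
      idx <- idx[sample.int(length(idx))]
      nTrain <- max(1L, floor(length(idx) * fraction))
      trainIdx <- c(trainIdx, idx[seq_len(nTrain)])
    } else {
      stems <- unique(segments@source$stem[idx])
      stems <- stems[sample.int(length(stems))]
      target <- length(idx) * fraction
      takeStems <- character(0)
      got <- 0L
      for (s in stems) {
        if (got >= target && length(takeStems) > 0) break
        takeStems <- c(takeStems, s)
        got <- got + sum(segments@source$stem[idx] == s)
      }
      trainIdx <- c(trainIdx, idx[segments@source$stem[idx] %in% takeStems])
    }
  }
  testIdx <- setdiff(seq_len(nSegments(segments)), trainIdx)
  list(train = segments[sort(trainIdx)], test = segments[sort(testIdx)],
       fraction = fraction, seed = seed)
}

#' Load, segment and pad a corpus directory
#'
#' Convenience wrapper: reads every recording with [readCorpus()], segments
#' by annotation, applies the six-second pad-or-discard rule, and logs
#' per-class counts.
#'
#' @param dir ICBHI-format corpus directory.
#' @param sampleRate Analysis rate in Hz.
#' @param maxSeconds Segment length in seconds.
#' @param verbose Print per-class counts after each filter.
#' @return An [AudioSegments-class] object with `"nDiscarded"` attribute.
#' @export
loadSegments <- function(dir, sampleRate = 22050L, maxSeconds = 6,
                         verbose = FALSE) {
  recs <- readCorpus(dir, sampleRate)
  slices <- do.call(c, lapply(recs, segmentRecording))
  segs <- padOrDiscard(slices, sampleRate, maxSeconds)
  if (verbose) {
    message(length(slices), " cycles in; ",
            attr(segs, "nDiscarded"), " discarded (> ", maxSeconds, " s); ",
            nSegments(segs), " segments out")
    tab <- table(segmentLabels(segs))
    message(paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  segs
}
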