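#' @import methods
NULL

#' Fixed-length labeled audio segments
#'
#' Container for respiratory-cycle segments after the pad-or-discard rule:
#' every waveform has exactly `segmentSamples(x)` samples (6 s at 22050 Hz by
#' default, i.e. 132300), padding beyond the original cycle duration is zero,
#' and each segment carries its diagnosis label and provenance (recording
#' stem + cycle index).
#'
#' @slot waves List of numeric vectors, one per segment, all the same length.
#' @slot labels Character vector of diagnosis labels.
#' @slot source Data frame with columns `stem` and `cycle` tracing each
#'   segment to its recording and cycle index.
#' @slot origDuration Numeric vector of the un-padded cycle durations (s).
#' @slot sampleRate Integer sample rate (Hz).
#' @exportClass AudioSegments
setClass("AudioSegments",
  representation(waves = "list", labels = "character", source = "data.frame",
                 origDuration = "numeric", sampleRate = "integer"),
  validity = function(object) {
    n <- length(object@waves)
    if (length(object@labels) != n) return("labels length != number of waves")
    if (nrow(object@source) != n) return("source rows != number of waves")
    if (length(object@origDuration) != n) return("origDuration length mismatch")
    if (n > 0) {
      lens <- lengths(object@waves)
      if (length(unique(lens)) != 1L) return("segments have unequal lengths")
    }
    TRUE
  })

#' Construct an AudioSegments object
#' @param waves List of equal-length numeric vectors.
#' @param labels Character labels, one per wave.
#' @param source Data frame with `stem` and `cycle` columns (defaults filled).
#' @param origDuration Original (pre-padding) durations in seconds.
#' @param sampleRate Sample rate in Hz.
#' @return An [AudioSegments-class] object.
#' @export
AudioSegments <- function(waves, labels,
                          source = data.frame(stem = rep(NA_character_,
                                                         length(waves)),
                                              cycle = seq_along(waves)),
                          origDuration = lengths(waves) / sampleRate,
                          sampleRate = 22050L) {
  new("AudioSegments", waves = waves, labels = as.character(labels),
      source = source, origDuration = as.numeric(origDuration),
      sampleRate = as.integer(sampleRate))
}

#' @describeIn AudioSegments-class Number of segments.
#' @param x,object An `AudioSegments` object.
#' @export
nSegments <- function(x) length(x@waves)

#' @describeIn AudioSegments-class Diagnosis labels.
#' @export
segmentLabels <- function(x) x@labels

#' @describeIn AudioSegments-class List of waveforms.
#' @export
segmentWaves <- function(x) x@waves

#' @describeIn AudioSegments-class Samples per segment.
#' @export
segmentSamples <- function(x) if (nSegments(x) == 0) 0L else length(x@waves[[1]])

#' @describeIn AudioSegments-class Subset by index, keeping metadata aligned.
#' @param i Integer or logical index.
#' @param j,drop,... Unused.
#' @export
setMethod("[", "AudioSegments", function(x, i, j, ..., drop = FALSE) {
  new("AudioSegments", waves = x@waves[i], labels = x@labels[i],
      source = x@source[i, , drop = FALSE],
      origDuration = x@origDuration[i], sampleRate = x@sampleRate)
})

#' @exportMethod show
setMethod("show", "AudioSegments", function(object) {
  cat("AudioSegments:", nSegments(object), "segments of",
      segmentSamples(object), "samples at", object@sampleRate, "Hz\n")
  if (nSegments(object) > 0) {
    tab <- table(object@labels)
    cat(" classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Normalized log-mel spectrogram set
#'
#' A set of mel spectrograms on a common normalization: log-power mel
#' matrices min-max scaled into `[0, 1]` with dataset-level `normMin` /
#' `normMax` fitted on a training set (see [fitMelNormalization()]).
#'
#' @slot specs List of `nMels x frames` matrices with entries in `[0, 1]`.
#' @slot labels Character vector of class labels.
#' @slot params List of front-end parameters (`nFft`, `hop`, `nMels`,
#'   `frames`, `sampleRate`, `logFloor`, `normMin`, `normMax`).
#' @exportClass MelSpecSet
setClass("MelSpecSet",
  representation(specs = "list", labels = "character", params = "list"),
  validity = function(object) {
    if (length(object@specs) != length(object@labels)) {
      return("specs/labels length mismatch")
    }
    p <- object@params
    for (nm in c("nMels", "frames", "normMin", "normMax")) {
      if (is.null(p[[nm]])) return(paste("missing param", nm))
    }
    if (p$normMax <= p$normMin) return("normMax must exceed normMin")
    for (s in object@specs) {
      if (!all(dim(s) == c(p$nMels, p$frames))) {
        return(sprintf("spectrogram dims must be %d x %d", p$nMels, p$frames))
      }
      if (min(s) < -1e-9 || max(s) > 1 + 1e-9) {
        return("spectrogram entries must lie in [0, 1]")
      }
    }
    TRUE
  })

#' Construct a MelSpecSet
#' @param specs List of matrices in `[0, 1]`.
#' @param labels Character labels.
#' @param params Front-end parameter list (see [melSpecParams()]).
#' @return A [MelSpecSet-class] object.
#' @export
MelSpecSet <- function(specs, labels, params) {
  new("MelSpecSet", specs = specs, labels = as.character(labels),
      params = params)
}

#' @describeIn MelSpecSet-class Number of spectrograms.
#' @param x,object A `MelSpecSet`.
#' @export
nSpecs <- function(x) length(x@specs)

#' @describeIn MelSpecSet-class Class labels.
#' @export
specLabels <- function(x) x@labels

#' @describeIn MelSpecSet-class List of spectrogram matrices.
#' @export
specMatrices <- function(x) x@specs

#' @describeIn MelSpecSet-class Front-end parameters.
#' @export
specParams <- function(x) x@params

#' @describeIn MelSpecSet-class Subset by index.
#' @param i Integer or logical index.
#' @param j,drop,... Unused.
#' @export
setMethod("[", "MelSpecSet", function(x, i, j, ..., drop = FALSE) {
  new("MelSpecSet", specs = x@specs[i], labels = x@labels[i],
      params = x@params)
})

setMethod("show", "MelSpecSet", function(object) {
  p <- object@params
  cat("MelSpecSet:", nSpecs(object), "spectrograms of", p$nMels, "x",
      p$frames, "\n")
  if (nSpecs(object) > 0) {
    tab <- table(object@labels)
    cat(" classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' A trained variational autoencoder
#'
#' Holds the weights of encoder and decoder, the variant configuration, the
#' training-loss history and (for unconditional variants) the single class
#' the instance was trained on.
#'
#' @slot variant One of `"mlp"`, `"cnn"`, `"conditional"`.
#' @slot config The [vaeConfig()] list used to build/train the model.
#' @slot params Named list of weight arrays.
#' @slot history Numeric vector of per-epoch training losses.
#' @slot classLabel Class the instance models (`NA` for conditional).
#' @exportClass TrainedVAE
setClass("TrainedVAE",
  representation(variant = "character", config = "list", params = "list",
                 history = "numeric", classLabel = "character"))

#' @describeIn TrainedVAE-class Per-epoch training loss.
#' @param x,object A `TrainedVAE`.
#' @export
lossHistory <- function(x) x@history

setMethod("show", "TrainedVAE", function(object) {
  cat("TrainedVAE <", object@variant, ">",
      if (!is.na(object@classLabel)) paste0(" class=", object@classLabel),
      " latentDim=", object@config$latentDim,
      " epochs=", length(object@history), "\n", sep = "")
  if (length(object@history) > 0) {
    cat(" final loss:", signif(utils::tail(object@history, 1), 5), "\n")
  }
})

#' A trained classifier (one or more trials)
#'
#' @slot arch Architecture name.
#' @slot config The [clfConfig()] list.
#' @slot trials List with one element per trial: `params` (weights) and
#'   `history` (per-epoch loss).
#' @slot labels Class vocabulary in output order.
#' @exportClass TrainedClassifier
setClass("TrainedClassifier",
  representation(arch = "character", config = "list", trials = "list",
                 labels = "character"))

#' @describeIn TrainedClassifier-class Number of training trials stored.
#' @param x,object A `TrainedClassifier`.
#' @export
nTrials <- function(x) length(x@trials)

setMethod("show", "TrainedClassifier", function(object) {
  cat("TrainedClassifier <", object@arch, "> ", nTrials(object),
      " trial(s), ", length(object@labels), " classes\n", sep = "")
})
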