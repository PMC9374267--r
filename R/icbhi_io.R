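#' Diagnosis label vocabulary
#'
#' The closed set of diagnosis labels supported by the package: chronic
#' obstructive pulmonary disease (COPD), upper/lower respiratory tract
#' infections (URTI/LRTI), Bronchiectasis, Bronchiolitis, Pneumonia, Asthma
#' and Healthy. Classifiers use the seven-class subset that excludes Asthma
#' (see [dropAsthma()]).
#'
#' @return Character vector of the eight recognised labels.
#' @export
diagnosisLabels <- function() {
  c("COPD", "Healthy", "URTI", "LRTI",
    "Bronchiectasis", "Bronchiolitis", "Pneumonia", "Asthma")
}

#' Seven-class label set used by the classifiers
#' @return Character vector: [diagnosisLabels()] without Asthma.
#' @export
classifierLabels <- function() setdiff(diagnosisLabels(), "Asthma")

#' Minority classes (all classifier classes except COPD)
#' @return Character vector of the six minority labels.
#' @export
minorityLabels <- function() setdiff(classifierLabels(), "COPD")

#' Parse an ICBHI recording file stem
#'
#' ICBHI recordings are named
#' `<patient>_<recording>_<chest location>_<acquisition mode>_<equipment>`,
#' e.g. `"101_1b1_Al_sc_Meditron"`.
#'
#' @param stem File stem (no directory, no extension) with exactly four
#'   underscores.
#' @return A list with fields `patientId`, `recordingIndex`, `chestLocation`,
#'   `acquisitionMode`, `equipment`.
#' @examples
#' parseRecordingStem("101_1b1_Al_sc_Meditron")
#' @export
parseRecordingStem <- function(stem) {
  stopifnot(is.character(stem), length(stem) == 1L)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 5L || any(!nzchar(parts))) {
    stop("malformed recording stem (need 5 underscore-separated fields): '",
         stem, "'")
  }
  list(patientId = parts[1], recordingIndex = parts[2],
       chestLocation = parts[3], acquisitionMode = parts[4],
       equipment = parts[5])
}

#' Reassemble a recording stem from its parsed fields
#' @param meta A list as returned by [parseRecordingStem()].
#' @return The file stem string.
#' @export
recordingStem <- function(meta) {
  paste(meta$patientId, meta$recordingIndex, meta$chestLocation,
        meta$acquisitionMode, meta$equipment, sep = "_")
}

#' Read a cycle-annotation text file
#'
#' Each row annotates one respiratory cycle with four whitespace-separated
#' columns: start time (s), end time (s), crackle flag (0/1), wheeze
#' flag (0/1).
#'
#' @param path Path to the annotation `.txt` file.
#' @return A data frame with columns `start`, `end`, `crackle`, `wheeze`,
#'   one row per cycle in file order. Empty files give zero rows.
#' @export
readCycleAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      crackle = integer(0), wheeze = integer(0))
  if (length(lines) == 0) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (length(f) != 4L) {
      stop("annotation parse error at line ", i, ": expected 4 columns, got ",
           length(f))
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("annotation parse error at line ", i,
                       ": non-numeric cell in '", lines[i], "'")
    if (v[2] <= v[1]) stop("annotation parse error at line ", i,
                           ": end time ", v[2], " <= start time ", v[1])
    if (v[1] < 0) stop("annotation parse error at line ", i,
                       ": negative start time")
    if (!all(v[3:4] %in% c(0, 1))) {
      stop("annotation parse error at line ", i,
           ": crackle/wheeze flags must be 0 or 1")
    }
    data.frame(start = v[1], end = v[2],
               crackle = as.integer(v[3]), wheeze = as.integer(v[4]))
  })
  do.call(rbind, rows)
}

#' Write a cycle-annotation text file
#' @param path Output path.
#' @param cycles Data frame with columns `start`, `end`, `crackle`, `wheeze`.
#' @return `path`, invisibly.
#' @export
writeCycleAnnotations <- function(path, cycles) {
  lines <- sprintf("%.4f\t%.4f\t%d\t%d",
                   cycles$start, cycles$end, cycles$crackle, cycles$wheeze)
  writeLines(lines, path)
  invisible(path)
}

#' Read a patient-diagnosis table
#'
#' Two-column CSV mapping `patient_id` to a diagnosis label from
#' [diagnosisLabels()]. A header row is detected automatically (a first row
#' whose second field is not a known label and whose first field is
#' non-numeric is treated as a header).
#'
#' @param path Path to the CSV.
#' @return A named character vector: names are patient ids, values labels.
#' @export
readDiagnosisTable <- function(path) {
  if (!file.exists(path)) stop("diagnosis file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) != 2L) stop("diagnosis table must have exactly 2 columns")
  if (nrow(raw) > 0 &&
      !(raw[1, 2] %in% diagnosisLabels()) &&
      is.na(suppressWarnings(as.numeric(raw[1, 1])))) {
    raw <- raw[-1, , drop = FALSE]
  }
  ids <- raw[[1]]
  labels <- raw[[2]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate patient id(s) in diagnosis table: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(labels), diagnosisLabels())
  if (length(bad) > 0) {
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(diagnosisLabels(), collapse = ", "))
  }
  stats::setNames(labels, ids)
}

#' Write a patient-diagnosis table
#' @param path Output path.
#' @param diagnosis Named character vector (names = patient ids).
#' @return `path`, invisibly.
#' @export
writeDiagnosisTable <- function(path, diagnosis) {
  utils::write.table(
    data.frame(patient_id = names(diagnosis), diagnosis = unname(diagnosis)),
    path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one annotated recording
#'
#' Reads a WAV file and its sibling annotation text file, attaches the
#' patient's diagnosis, converts the audio to mono float in `[-1, 1]` and
#' resamples to `sampleRate`. Annotations whose end time overruns the
#' waveform duration by a small amount are clamped with a warning; cycles
#' starting at or beyond the duration are rejected.
#'
#' @param wavPath Path to the recording `.wav`; the annotation file is the
#'   same path with extension `.txt`.
#' @param diagnosis Named character vector from [readDiagnosisTable()].
#' @param sampleRate Analysis sample rate in Hz (default 22050).
#' @return A list of class `"AnnotatedRecording"` with fields `meta`,
#'   `samples`, `sampleRate`, `cycles`, `diagnosis`, `stem`.
#' @export
readRecording <- function(wavPath, diagnosis, sampleRate = 22050L) {
  stem <- sub("\\.wav$", "", basename(wavPath), ignore.case = TRUE)
  meta <- parseRecordingStem(stem)
  txtPath <- file.path(dirname(wavPath), paste0(stem, ".txt"))
  cycles <- readCycleAnnotations(txtPath)
  wav <- readWav(wavPath, resampleTo = sampleRate)
  dur <- length(wav$samples) / wav$sampleRate
  if (nrow(cycles) > 0) {
    tooLate <- cycles$start >= dur
    if (any(tooLate)) {
      stop("annotation cycle starts at/after waveform end in ", stem)
    }
    overrun <- cycles$end > dur
    if (any(overrun)) {
      warning(sum(overrun), " cycle(s) in ", stem,
              " end past the waveform; clamped to ", round(dur, 3), " s")
      cycles$end[overrun] <- dur
    }
  }
  if (!(meta$patientId %in% names(diagnosis))) {
    stop("patient ", meta$patientId, " missing from diagnosis table")
  }
  structure(
    list(meta = meta, samples = wav$samples, sampleRate = wav$sampleRate,
         cycles = cycles, diagnosis = unname(diagnosis[meta$patientId]),
         stem = stem),
    class = "AnnotatedRecording")
}

#' @export
print.AnnotatedRecording <- function(x, ...) {
  cat("AnnotatedRecording", x$stem, "\n",
      " diagnosis:", x$diagnosis, "\n",
      " duration:", round(length(x$samples) / x$sampleRate, 2), "s at",
      x$sampleRate, "Hz;", nrow(x$cycles), "cycles\n")
  invisible(x)
}

#' Read every recording in an ICBHI-format directory
#'
#' @param dir Directory containing `.wav` + `.txt` pairs and a
#'   `diagnosis.csv`.
#' @param sampleRate Analysis sample rate (Hz).
#' @return List of `AnnotatedRecording` objects.
#' @export
readCorpus <- function(dir, sampleRate = 22050L) {
  diagPath <- file.path(dir, "diagnosis.csv")
  diagnosis <- readDiagnosisTable(diagPath)
  wavs <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  if (length(wavs) == 0) stop("no WAV files found in ", dir)
  lapply(wavs, readRecording, diagnosis = diagnosis, sampleRate = sampleRate)
}
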