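mkRecording <- function(durations, diagnosis = "COPD", sr = 22050L) {
  ends <- cumsum(durations)
  starts <- c(0, ends[-length(ends)])
  structure(list(
    meta = parseRecordingStem("201_1b1_Al_sc_Synth"),
    samples = numeric(round(sum(durations) * sr)) + 0.1,
    sampleRate = sr,
    cycles = data.frame(start = starts, end = ends,
                        crackle = 0L, wheeze = 0L),
    diagnosis = diagnosis, stem = "201_1b1_Al_sc_Synth"),
    class = "AnnotatedRecording")
}

test_that("segmentation slices follow the annotations sample-exactly", {
  rec <- mkRecording(c(2.5, 2.5, 5))
  slices <- segmentRecording(rec)
  expect_length(slices, 3)
  expect_equal(length(slices[[1]]$wave), 55125)    # 2.5 s * 22050
  expect_equal(length(slices[[2]]$wave), 55125)
  expect_equal(slices[[1]]$label, "COPD")
  expect_equal(slices[[2]]$cycle, 2)

  whole <- mkRecording(4)
  s <- segmentRecording(whole)
  expect_equal(s[[1]]$wave, whole$samples)

  rec$cycles <- rec$cycles[0, ]
  expect_warning(empty <- segmentRecording(rec), "no annotations")
  expect_length(empty, 0)
})

test_that("pad-or-discard pads with trailing silence and drops >6 s cycles", {
  rec <- mkRecording(c(2.5, 7, 6))
  slices <- segmentRecording(rec)
  segs <- padOrDiscard(slices)
  expect_equal(nSegments(segs), 2)                 # the 7 s cycle is gone
  expect_equal(attr(segs, "nDiscarded"), 1)
  w <- segmentWaves(segs)[[1]]
  expect_length(w, 132300)
  expect_true(all(w[55126:132300] == 0))           # padding is exact zeros
  expect_true(all(w[1:55125] != 0))
  # the exactly-6 s cycle is kept unpadded
  expect_equal(segs@origDuration[2], 6)
  expect_true(all(segmentWaves(segs)[[2]] != 0))
})

test_that("slice conservation: cycles in = segments out + discarded", {
  set.seed(7)
  durations <- runif(40, 1, 8)
  rec <- mkRecording(durations)
  segs <- padOrDiscard(segmentRecording(rec))
  expect_equal(length(durations),
               nSegments(segs) + attr(segs, "nDiscarded"))
  expect_equal(attr(segs, "nDiscarded"), sum(durations > 6))
})

test_that("stratified splits give floor(n * fraction) per class, deterministically", {
  waves <- replicate(16, numeric(8), simplify = FALSE)
  labels <- c(rep("COPD", 10), rep("URTI", 4), rep("LRTI", 2))
  segs <- AudioSegments(waves, labels)
  sp1 <- stratifiedSplit(segs, 0.7, seed = 3)
  expect_equal(sum(segmentLabels(sp1$train) == "COPD"), 7)
  expect_equal(sum(segmentLabels(sp1$test) == "COPD"), 3)
  expect_equal(sum(segmentLabels(sp1$train) == "URTI"), 2)  # floor(4*0.7)
  sp2 <- stratifiedSplit(segs, 0.7, seed = 3)
  expect_identical(sp1$train@source, sp2$train@source)
  expect_equal(nSegments(sp1$train) + nSegments(sp1$test), 16)

  one <- AudioSegments(waves[1:3], c("COPD", "COPD", "URTI"))
  expect_error(stratifiedSplit(one), "URTI")
})

test_that("large imbalanced label sets split at 70% per class within one segment", {
  counts <- c(COPD = 5641, Healthy = 322, URTI = 243, Pneumonia = 285,
              Bronchiolitis = 160, Bronchiectasis = 104, LRTI = 63)
  labels <- rep(names(counts), counts)
  waves <- replicate(length(labels), numeric(2), simplify = FALSE)
  segs <- AudioSegments(waves, labels)
  sp <- stratifiedSplit(segs, 0.7, seed = 1)
  trainTab <- table(segmentLabels(sp$train))
  for (cls in names(counts)) {
    expect_lte(abs(trainTab[[cls]] - 0.7 * counts[[cls]]), 1)
  }
})

test_that("recording-level splits never put one recording in both sets", {
  waves <- replicate(24, numeric(4), simplify = FALSE)
  stems <- rep(sprintf("p%d_1b1_Al_sc_X", 1:6), each = 4)
  labels <- rep(c("COPD", "URTI"), each = 12)
  segs <- AudioSegments(waves, labels,
                        source = data.frame(stem = stems, cycle = rep(1:4, 6)))
  sp <- stratifiedSplit(segs, 0.7, seed = 2, unit = "recording")
  expect_length(intersect(unique(sp$train@source$stem),
                          unique(sp$test@source$stem)), 0)
})

test_that("Asthma segments are dropped before classification", {
  waves <- replicate(5, numeric(4), simplify = FALSE)
  segs <- AudioSegments(waves, c("COPD", "Asthma", "URTI", "Asthma", "COPD"))
  expect_message(kept <- dropAsthma(segs), "2 Asthma")
  expect_equal(nSegments(kept), 3)
  expect_false("Asthma" %in% segmentLabels(kept))
})

test_that("an on-disk corpus loads, segments and conserves cycle counts", {
  tc <- tinyCorpus(seed = 13L)
  segs <- loadSegments(tc$dir)
  nCycles <- nrow(tc$gen$cycles)
  expect_equal(nCycles, nSegments(segs) + attr(segs, "nDiscarded"))
  expect_equal(attr(segs, "nDiscarded"), tc$gen$nOverSixSeconds)
  expect_true(all(lengths(segmentWaves(segs)) == 132300))
})
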