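# End-to-end experiment: synthetic (or on-disk) corpus -> segmentation ->
# mel front end -> VAE training and sampling -> Griffin-Lim inversion ->
# MFCC -> generative-quality metrics -> classifier training on imbalanced
# and augmented sets -> classification metrics and ANOVA.

#' Experiment configuration
#'
#' Two presets are provided. `"desk"` is the reduced configuration used
#' throughout the test suite: a 20x scaled-down corpus with the same ~82%
#' majority fraction, VAEs trained for 30 epochs on 64 x 64 block-averaged
#' spectrograms, 4 Griffin-Lim iterations (MFCC features depend on the
#' magnitude spectrum, which stabilises after a few iterations), 40
#' training segments per minority class after augmentation, and classifiers
#' with reduced widths trained for 15 epochs at the study's learning rate
#' of 1e-4. `"paper"` keeps the full-scale settings: full-size
#' spectrograms, 100-epoch VAEs and classifiers, augmentation up to the
#' majority-class count, and 50-sample evaluation protocols.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Global seed; stage seeds are derived from it.
#' @param dataDir Optional existing ICBHI-format directory; `NULL` (default)
#'   generates a synthetic corpus with [imbalancedPreset()].
#' @param variants VAE variants to run.
#' @param archs Classifier architectures to run.
#' @return A list of class `"experimentConfig"`.
#' @export
experimentConfig <- function(preset = c("desk", "paper"), seed = 1L,
                             dataDir = NULL,
                             variants = c("mlp", "cnn", "conditional"),
                             archs = c("mlp", "cnn", "lstm", "resnet50",
                                       "efficientnetb0")) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  desk <- preset == "desk"
  structure(list(
    preset = preset, seed = seed, dataDir = dataDir,
    variants = variants, archs = archs,
    synth = imbalancedPreset(seed = seed),
    splitFraction = 0.7, splitUnit = "segment",
    melParams = melSpecParams(),
    vaeDownscale = if (desk) c(2L, 4L) else c(1L, 1L),
    vaeEpochs = if (desk) 30L else 100L,
    vaeBatch = if (desk) 16L else 32L,
    vaeLearningRate = 1e-3,
    glIter = if (desk) 4L else 32L,
    augmentTo = if (desk) 40L else NA_integer_,   # NA = majority count
    ccPerClass = if (desk) 15L else 50L,
    mcdPerClass = if (desk) 10L else 50L,
    fadEmbedder = "melstats",
    clfEpochs = if (desk) 15L else 100L,
    clfLearningRate = 1e-4,
    clfTrials = 3L, clfBatch = 32L
  ), class = "experimentConfig")
}

# Architecture-specific classifier configuration under a preset.
.clfConfigFor <- function(arch, config, seed) {
  base <- list(arch = arch, learningRate = config$clfLearningRate,
               epochs = config$clfEpochs, nTrials = config$clfTrials,
               batchSize = config$clfBatch, seed = seed)
  if (config$preset == "desk") {
    base <- c(base, switch(arch,
      mlp = list(mlpHidden = c(64L, 64L, 64L, 128L, 64L, 64L, 64L),
                 mlpDropout = c(0.1, 0.1, 0.1, 0.2, 0.1, 0.1, 0.1)),
      cnn = list(cnnFilters = c(8L, 8L), cnnDense = c(32L, 64L, 64L, 32L)),
      lstm = list(lstmUnits = c(16L, 32L), lstmDense = c(32L, 64L, 32L),
                  timeStride = 4L),
      resnet50 = list(resnetChannels = c(8L, 16L, 32L), resnetOut = 128L,
                      resnetDense = c(64L, 32L, 16L),
                      resnetDropout = c(0.1, 0.1, 0.1)),
      efficientnetb0 = list(effnetChannels = c(8L, 12L, 16L, 24L, 64L),
                            effnetDense = c(64L, 32L, 16L))))
  }
  do.call(clfConfig, base)
}

.stageCache <- function(cacheDir, key, expr, verbose = FALSE) {
  if (is.null(cacheDir)) return(force(expr))
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  f <- tempfile()
  saveRDS(key, f)
  path <- file.path(cacheDir, paste0(unname(tools::md5sum(f)), ".rds"))
  unlink(f)
  if (file.exists(path)) {
    if (verbose) message("  [cached] ", key[[1]])
    return(readRDS(path))
  }
  val <- force(expr)
  saveRDS(val, path)
  val
}

#' Run the full augmentation experiment
#'
#' Executes every stage of the study pipeline and returns all reports.
#' With a `cacheDir`, each stage's output is stored keyed by a hash of the
#' stage name and its configuration inputs, so reruns with an unchanged
#' configuration skip completed stages and a change invalidates only the
#' stages that depend on it.
#'
#' @param config An [experimentConfig()].
#' @param workDir Writable working directory for the corpus (default a
#'   per-session temporary directory).
#' @param cacheDir Optional stage-cache directory (`NULL` disables caching).
#' @param verbose Log stage progress.
#' @return A list with elements `counts` (cycle bookkeeping), `split`
#'   (per-class train/test counts), `fad` and `fadNoise` (per-class Frechet
#'   distances of generated audio and of a white-noise baseline), `cc`,
#'   `mcdTable`, `pca`, `metrics` (per class x trial x training set x
#'   classifier), `macro` (aggregated), `anova` (per metric), `minorityF1`
#'   (per training set x classifier mean minority-class F1), and
#'   `trainSetSizes`.
#' @export
runExperiment <- function(config, workDir = file.path(tempdir(), "respaug"),
                          cacheDir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experimentConfig"))
  say <- function(...) if (verbose) message(...)
  dir.create(workDir, showWarnings = FALSE, recursive = TRUE)

  # --- stage 1: corpus ------------------------------------------------------
  say("stage: corpus")
  if (is.null(config$dataDir)) {
    corpusDir <- file.path(workDir, "corpus")
    gen <- .stageCache(cacheDir, list("corpus", config$synth), {
      generateCorpus(config$synth, corpusDir)
    }, verbose)
    counts <- list(nCycles = nrow(gen$cycles),
                   nOverSix = gen$nOverSixSeconds,
                   perClass = gen$perClassCycles)
  } else {
    corpusDir <- config$dataDir
    counts <- NULL
  }

  # --- stage 2: segment + split --------------------------------------------
  say("stage: preprocess")
  pre <- .stageCache(cacheDir,
                     list("preprocess", config$synth, config$dataDir,
                          config$splitFraction, config$splitUnit,
                          config$seed), {
    segs <- loadSegments(corpusDir, config$melParams$sampleRate)
    nDiscarded <- attr(segs, "nDiscarded")
    segs <- dropAsthma(segs)
    split <- stratifiedSplit(segs, config$splitFraction,
                             seed = config$seed, unit = config$splitUnit)
    list(split = split, nDiscarded = nDiscarded,
         nSegments = nSegments(segs))
  }, verbose)
  split <- pre$split
  trainLabels <- segmentLabels(split$train)
  testLabels <- segmentLabels(split$test)

  # --- stage 3: mel front end ----------------------------------------------
  say("stage: mel front end")
  minority <- minorityLabels()
  minTrainIdx <- which(trainLabels %in% minority)
  melParams <- .stageCache(cacheDir, list("melnorm", config$synth,
                                          config$dataDir, config$seed), {
    fitMelNormalization(split$train[minTrainIdx], config$melParams)
  }, verbose)
  rf <- config$vaeDownscale[1]; cf <- config$vaeDownscale[2]
  vaeInputDim <- c(melParams$nMels %/% rf, melParams$frames %/% cf)

  # --- stage 4/5: train VAEs and generate ----------------------------------
  majorityTrain <- sum(trainLabels == "COPD")
  targetPerClass <- if (is.na(config$augmentTo)) majorityTrain
                    else config$augmentTo
  nRealTrain <- table(trainLabels)

  minoritySpecs <- .stageCache(cacheDir, list("melspecs", config$synth,
                                              config$dataDir, config$seed,
                                              config$vaeDownscale), {
    ms <- melSpectrogramSet(split$train[minTrainIdx], melParams)
    if (rf > 1 || cf > 1) ms <- downscaleSpecSet(ms, rf, cf) else ms
  }, verbose)

  genSpecs <- list()   # variant -> MelSpecSet of generated spectrograms
  vaeHistories <- list()
  for (variant in config$variants) {
    say("stage: train-vae [", variant, "]")
    res <- .stageCache(cacheDir, list("vae", variant, config$synth,
                                      config$dataDir, config$seed,
                                      config$vaeDownscale, config$vaeEpochs,
                                      config$vaeBatch,
                                      config$vaeLearningRate,
                                      targetPerClass), {
      vcfg <- function(s) vaeConfig(variant, epochs = config$vaeEpochs,
                                    batchSize = config$vaeBatch,
                                    learningRate = config$vaeLearningRate,
                                    seed = s, inputDim = vaeInputDim)
      sets <- list()
      hist <- list()
      if (variant == "conditional") {
        vae <- trainVae(minoritySpecs, vcfg(config$seed + 1000L))
        hist[["all"]] <- lossHistory(vae)
        set.seed(config$seed + 2000L)
        for (cls in minority) {
          nGen <- max(targetPerClass - nRealTrain[[cls]], 1L)
          sets[[cls]] <- generateSamples(vae, nGen, cls, params = melParams)
        }
      } else {
        for (k in seq_along(minority)) {
          cls <- minority[k]
          sub <- minoritySpecs[specLabels(minoritySpecs) == cls]
          vae <- trainVae(sub, vcfg(config$seed + 1000L + k))
          hist[[cls]] <- lossHistory(vae)
          set.seed(config$seed + 2000L + k)
          nGen <- max(targetPerClass - nRealTrain[[cls]], 1L)
          sets[[cls]] <- generateSamples(vae, nGen, params = melParams)
        }
      }
      merged <- MelSpecSet(
        do.call(c, lapply(sets, specMatrices)),
        unlist(lapply(sets, specLabels)),
        specParams(sets[[1]]))
      list(specs = merged, hist = hist)
    }, verbose)
    genSpecs[[variant]] <- res$specs
    vaeHistories[[variant]] <- res$hist
  }

  # --- stage 6: invert to audio, evaluate, extract MFCCs --------------------
  segLen <- 6L * melParams$sampleRate
  realTrainMfcc <- .stageCache(cacheDir, list("mfcc-train", config$synth,
                                              config$dataDir, config$seed), {
    mfccSet(split$train)
  }, verbose)
  realTestMfcc <- .stageCache(cacheDir, list("mfcc-test", config$synth,
                                             config$dataDir, config$seed), {
    mfccSet(split$test)
  }, verbose)

  fad <- list(); cc <- list(); mcdTab <- list(); pca <- list()
  synMfcc <- list()
  for (variant in config$variants) {
    say("stage: invert+eval [", variant, "]")
    ev <- .stageCache(cacheDir, list("geneval", variant, config$synth,
                                     config$dataDir, config$seed,
                                     config$vaeDownscale, config$vaeEpochs,
                                     config$glIter, targetPerClass,
                                     config$ccPerClass, config$mcdPerClass,
                                     config$fadEmbedder), {
      specs <- genSpecs[[variant]]
      if (rf > 1 || cf > 1) specs <- upscaleSpecSet(specs, rf, cf)
      set.seed(config$seed + 3000L)
      synSegs <- invertMelSpecSet(specs, nIter = config$glIter,
                                  targetLength = segLen)
      mf <- mfccSet(synSegs)
      fadV <- fadPerClass(split$train, synSegs,
                          embedder = config$fadEmbedder, classes = minority)
      ccV <- ccMatrix(split$train, synSegs, config$ccPerClass,
                      seed = config$seed + 4000L, classes = minority)
      mcdV <- mcdSummary(realTrainMfcc, mf,
                         realLabels = trainLabels,
                         nPerClass = config$mcdPerClass,
                         seed = config$seed + 5000L, classes = minority)
      # 39-d summary features of real + synthetic, projected to 2-D
      featReal <- t(vapply(realTrainMfcc[trainLabels %in% minority],
                           summary39, numeric(39)))
      featSyn <- t(vapply(mf, summary39, numeric(39)))
      pcaV <- pcaProject(rbind(featReal, featSyn))
      pcaV$group <- c(rep("real", nrow(featReal)),
                      rep("synthetic", nrow(featSyn)))
      pcaV$label <- c(trainLabels[trainLabels %in% minority],
                      attr(mf, "labels"))
      list(mfcc = mf, fad = fadV, cc = ccV, mcd = mcdV, pca = pcaV)
    }, verbose)
    synMfcc[[variant]] <- ev$mfcc
    fad[[variant]] <- ev$fad
    cc[[variant]] <- ev$cc
    mcdTab[[variant]] <- ev$mcd
    pca[[variant]] <- ev$pca
  }

  # --- noise-baseline FAD: how far is plain white noise from the real data --
  say("stage: noise baseline")
  fadNoise <- .stageCache(cacheDir, list("fadnoise", config$synth,
                                         config$dataDir, config$seed,
                                         config$fadEmbedder), {
    set.seed(config$seed + 6000L)
    nPer <- 12L
    noiseSegs <- AudioSegments(
      lapply(seq_len(nPer * length(minority)),
             function(i) stats::runif(segLen, -0.5, 0.5)),
      rep(minority, each = nPer), sampleRate = melParams$sampleRate)
    fadPerClass(split$train, noiseSegs, embedder = config$fadEmbedder,
                classes = minority)
  }, verbose)

  # --- stage 7: classifiers on imbalanced + augmented sets ------------------
  trainSets <- list(imbalanced = list(mfcc = realTrainMfcc,
                                      labels = trainLabels))
  for (variant in config$variants) {
    nm <- paste0(variant, "vae")
    trainSets[[nm]] <- list(
      mfcc = c(realTrainMfcc, synMfcc[[variant]]),
      labels = c(trainLabels, attr(synMfcc[[variant]], "labels")))
  }

  metricRows <- list()
  for (setName in names(trainSets)) {
    for (arch in config$archs) {
      say("stage: train-clf [", setName, " / ", arch, "]")
      rows <- .stageCache(cacheDir, list("clf", setName, arch, config$synth,
                                         config$dataDir, config$seed,
                                         config$clfEpochs,
                                         config$clfLearningRate,
                                         config$clfTrials, config$preset,
                                         config$vaeEpochs, targetPerClass,
                                         config$glIter), {
        ccfg <- .clfConfigFor(arch, config, config$seed + 7000L)
        clf <- trainClassifier(trainSets[[setName]]$mfcc,
                               trainSets[[setName]]$labels, ccfg)
        out <- list()
        for (tr in seq_len(nTrials(clf))) {
          pred <- predictClassifier(clf, realTestMfcc, trial = tr)
          cm <- confusionCounts(testLabels, pred$labels)
          pm <- perClassMetrics(cm)
          pm$trainset <- setName; pm$classifier <- arch; pm$trial <- tr
          out[[tr]] <- pm
        }
        do.call(rbind, out)
      }, verbose)
      metricRows[[paste(setName, arch)]] <- rows
    }
  }
  metrics <- do.call(rbind, metricRows)
  rownames(metrics) <- NULL

  macro <- macroReport(metrics)
  anova <- list()
  for (m in c("specificity", "recall", "precision", "f1")) {
    anova[[m]] <- anovaTwoWay(metrics[[m]], metrics$trainset,
                              metrics$classifier)
  }

  minoritySel <- metrics$class %in% minority
  minorityF1 <- stats::aggregate(
    f1 ~ trainset + classifier, data = metrics[minoritySel, ], FUN = mean)

  list(counts = counts,
       nDiscarded = pre$nDiscarded, nSegments = pre$nSegments,
       split = list(train = table(trainLabels), test = table(testLabels)),
       melParams = melParams, vaeHistories = vaeHistories,
       fad = fad, fadNoise = fadNoise, cc = cc, mcdTable = mcdTab, pca = pca,
       metrics = metrics, macro = macro, anova = anova,
       minorityF1 = minorityF1,
       trainSetSizes = vapply(trainSets, function(s) length(s$mfcc),
                              integer(1)))
}

#' Write experiment reports to CSV
#'
#' @param result Return value of [runExperiment()].
#' @param outDir Output directory.
#' @return `outDir`, invisibly.
#' @export
writeReports <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fadTab <- do.call(rbind, lapply(names(result$fad), function(v) {
    data.frame(variant = v, class = names(result$fad[[v]]$perClass),
               fad = unname(result$fad[[v]]$perClass))
  }))
  utils::write.csv(fadTab, file.path(outDir, "fad.csv"), row.names = FALSE)
  for (v in names(result$cc)) {
    utils::write.csv(result$cc[[v]]$mean,
                     file.path(outDir, paste0("cc_mean_", v, ".csv")))
  }
  mcdTab <- do.call(rbind, lapply(names(result$mcdTable), function(v) {
    cbind(variant = v, result$mcdTable[[v]])
  }))
  utils::write.csv(mcdTab, file.path(outDir, "mcd.csv"), row.names = FALSE)
  utils::write.csv(result$metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$macro, file.path(outDir, "macro.csv"),
                   row.names = FALSE)
  anovaTab <- do.call(rbind, lapply(names(result$anova), function(m) {
    a <- result$anova[[m]]
    data.frame(metric = m, F = a$F, criticalF = a$criticalF, p = a$p)
  }))
  utils::write.csv(anovaTab, file.path(outDir, "anova.csv"),
                   row.names = FALSE)
  invisible(outDir)
}

#' Plot a mel spectrogram
#' @param spec Matrix (mel bins x frames).
#' @param main Title.
#' @return Invisibly, `NULL`.
#' @export
plotMelSpec <- function(spec, main = "mel spectrogram") {
  graphics::image(t(spec), col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "frame", ylab = "mel bin", main = main, axes = FALSE)
  invisible(NULL)
}

#' Scatter plot of 2-D PCA scores for real vs synthetic features
#' @param pca A `pca` element of [runExperiment()] output (with `group`).
#' @param main Title.
#' @return Invisibly, `NULL`.
#' @export
plotPcaScatter <- function(pca, main = "MFCC summary features (PCA)") {
  col <- ifelse(pca$group == "real", "#1b7837", "#762a83")
  graphics::plot(pca$scores[, 1], pca$scores[, 2], col = col, pch = 16,
                 cex = 0.6, xlab = "PC1", ylab = "PC2", main = main)
  graphics::legend("topright", legend = c("real", "synthetic"),
                   col = c("#1b7837", "#762a83"), pch = 16, bty = "n")
  invisible(NULL)
}
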