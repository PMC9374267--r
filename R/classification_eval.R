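# Per-class and aggregate classification metrics, and the two-way ANOVA
# with replication comparing training sets across classifiers.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order of
#' `levels`.
#'
#' @param trueLabels,predLabels Equal-length character vectors.
#' @param levels Class vocabulary (default [classifierLabels()]).
#' @return Integer matrix `length(levels) x length(levels)`.
#' @export
confusionCounts <- function(trueLabels, predLabels,
                            levels = classifierLabels()) {
  stopifnot(length(trueLabels) == length(predLabels))
  bad <- setdiff(unique(c(trueLabels, predLabels)), levels)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  t1 <- factor(trueLabels, levels); t2 <- factor(predLabels, levels)
  cm <- table(t1, t2)
  m <- matrix(as.integer(cm), length(levels), length(levels),
              dimnames = list(true = levels, predicted = levels))
  m
}

#' Per-class precision, recall, specificity and F1
#'
#' One-vs-rest reduction of a confusion matrix: for each class,
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` (sensitivity),
#' `specificity = TN/(TN+FP)` and `F1 = 2PR/(P+R)`. Metrics with a zero
#' denominator are set to 0 and flagged `degenerate`.
#'
#' @param cm Confusion matrix from [confusionCounts()].
#' @return Data frame with one row per class: `class`, `precision`,
#'   `recall`, `specificity`, `f1`, `degenerate`.
#' @export
perClassMetrics <- function(cm) {
  n <- sum(cm)
  rows <- lapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- n - tp - fp - fn
    safe <- function(num, den) if (den == 0) 0 else num / den
    precision <- safe(tp, tp + fp)
    recall <- safe(tp, tp + fn)
    specificity <- safe(tn, tn + fp)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class = rownames(cm)[k], precision = precision,
               recall = recall, specificity = specificity, f1 = f1,
               degenerate = (tp + fp == 0) || (tp + fn == 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate metrics over classes and trials
#'
#' Unweighted mean and population standard deviation of the per-class,
#' per-trial metric values — the "mean +/- std" cells of a results table.
#'
#' @param metricValues Numeric vector of per-(class, trial) values.
#' @return Named vector `c(mean, sd)` with population (n-denominator) sd.
#' @export
macroStat <- function(metricValues) {
  m <- mean(metricValues)
  s <- sqrt(mean((metricValues - m)^2))
  c(mean = m, sd = s)
}

#' Macro report over training sets, classifiers, classes and trials
#'
#' @param df Data frame with columns `trainset`, `classifier`, `class`,
#'   `trial`, and one column per metric (`precision`, `recall`,
#'   `specificity`, `f1`).
#' @param metrics Metric column names to aggregate.
#' @return Data frame with one row per (trainset, classifier, metric):
#'   `mean` and `sd` over the class x trial values.
#' @export
macroReport <- function(df, metrics = c("specificity", "recall",
                                        "precision", "f1")) {
  combos <- unique(df[, c("trainset", "classifier")])
  rows <- list()
  for (r in seq_len(nrow(combos))) {
    sel <- df$trainset == combos$trainset[r] &
      df$classifier == combos$classifier[r]
    for (m in metrics) {
      st <- macroStat(df[[m]][sel])
      rows[[length(rows) + 1L]] <- data.frame(
        trainset = combos$trainset[r], classifier = combos$classifier[r],
        metric = m, mean = st["mean"], sd = st["sd"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA with replication
#'
#' Balanced two-factor analysis of variance (training set x classifier)
#' with replicates per cell, fitted with [stats::aov()]. The F ratio,
#' critical F at `alpha`, and p-value reported are those of the first
#' factor (the training-set effect), matching the hypothesis "no
#' significant difference in the performance metric across training sets".
#'
#' @param values Numeric metric values.
#' @param factorA Training-set labels (the tested factor).
#' @param factorB Classifier labels.
#' @param alpha Significance level (default 0.05).
#' @return List with `F`, `criticalF`, `p`, `df1`, `df2`, `table` (the full
#'   ANOVA table), and `degenerate` (TRUE when the within-cell variance is
#'   zero).
#' @export
anovaTwoWay <- function(values, factorA, factorB, alpha = 0.05) {
  stopifnot(length(values) == length(factorA),
            length(values) == length(factorB))
  fA <- factor(factorA); fB <- factor(factorB)
  cellN <- table(fA, fB)
  if (length(unique(as.vector(cellN))) != 1L || any(cellN == 0)) {
    stop("unbalanced design: every (A, B) cell needs the same number of ",
         "replicates")
  }
  if (cellN[1, 1] < 2) stop("need >= 2 replicates per cell")
  fit <- stats::aov(values ~ fA * fB)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  iA <- match("fA", rn); iR <- match("Residuals", rn)
  df1 <- tab[iA, "Df"]
  df2 <- tab[iR, "Df"]
  ssRes <- tab[iR, "Sum Sq"]
  degenerate <- ssRes < .Machine$double.eps * sum(values^2)
  Fr <- tab[iA, "F value"]
  p <- tab[iA, "Pr(>F)"]
  if (degenerate) warning("zero within-cell variance; F and p degenerate")
  list(F = Fr, criticalF = stats::qf(1 - alpha, df1, df2), p = p,
       df1 = df1, df2 = df2, table = tab, degenerate = degenerate)
}
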