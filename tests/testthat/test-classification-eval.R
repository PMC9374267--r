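test_that("confusion matrices tally true/predicted pairs exactly", {
  lv <- classifierLabels()
  truth <- rep(lv[1:3], each = 2)
  cm <- confusionCounts(truth, truth)
  expect_equal(sum(diag(cm)), 6)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  pred <- truth; pred[c(2, 5)] <- lv[c(4, 5)]   # two known errors
  cm2 <- confusionCounts(truth, pred)
  expect_equal(sum(cm2) - sum(diag(cm2)), 2)
  expect_equal(sum(cm2), 6)

  # brute-force pairwise tally oracle on random labels
  set.seed(18)
  t3 <- sample(lv, 60, TRUE); p3 <- sample(lv, 60, TRUE)
  cm3 <- confusionCounts(t3, p3)
  for (a in lv) for (b in lv) {
    expect_equal(cm3[a, b], sum(t3 == a & p3 == b))
  }
  expect_error(confusionCounts("COPD", "Flu"), "unknown")
})

test_that("per-class metrics reproduce hand-computed one-vs-rest values", {
  lv <- c("A", "B")
  cm <- matrix(c(8L, 1L, 2L, 9L), 2, 2, dimnames = list(lv, lv))
  # row A: TP=8 FN=2; col A: FP=1; TN=9
  m <- perClassMetrics(cm)
  a <- m[m$class == "A", ]
  expect_equal(a$precision, 8 / 9, tolerance = 1e-12)
  expect_equal(a$recall, 0.8)
  expect_equal(a$specificity, 0.9)
  expect_equal(a$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-12)

  perfect <- diag(5L); dimnames(perfect) <- list(letters[1:5], letters[1:5])
  mp <- perClassMetrics(perfect)
  expect_true(all(mp$precision == 1 & mp$recall == 1 &
                  mp$specificity == 1 & mp$f1 == 1))

  # a class never present and never predicted: all metrics 0, flagged
  cm0 <- matrix(c(4L, 0L, 0L, 0L), 2, 2, dimnames = list(lv, lv))
  m0 <- perClassMetrics(cm0)
  b <- m0[m0$class == "B", ]
  expect_equal(c(b$precision, b$recall, b$f1), c(0, 0, 0))
  expect_true(b$degenerate)
})

test_that("confusion-derived counts satisfy the one-vs-rest identities", {
  set.seed(19)
  lv <- classifierLabels()
  truth <- sample(lv, 80, TRUE); pred <- sample(lv, 80, TRUE)
  cm <- confusionCounts(truth, pred)
  tpSum <- sum(diag(cm))
  expect_equal(tpSum, sum(truth == pred))
  for (k in seq_along(lv)) {
    tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    tn <- sum(cm) - tp - fp - fn
    expect_equal(tp + fp + tn + fn, 80)
  }
  # F1 equals the harmonic mean wherever P, R > 0
  m <- perClassMetrics(cm)
  ok <- m$precision > 0 & m$recall > 0
  expect_equal(m$f1[ok], 2 / (1 / m$precision[ok] + 1 / m$recall[ok]),
               tolerance = 1e-12)
})

test_that("macro aggregation uses the population standard deviation", {
  expect_equal(macroStat(0.7), c(mean = 0.7, sd = 0))
  expect_equal(macroStat(c(0, 1)), c(mean = 0.5, sd = 0.5))
  set.seed(20)
  v <- runif(35)
  st <- macroStat(v)
  expect_equal(unname(st["mean"]), sum(v) / 35)
  expect_equal(unname(st["sd"]), sqrt(sum((v - mean(v))^2) / 35))

  df <- data.frame(trainset = rep(c("imb", "aug"), each = 6),
                   classifier = "mlp",
                   class = rep(c("A", "B", "C"), 4),
                   trial = rep(rep(1:2, each = 3), 2),
                   f1 = runif(12), precision = runif(12),
                   recall = runif(12), specificity = runif(12))
  rep <- macroReport(df)
  cell <- rep[rep$trainset == "imb" & rep$metric == "f1", ]
  expect_equal(cell$mean, mean(df$f1[df$trainset == "imb"]))
})

test_that("the two-way ANOVA matches a from-scratch sums-of-squares oracle", {
  # textbook-size balanced design: 2 x 2 cells, 2 replicates
  values <- c(10, 12, 20, 21, 14, 15, 23, 26)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(rep(c("b1", "b2"), each = 2), 2)
  got <- anovaTwoWay(values, A, B)

  grand <- mean(values)
  ssA <- 4 * sum((tapply(values, A, mean) - grand)^2)
  ssB <- 4 * sum((tapply(values, B, mean) - grand)^2)
  cellMeans <- tapply(values, list(A, B), mean)
  ssCells <- 2 * sum((cellMeans - grand)^2)
  ssAB <- ssCells - ssA - ssB
  ssErr <- sum((values - rep(as.vector(t(cellMeans))[c(1, 1, 2, 2, 3, 3, 4, 4)],
                             1))^2)
  msA <- ssA / 1; msErr <- ssErr / 4
  expect_equal(got$F, msA / msErr, tolerance = 1e-10)
  expect_equal(got$df1, 1)
  expect_equal(got$df2, 4)
  expect_equal(got$p, 1 - pf(msA / msErr, 1, 4), tolerance = 1e-10)
  expect_equal(got$criticalF, qf(0.95, 1, 4), tolerance = 1e-12)
})

test_that("ANOVA rejects unbalanced designs and flags zero variance", {
  values <- rnorm(7)
  expect_error(anovaTwoWay(values, c(rep("a", 4), rep("b", 3)),
                           rep(c("x", "y"), length.out = 7)), "unbalanced")
  const <- rep(1, 8)
  A <- rep(c("a", "b"), each = 4); B <- rep(rep(c("x", "y"), each = 2), 2)
  expect_warning(res <- anovaTwoWay(const, A, B), "degenerate")
  expect_true(res$degenerate)
})

test_that("under the null the training-set factor keeps its nominal size", {
  set.seed(77)
  hits <- 0; nSim <- 200
  for (s in seq_len(nSim)) {
    values <- rnorm(4 * 5 * 3)          # equal means everywhere
    A <- rep(paste0("set", 1:4), each = 15)
    B <- rep(rep(paste0("clf", 1:5), each = 3), 4)
    r <- anovaTwoWay(values, A, B)
    if (r$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / nSim, 0.03)
  expect_lte(hits / nSim, 0.07)
})
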