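test_that("the default embedder is deterministic with length 2 * nMels", {
  w <- toneWave(440, 2)
  e1 <- embedAudio(w)
  e2 <- embedAudio(w)
  expect_identical(e1, e2)
  expect_length(e1, 64)                       # 2 x 32 mel bands
  expect_error(embedAudio(w, embedder = "nosuch"), "melstats")
  expect_error(embedAudio(toneWave(440, 0.2)), "1 s")
})

test_that("tones at different frequencies separate in their mel bands", {
  e440 <- embedAudio(toneWave(440, 2))
  e3k <- embedAudio(toneWave(3000, 2))
  d <- abs(e440[1:32] - e3k[1:32])            # mean-log-energy half
  centers <- melCenterFrequencies(32)
  band440 <- which.min(abs(centers - 440))
  band3k <- which.min(abs(centers - 3000))
  expect_true(which.max(d) %in% c(band440 + (-1:1), band3k + (-1:1)))
})

test_that("Frechet distance matches 1-D Gaussian closed forms", {
  g <- function(mu, var) list(mu = mu, sigma = matrix(var, 1, 1), n = 10)
  expect_equal(frechetDistance(g(0, 1), g(0, 1)), 0)
  expect_equal(frechetDistance(g(0, 1), g(2, 1)), 4)       # (mu diff)^2
  expect_equal(frechetDistance(g(0, 1), g(0, 4)), 1)       # (1 - 2)^2
  # symmetry and non-negativity on random PSD inputs
  set.seed(12)
  for (i in 1:10) {
    A <- crossprod(matrix(rnorm(9), 3)); B <- crossprod(matrix(rnorm(9), 3))
    sa <- list(mu = rnorm(3), sigma = A, n = 5)
    sb <- list(mu = rnorm(3), sigma = B, n = 5)
    d1 <- frechetDistance(sa, sb); d2 <- frechetDistance(sb, sa)
    expect_gte(d1, 0)
    expect_equal(d1, d2, tolerance = 1e-8)
  }
  expect_error(frechetDistance(g(0, 1), list(mu = c(0, 0),
                                             sigma = diag(2), n = 3)),
               "dimensions")
})

test_that("per-class FAD is near zero for a bootstrap of the real data", {
  set.seed(31)
  waves <- lapply(1:24, function(i) {
    0.3 * sin(2 * pi * runif(1, 300, 600) * (0:33074) / 22050) +
      0.05 * rnorm(33075)
  })
  real <- AudioSegments(waves, rep(c("URTI", "LRTI"), each = 12))
  boot <- real[c(sample(1:12, 12, TRUE), 12 + sample(1:12, 12, TRUE))]
  fadBoot <- fadPerClass(real, boot)
  noise <- AudioSegments(lapply(1:24, function(i) stats::runif(33075, -1, 1)),
                         rep(c("URTI", "LRTI"), each = 12))
  fadNoise <- fadPerClass(real, noise)
  expect_lt(fadBoot$mean, 0.25 * fadNoise$mean)
  # identical sets give exactly zero
  fadSame <- fadPerClass(real, real)
  expect_equal(unname(fadSame$perClass), c(0, 0), tolerance = 1e-8)
})

test_that("normalized cross-correlation hits its exact reference points", {
  set.seed(7)
  x <- rnorm(1000)
  expect_equal(ncc(x, x), 1)
  expect_equal(ncc(x, -x), -1)
  t <- (0:999) / 100
  expect_lt(abs(ncc(sin(2 * pi * t), cos(2 * pi * t))), 1e-10)
  expect_warning(z <- ncc(numeric(10), rnorm(10)), "zero-energy")
  expect_equal(z, 0)
})

test_that("the cross-correlation matrix matches a brute-force double loop", {
  set.seed(9)
  mk <- function(f) sin(2 * pi * f * (0:299) / 100) + rnorm(300, 0, 0.1)
  realWaves <- lapply(c(3, 3.2, 7, 7.1, 12, 12.3), mk)
  synWaves <- lapply(c(3.1, 7.2, 12.1), mk)
  real <- AudioSegments(realWaves, rep(c("A1", "A2", "A3"), each = 2),
                        sampleRate = 100L)
  syn <- AudioSegments(synWaves, c("A1", "A2", "A3"), sampleRate = 100L)
  got <- suppressWarnings(ccMatrix(real, syn, nPerClass = 10, seed = 1,
                                   classes = c("A1", "A2", "A3")))
  for (sc in c("A1", "A2", "A3")) {
    for (rc in c("A1", "A2", "A3")) {
      si <- which(segmentLabels(syn) == sc)
      ri <- which(segmentLabels(real) == rc)
      best <- vapply(si, function(i) {
        max(vapply(ri, function(j) ncc(synWaves[[i]], realWaves[[j]]),
                   numeric(1)))
      }, numeric(1))
      expect_equal(got$mean[sc, rc], mean(best), tolerance = 1e-12)
    }
  }
  expect_true(all(got$mean >= -1 & got$mean <= 1))
  # synthetic = real copy puts 1.0 on the diagonal
  same <- ccMatrix(real, real, nPerClass = 10, seed = 1,
                   classes = c("A1", "A2", "A3"))
  expect_equal(unname(diag(same$mean)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("DTW alignment beats enumeration on a small grid", {
  set.seed(14)
  A <- matrix(rnorm(2 * 3), 2, 3)
  B <- matrix(rnorm(2 * 4), 2, 4)
  al <- dtwAlign(A, B)
  D <- as.matrix(dist(rbind(t(A), t(B))))[1:3, 4:7]
  # enumerate all monotone paths from (1,1) to (3,4)
  bestCost <- Inf
  walk <- function(i, j, cost) {
    cost <- cost + D[i, j]
    if (i == 3 && j == 4) { bestCost <<- min(bestCost, cost); return() }
    if (i < 3) walk(i + 1, j, cost)
    if (j < 4) walk(i, j + 1, cost)
    if (i < 3 && j < 4) walk(i + 1, j + 1, cost)
  }
  walk(1, 1, 0)
  expect_equal(al$dist, bestCost, tolerance = 1e-12)
  # path is monotone and spans both sequences
  expect_true(all(diff(al$path[, 1]) >= 0))
  expect_true(all(diff(al$path[, 2]) >= 0))
  expect_equal(al$path[1, ], c(1, 1))
  expect_equal(al$path[nrow(al$path), ], c(3, 4))
})

test_that("MCD has its closed form under a unit offset and improves with DTW", {
  set.seed(15)
  A <- matrix(rnorm(13 * 20), 13, 20)
  expect_equal(mcd(A, A), 0)
  B <- A; B[5, ] <- B[5, ] + 1                 # +1 in one coefficient
  expect_equal(mcd(A, B), 10 * sqrt(2) / log(10), tolerance = 1e-10)
  # a time shift is recovered by alignment
  C <- A[, c(rep(1, 5), 1:15)]
  expect_lte(mcd(A, C), mcd(A, C, align = FALSE))
  expect_gte(mcd(A, C), 0)
})

test_that("the per-class MCD summary matches a hand loop on a toy set", {
  set.seed(16)
  realM <- lapply(1:4, function(i) matrix(rnorm(13 * 8), 13, 8))
  synM <- lapply(1:4, function(i) matrix(rnorm(13 * 8), 13, 8))
  labs <- c("A", "A", "B", "B")
  got <- mcdSummary(realM, synM, realLabels = labs, synLabels = labs,
                    nPerClass = 10, seed = 2, classes = c("A", "B"))
  valsA <- as.vector(sapply(1:2, function(i) {
    sapply(1:2, function(j) mcd(realM[[j]], synM[[i]]))
  }))
  expect_equal(got$mean[got$class == "A"], mean(valsA), tolerance = 1e-12)
  expect_true(all(got$mean >= 0))
  # synthetic = real copies give zero mean distortion
  same <- mcdSummary(realM, realM, realLabels = labs, synLabels = labs,
                     nPerClass = 10, seed = 2, classes = c("A", "B"))
  expect_equal(same$mean, c(0, 0) + sapply(c("A", "B"), function(cl) {
    idx <- which(labs == cl)
    mean(sapply(idx, function(i) sapply(idx, function(j)
      mcd(realM[[j]], realM[[i]]))))
  }), ignore_attr = TRUE, tolerance = 1e-12)
})
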