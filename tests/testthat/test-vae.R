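# Small spectrogram sets used across the VAE tests.
tinySpecParams <- melSpecParams(nMels = 16L, frames = 32L,
                                normMin = 0, normMax = 1)

tinySpecSet <- function(class = "URTI", n = 6, seed = 1) {
  set.seed(seed)
  specs <- lapply(seq_len(n), function(i) {
    base <- outer(seq(0, 1, length.out = 16), seq(0, 1, length.out = 32))
    pmin(pmax(base + matrix(rnorm(16 * 32, 0, 0.05), 16, 32), 0), 1)
  })
  MelSpecSet(specs, rep(class, n), tinySpecParams)
}

tinyVaeConfig <- function(variant, epochs = 40, seed = 7, ...) {
  vaeConfig(variant, latentDim = 2, intermediateDim = 32,
            encDense = c(24, 16), convFilters = c(4, 8),
            deconvFilters = c(8, 4, 1), epochs = epochs,
            batchSize = 8, seed = seed, inputDim = c(16L, 32L), ...)
}

test_that("reparameterization draws z = mu + sigma * eps", {
  mu <- c(1.5, -2)
  z0 <- reparameterize(mu, c(-50, -50))
  expect_equal(z0, mu, tolerance = 1e-10)      # vanishing variance

  set.seed(3); z1 <- reparameterize(mu, c(0, 0))
  set.seed(3); z2 <- reparameterize(mu, c(0, 0))
  expect_identical(z1, z2)

  set.seed(4)
  n <- 1e5
  draws <- reparameterize(matrix(0, n, 1), matrix(0, n, 1))
  expect_lt(abs(mean(draws)), 4 / sqrt(n))
  expect_lt(abs(stats::var(as.vector(draws)) - 1), 0.05)
})

test_that("KL divergence has its closed form and is non-negative", {
  expect_equal(klDivergence(0, 0), 0)
  expect_equal(klDivergence(1, 0), 0.5)        # 0.5 * (1 + 1 - 1 - 0)
  expect_equal(klDivergence(c(1, 1), c(0, 0)), 1)
  set.seed(5)
  for (i in 1:25) {
    expect_gte(klDivergence(rnorm(3), rnorm(3)), 0)
  }
})

test_that("the objective decomposes into reconstruction and weighted KL", {
  set.seed(6)
  x <- matrix(runif(12), 3, 4)
  xhat <- matrix(runif(12), 3, 4)
  mu <- matrix(rnorm(2), 1, 2)
  lv <- matrix(rnorm(2), 1, 2)
  expect_equal(vaeLoss(x, x, matrix(0, 1, 2), matrix(0, 1, 2)), 0)
  expect_equal(vaeLoss(x, xhat, mu, lv, beta = 0), sum((x - xhat)^2))
  l1 <- vaeLoss(x, xhat, mu, lv, beta = 1)
  l2 <- vaeLoss(x, xhat, mu, lv, beta = 2)
  expect_equal(l2 - l1, klDivergence(mu, lv), tolerance = 1e-10)
  recon <- sum((x - xhat)^2)
  expect_equal(l1, recon + klDivergence(mu, lv), tolerance = 1e-6)
})

test_that("untrained models have the contracted output shapes and ranges", {
  cfg <- tinyVaeConfig("mlp")
  set.seed(1)
  m <- buildVae(cfg)
  X <- matrix(runif(2 * 16 * 32), 2)
  enc <- respaug:::.vaeEncodeF(m$params, cfg, X)
  expect_equal(dim(enc$mu), c(2, 2))
  dec <- respaug:::.vaeDecodeF(m$params, cfg, enc$mu)
  expect_equal(dim(dec$Xhat), dim(X))
  expect_true(all(dec$Xhat >= 0 & dec$Xhat <= 1))   # sigmoid output

  cfgc <- tinyVaeConfig("cnn")
  set.seed(1)
  mc <- buildVae(cfgc)
  # decoder output is 8x the reshape grid: three stride-2 upsamplings
  Z <- matrix(rnorm(6), 3, 2)
  decc <- respaug:::.vaeDecodeF(mc$params, cfgc, Z)
  expect_equal(dim(decc$Xhat), c(16, 32, 1, 3))
  expect_equal(c(16, 32), c(16 %/% 8, 32 %/% 8) * 8)

  expect_error(vaeConfig("cnn", inputDim = c(30L, 50L)), "divisible by 8")
})

test_that("full-size dense VAE accepts a 128 x 256 spectrogram", {
  cfg <- vaeConfig("mlp")
  set.seed(2)
  m <- buildVae(cfg)
  X <- matrix(runif(128 * 256), 1)
  enc <- respaug:::.vaeEncodeF(m$params, cfg, X)
  dec <- respaug:::.vaeDecodeF(m$params, cfg, reparameterize(enc$mu, enc$logvar))
  expect_equal(dim(dec$Xhat), c(1, 128 * 256))
  expect_true(all(dec$Xhat >= 0 & dec$Xhat <= 1))
  rm(m, dec); gc(verbose = FALSE)
})

test_that("training drives the loss down and overfits a repeated spectrogram", {
  specs <- tinySpecSet(n = 1, seed = 2)
  rep50 <- MelSpecSet(rep(specMatrices(specs), 50), rep("URTI", 50),
                      tinySpecParams)
  cfg <- tinyVaeConfig("mlp", epochs = 200)
  vae <- trainVae(rep50, cfg)
  h <- lossHistory(vae)
  expect_length(h, 200)
  expect_lt(mean(utils::tail(h, 10)), mean(utils::head(h, 10)))
  x <- specMatrices(specs)[[1]]
  xhat <- vaeReconstruct(vae, rep50[1])[[1]]
  mseFinal <- sum((x - xhat)^2)
  # initial reconstruction error from an untrained model
  set.seed(cfg$seed)
  m0 <- buildVae(cfg)
  enc0 <- respaug:::.vaeEncodeF(m0$params, cfg, matrix(as.vector(x), 1))
  dec0 <- respaug:::.vaeDecodeF(m0$params, cfg, enc0$mu)
  mse0 <- sum((as.vector(x) - dec0$Xhat)^2)
  expect_lt(mseFinal, 0.1 * mse0)
})

test_that("training is deterministic given the seed", {
  specs <- tinySpecSet(n = 8, seed = 3)
  cfg <- tinyVaeConfig("cnn", epochs = 10)
  h1 <- lossHistory(trainVae(specs, cfg))
  h2 <- lossHistory(trainVae(specs, cfg))
  expect_identical(h1, h2)
  cfg2 <- tinyVaeConfig("cnn", epochs = 10, seed = 8)
  h3 <- lossHistory(trainVae(specs, cfg2))
  expect_false(identical(h1, h3))
})

test_that("class guards reject majority and mixed-class unconditional training", {
  copd <- tinySpecSet("COPD", n = 4)
  expect_error(trainVae(copd, tinyVaeConfig("mlp", epochs = 1)), "COPD")
  mixed <- MelSpecSet(c(specMatrices(tinySpecSet("URTI", 2)),
                        specMatrices(tinySpecSet("LRTI", 2))),
                      c("URTI", "URTI", "LRTI", "LRTI"), tinySpecParams)
  expect_error(trainVae(mixed, tinyVaeConfig("mlp", epochs = 1)),
               "single class")
  expect_warning(trainVae(tinySpecSet("URTI", 4),
                          tinyVaeConfig("conditional", epochs = 1)),
                 "single class")
  empty <- MelSpecSet(list(), character(0), tinySpecParams)
  expect_error(trainVae(empty, tinyVaeConfig("mlp", epochs = 1)), "empty")
})

test_that("a conditional decoder depends functionally on the class label", {
  set.seed(11)
  mkClassSpecs <- function(cls, rowBand, n = 10) {
    specs <- lapply(seq_len(n), function(i) {
      s <- matrix(0.05, 16, 32)
      s[rowBand, ] <- 0.9
      pmin(pmax(s + matrix(rnorm(16 * 32, 0, 0.03), 16, 32), 0), 1)
    })
    MelSpecSet(specs, rep(cls, n), tinySpecParams)
  }
  a <- mkClassSpecs("URTI", 2:4)
  b <- mkClassSpecs("LRTI", 12:14)
  both <- MelSpecSet(c(specMatrices(a), specMatrices(b)),
                     c(specLabels(a), specLabels(b)), tinySpecParams)
  cfg <- tinyVaeConfig("conditional", epochs = 120)
  vae <- trainVae(both, cfg)
  set.seed(1); sa <- generateSamples(vae, 1, "URTI", params = tinySpecParams)
  set.seed(1); sb <- generateSamples(vae, 1, "LRTI", params = tinySpecParams)
  da <- specMatrices(sa)[[1]]; db <- specMatrices(sb)[[1]]
  expect_gt(mean(abs(da - db)), 0.01)
  # the bright band should sit where each class put it
  expect_gt(mean(da[2:4, ]), mean(da[12:14, ]))
  expect_gt(mean(db[12:14, ]), mean(db[2:4, ]))
})

test_that("sampling honours counts, determinism and spectrogram invariants", {
  specs <- tinySpecSet("Pneumonia", n = 8, seed = 5)
  vae <- trainVae(specs, tinyVaeConfig("mlp", epochs = 20))
  expect_error(generateSamples(vae, 0, params = tinySpecParams), "positive")
  set.seed(2); g1 <- generateSamples(vae, 5, params = tinySpecParams)
  set.seed(2); g2 <- generateSamples(vae, 5, params = tinySpecParams)
  expect_identical(specMatrices(g1), specMatrices(g2))
  expect_equal(specLabels(g1), rep("Pneumonia", 5))
  expect_error(generateSamples(vae, 2, classLabel = "URTI",
                               params = tinySpecParams), "Pneumonia")
  set.seed(3)
  g100 <- generateSamples(vae, 100, params = tinySpecParams)
  expect_equal(nSpecs(g100), 100)
  for (s in specMatrices(g100)[c(1, 50, 100)]) {
    expect_equal(dim(s), c(16, 32))
    expect_gte(min(s), 0); expect_lte(max(s), 1)
  }
  # a large requested count is honoured exactly
  set.seed(4)
  gBig <- generateSamples(vae, 641, params = tinySpecParams)
  expect_equal(nSpecs(gBig), 641)
})
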