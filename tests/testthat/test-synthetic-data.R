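smallCfg <- function(...) {
  synthConfig(nSamples = c(serum = 120, csf = 60),
              caseFraction = c(serum = 0.5, csf = 0.5),
              nProteins = c(v2 = 40, v3 = 60), nOverlap = 30,
              nInformative = 5, informativeEffect = 0.8,
              moduleBlocks = list(), noiseSd = 0.5, seed = 11, ...)
}

test_that("Table-1-scale composition is fixed, not sampled", {
  cfg <- synthConfig(nSamples = c(serum = 572),
                     caseFraction = c(serum = 0.699),
                     nProteins = c(v2 = 50, v3 = 50), nOverlap = 50,
                     nInformative = 5, moduleBlocks = list(), seed = 1)
  pe <- generateCohort(cfg, "serum")
  tab <- table(sampleData(pe)$status)
  expect_identical(unname(tab[["case"]]), 400L)
  expect_identical(unname(tab[["control"]]), 172L)
  expect_identical(transformState(pe), "raw")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- smallCfg()
  a <- generateCohort(cfg, "serum")
  b <- generateCohort(cfg, "serum")
  expect_identical(proteinValues(a), proteinValues(b))
  expect_identical(sampleData(a), sampleData(b))
})

test_that("a null generator carries no class signal", {
  cfg <- synthConfig(nSamples = c(serum = 500), caseFraction = c(serum = 0.5),
                     nProteins = c(v2 = 20, v3 = 20), nOverlap = 20,
                     informative = data.frame(id = "P0001", effect = 0),
                     moduleBlocks = list(), seed = 4)
  pe <- log2AndStandardize(generateCohort(cfg, "serum"))
  case <- sampleData(pe)$status == "case"
  set.seed(1)
  folds <- proteoPanel:::.stratifiedFolds(case, 5)
  fit <- subsetFitness(proteinValues(pe), case, "P0001", folds)
  expect_lt(abs(fit - 0.5), 0.08)
})

test_that("planted log2 effects are realized at their stated size", {
  cfg <- synthConfig(nSamples = c(serum = 400), caseFraction = c(serum = 0.5),
                     nProteins = c(v2 = 30, v3 = 30), nOverlap = 30,
                     informative = data.frame(id = "P0001", effect = 1.0),
                     moduleBlocks = list(), noiseSd = 0.5, seed = 21)
  pe <- generateCohort(cfg, "serum")
  X <- log2(proteinValues(pe))
  case <- sampleData(pe)$status == "case"
  contrast <- mean(X[case, "P0001"]) - mean(X[!case, "P0001"])
  se <- 0.5 * sqrt(1 / sum(case) + 1 / sum(!case))
  expect_lt(abs(contrast - 1.0), 3 * se)
})

test_that("panel versions intersect at the configured overlap", {
  cfg <- synthConfig(nProteins = c(v2 = 1129, v3 = 4006), nOverlap = 1047,
                     nInformative = 5, moduleBlocks = list())
  panels <- panelProteins(cfg)
  expect_length(intersect(panels$v2, panels$v3), 1047L)
  expect_length(panels$v2, 1129L)
  expect_length(panels$v3, 4006L)
})

test_that("attenuation scales cross-modality effect transfer", {
  # zero attenuation: a serum-trained single-protein rule is noise on brain
  cfg <- synthConfig(
    nSamples = c(serum = 300, brain = 300),
    caseFraction = c(serum = 0.5, brain = 0.5),
    nProteins = c(v2 = 30, v3 = 30), nOverlap = 30,
    informative = data.frame(id = "P0001", effect = 1.5),
    moduleBlocks = list(), attenuation = c(serum = 1, brain = 0), seed = 5)
  st <- generateMultimodalStudy(cfg, c("serum", "brain"))
  brainX <- log2(proteinValues(st$brain))
  aucBrain <- rocAuc(brainX[, "P0001"], sampleData(st$brain)$status)
  expect_lt(abs(aucBrain - 0.5), 0.1)

  # full attenuation: per-protein contrasts agree between modalities
  effs <- data.frame(id = sprintf("P%04d", 1:30),
                     effect = seq(0.3, 1.2, length.out = 30))
  cfg2 <- synthConfig(
    nSamples = c(serum = 400, csf = 400),
    caseFraction = c(serum = 0.5, csf = 0.5),
    nProteins = c(v2 = 200, v3 = 200), nOverlap = 200,
    informative = effs, moduleBlocks = list(),
    attenuation = c(serum = 1, csf = 1), seed = 6)
  st2 <- generateMultimodalStudy(cfg2, c("serum", "csf"))
  contrasts <- lapply(st2, function(pe) {
    X <- log2(proteinValues(pe))
    case <- sampleData(pe)$status == "case"
    colMeans(X[case, ]) - colMeans(X[!case, ])
  })
  expect_gt(cor(contrasts$serum, contrasts$csf), 0.7)
})

test_that("batch injection follows its closed-form construction", {
  pe <- makePE(40, 6, state = "raw", seed = 9)
  md <- sampleData(pe)
  md$batch <- rep(c("B1", "B2"), 20)
  pe <- joinSampleMetadata(pe, md)
  delta <- 0.7
  spec <- data.frame(label = c("B1", "B2"), shift = c(delta, -delta),
                     scale = 1)
  shifted <- injectBatchEffects(pe, spec)
  X0 <- log2(proteinValues(pe))
  X <- log2(proteinValues(shifted))
  b <- sampleData(shifted)$batch
  gap0 <- mean(X0[b == "B1", ]) - mean(X0[b == "B2", ])
  gap <- mean(X[b == "B1", ]) - mean(X[b == "B2", ])
  expect_equal(gap - gap0, 2 * delta, tolerance = 1e-8)
  expect_identical(transformState(shifted), "raw")

  ident <- injectBatchEffects(pe, data.frame(label = c("B1", "B2"),
                                             shift = 0, scale = 1))
  expect_equal(proteinValues(ident), proteinValues(pe), tolerance = 1e-10)
  expect_error(
    injectBatchEffects(pe, data.frame(label = "B9", shift = 0, scale = 1)),
    "unknown batch")
})

test_that("a batch shift confounded with status biases the naive contrast", {
  cfg <- synthConfig(nSamples = c(serum = 400), caseFraction = c(serum = 0.5),
                     nProteins = c(v2 = 20, v3 = 20), nOverlap = 20,
                     informative = data.frame(id = "P0001", effect = 0),
                     moduleBlocks = list(), noiseSd = 0.5, seed = 31)
  pe <- generateCohort(cfg, "serum")
  md <- sampleData(pe)
  md$batch <- ifelse(md$status == "case", "B1", "B2")
  pe <- joinSampleMetadata(pe, md)
  shifted <- injectBatchEffects(
    pe, data.frame(label = c("B1", "B2"), shift = c(0.5, -0.5), scale = 1))
  X <- log2(proteinValues(shifted))
  case <- sampleData(shifted)$status == "case"
  contrast <- mean(X[case, "P0002"]) - mean(X[!case, "P0002"])
  se <- 0.5 * sqrt(1 / sum(case) + 1 / sum(!case))
  expect_lt(abs(contrast - 1.0), 3 * se)   # bias equals the shift difference
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(nSamples = c(serum = 10),
                           caseFraction = c(serum = 1.2),
                           nProteins = c(v2 = 20, v3 = 20), nOverlap = 20,
                           nInformative = 2, moduleBlocks = list()),
               "caseFraction")
  expect_error(synthConfig(nSamples = c(serum = 10),
                           caseFraction = c(serum = 0.5),
                           nProteins = c(v2 = 20, v3 = 20), nOverlap = 25,
                           nInformative = 2, moduleBlocks = list()),
               "nOverlap")
  expect_error(synthConfig(nSamples = c(serum = 10),
                           caseFraction = c(serum = 0.5),
                           nProteins = c(v2 = 20, v3 = 20), nOverlap = 20,
                           informative = data.frame(id = "Z9999", effect = 1),
                           moduleBlocks = list()),
               "unknown protein")
})
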