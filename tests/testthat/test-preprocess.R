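test_that("QC filtering applies the closed acceptance interval", {
  pe <- makePE(3, 2, state = "raw")
  sf <- setNames(c(1.0, 0.3, 2.6), sampleIds(pe))
  out <- qcFilterSamples(pe, sf)
  expect_identical(sampleIds(out), sampleIds(pe)[1])
  rep <- S4Vectors::metadata(out)$qcReport
  expect_setequal(rep$sample_id, sampleIds(pe)[2:3])

  sf2 <- setNames(c(0.4, 2.5, 1.0), sampleIds(pe))   # boundaries kept
  expect_identical(ncol(qcFilterSamples(pe, sf2)), 3L)
  sf3 <- setNames(rep(1, 3), sampleIds(pe))
  expect_equal(proteinValues(qcFilterSamples(pe, sf3)), proteinValues(pe))
  expect_error(qcFilterSamples(pe, sf[1:2]), "missing scale factor")
})

test_that("log2 + standardization matches the closed form", {
  m <- matrix(c(1, 2, 4, 8, 2, 32), 3, 2,
              dimnames = list(c("S1", "S2", "S3"), c("A", "B")))
  pe <- ProteinExperiment(m)
  z <- log2AndStandardize(pe)
  expect_equal(unname(proteinValues(z)[, "A"]), c(-1, 0, 1))
  expect_identical(transformState(z), "standardized")

  big <- log2AndStandardize(makePE(50, 8, state = "raw", seed = 2))
  Z <- proteinValues(big)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))

  m[, "B"] <- 4
  expect_error(log2AndStandardize(ProteinExperiment(m)), "zero-variance.*B")
  dropped <- log2AndStandardize(ProteinExperiment(m), onZeroVariance = "drop")
  expect_identical(proteinIds(dropped), "A")
})

test_that("residualization removes covariate structure exactly", {
  n <- 200
  set.seed(3)
  age <- runif(n, 40, 90)
  eps <- rnorm(n, 0, 0.3)
  m <- cbind(exact = 2 * age, noisy = 1 + 0.5 * age + eps,
             indep = rnorm(n))
  rownames(m) <- sprintf("S%03d", 1:n)
  md <- data.frame(sample_id = rownames(m),
                   status = rep(c("case", "control"), n / 2), age = age)
  pe <- ProteinExperiment(m, sampleData = md, transformState = "log2")
  r <- residualizeCovariates(pe, "age")
  R <- proteinValues(r)
  expect_true(all(abs(R[, "exact"]) < 1e-8))
  expect_gt(cor(R[, "indep"], m[, "indep"] - mean(m[, "indep"])), 0.999)
  expect_lt(abs(cor(R[, "noisy"], age)), 1e-8)
  # fitted slope agrees with the normal-equation oracle within 3 SE
  beta <- coef(lm(m[, "noisy"] ~ age))
  expect_lt(abs(beta["age"] - 0.5), 3 * summary(lm(m[, "noisy"] ~ age))$coefficients["age", 2])
  expect_identical(transformState(r), "residualized")

  md$flat <- 1
  pe2 <- ProteinExperiment(m, sampleData = md, transformState = "log2")
  expect_error(residualizeCovariates(pe2, "flat"), "constant")
})

test_that("residualization drops and reports samples with missing covariates", {
  pe <- makePE(30, 4, state = "raw", seed = 8)
  md <- sampleData(pe)
  md$ledd <- c(rep(NA, 3), runif(27, 0, 1000))
  pe <- joinSampleMetadata(pe, md)
  r <- residualizeCovariates(log2Transform(pe), c("age", "ledd"))
  expect_identical(ncol(r), 27L)
  expect_identical(
    S4Vectors::metadata(r)$residualizeReport$nDroppedMissingCovariates, 3L)
})

test_that("batch adjustment equalizes a pure location shift and is a no-op for one batch", {
  pe <- makePE(60, 40, state = "raw", seed = 12)
  md <- sampleData(pe)
  md$batch <- "B1"
  one <- joinSampleMetadata(pe, md)
  expect_equal(proteinValues(combatAdjust(log2Transform(one))),
               proteinValues(log2Transform(one)), tolerance = 1e-8)

  md$batch <- rep(c("B1", "B2"), 30)
  two <- injectBatchEffects(
    joinSampleMetadata(pe, md),
    data.frame(label = c("B1", "B2"), shift = c(0.6, -0.6), scale = 1))
  pre <- proteinValues(log2Transform(two))
  adj <- suppressMessages(combatAdjust(log2Transform(two)))
  X <- proteinValues(adj)
  b <- sampleData(adj)$batch
  gaps <- colMeans(X[b == "B1", ]) - colMeans(X[b == "B2", ])
  expect_lt(abs(mean(gaps)), 0.05)        # 1.2 log2-unit gap removed
  expect_lt(mean(abs(gaps)), 0.25)        # per-protein residual is noise-scale
  # closed-form location behaviour: each batch moved by about -/+ delta
  moved1 <- mean(X[b == "B1", ] - pre[b == "B1", ])
  moved2 <- mean(X[b == "B2", ] - pre[b == "B2", ])
  expect_equal(moved1, -0.6, tolerance = 0.1)
  expect_equal(moved2, 0.6, tolerance = 0.1)

  mdBad <- md; mdBad$batch <- ifelse(md$status == "case", "B1", "B2")
  bad <- joinSampleMetadata(pe, mdBad)
  expect_error(combatAdjust(log2Transform(bad)), "confounded")
  mdOne <- md; mdOne$batch[1] <- "B3"
  expect_error(combatAdjust(log2Transform(joinSampleMetadata(pe, mdOne))),
               "single sample")
})

test_that("batch adjustment preserves a planted status effect", {
  cfg <- synthConfig(nSamples = c(serum = 200), caseFraction = c(serum = 0.5),
                     nProteins = c(v2 = 60, v3 = 60), nOverlap = 60,
                     informative = data.frame(id = "P0001", effect = 0.8),
                     moduleBlocks = list(), noiseSd = 0.5,
                     batchSpec = data.frame(label = c("B1", "B2"),
                                            shift = c(0.5, -0.5), scale = 1,
                                            fraction = 0.5),
                     seed = 13)
  pe <- generateCohort(cfg, "serum")
  adj <- suppressMessages(combatAdjust(log2Transform(pe)))
  X <- proteinValues(adj)
  case <- sampleData(adj)$status == "case"
  contrast <- mean(X[case, "P0001"]) - mean(X[!case, "P0001"])
  se <- 0.5 * sqrt(1 / sum(case) + 1 / sum(!case))
  expect_lt(abs(contrast - 0.8), 3 * se)
})

test_that("the PC scan flags a planted batch shift and stays quiet on noise", {
  set.seed(14)
  n <- 200; p <- 50
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("P%03d", 1:p)))
  batch <- rep(c("A", "B"), n / 2)
  m[batch == "A", ] <- m[batch == "A", ] + 2   # 2-sd shift on every protein
  md <- data.frame(sample_id = rownames(m),
                   status = rep(c("case", "control"), n / 2), batch = batch)
  pe <- ProteinExperiment(scale(m), sampleData = md,
                          transformState = "standardized")
  scan <- pcConfounderScan(pe, "batch", k = 3)
  pc1 <- scan[scan$pc == 1 & scan$confounder == "batch", ]
  expect_true(pc1$flagged)
  expect_lt(pc1$p, 1e-6)

  expect_identical(nrow(pcConfounderScan(pe, "batch", k = 0)), 0L)

  # null calibration: flags on pure noise stay near the alpha level
  flags <- 0L; tests <- 0L
  for (s in 1:10) {
    peN <- makePE(60, 30, seed = 100 + s)
    sc <- pcConfounderScan(peN, c("status", "age"), k = 5, alpha = 0.01)
    flags <- flags + sum(sc$flagged); tests <- tests + nrow(sc)
  }
  expect_lte(flags, 3 * 0.01 * tests + 1)
})

test_that("the normalization chain preserves sample order and end state", {
  pe <- makePE(40, 6, state = "raw", seed = 15)
  sf <- setNames(rep(1, 40), sampleIds(pe))
  out <- residualizeCovariates(log2AndStandardize(qcFilterSamples(pe, sf)),
                               c("age", "sex"))
  expect_identical(sampleIds(out), sampleIds(pe))
  expect_identical(transformState(out), "residualized")
})
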