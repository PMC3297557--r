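test_that("noiseEta is the population coefficient of variation", {
  expect_equal(noiseEta(rep(3, 10)), 0)
  expect_equal(noiseEta(c(1, 3)), 0.5)
  set.seed(9)
  x <- rlnorm(1e5, 0, 0.4)
  expect_equal(noiseEta(x), sqrt(exp(0.4^2) - 1), tolerance = 0.02)
  # scale invariance
  set.seed(10); y <- runif(100, 1, 2)
  expect_equal(noiseEta(y), noiseEta(7.3 * y))
  expect_error(noiseEta(3), "two values")
  expect_error(noiseEta(c(-1, 1)), "zero mean")
})

test_that("cycle stages split the trajectory in the configured time fractions", {
  p <- mitoParams()
  expect_equal(as.character(assignCycleStage(p@VDiv / 2 * 1.01, p)), "G1")
  expect_equal(as.character(assignCycleStage(p@VDiv * 0.999, p)), "G2")
  # dwell times along the stationary trajectory match the stage fractions
  st <- referenceBirthState(p)
  L <- timeToDivision(st, p)
  tt <- seq(0, L, length.out = 20001)[-20001]
  Vt <- vapply(tt, function(t) growCell(st, t, p)@V, 0)
  frac <- table(assignCycleStage(pmin(Vt, p@VDiv), p)) / length(tt)
  expect_equal(as.numeric(frac), unname(p@stageFractions), tolerance = 0.01)
  expect_error(assignCycleStage(p@VDiv * 1.2, p), "range")
})

test_that("zero-noise populations collapse to a deterministic trajectory", {
  p0 <- mitoParams(sigmaV = 1e-12, sigmaF = 1e-12, alphaF = 0.5, betaF = 0.5,
                   vMito = 0.01)   # many tiny mitochondria: negligible noise
  set.seed(11)
  rec <- simulateFixedPopulation(nCells = 30, nDivisions = 900,
                                 burnInCycles = 6)
  set.seed(11)
  rec0 <- simulateFixedPopulation(nCells = 30, nDivisions = 900, params = p0,
                                  burnInCycles = 6)
  cv0 <- noiseEta(cycleRecords(rec0)$cycleLength)
  expect_lt(cv0, 0.01)
  expect_gt(noiseEta(cycleRecords(rec)$cycleLength), 10 * cv0)
  s <- stageResolvedNoise(rec0, minCells = 20)
  expect_true(all(s$eta < 0.01))
})

test_that("the stationary population reproduces the parameterisation targets", {
  set.seed(12)
  rec <- simulateFixedPopulation(nCells = 400, nDivisions = 8000)
  cy <- cycleRecords(rec)
  expect_gt(nrow(cy), 2000)
  # mean control cycle length near 18-20 h
  expect_gt(mean(cy$cycleLength), 15)
  expect_lt(mean(cy$cycleLength), 22)
  # mitochondrial mass distribution skewed towards low values
  M <- snapshotRecords(rec)$M
  expect_gt(mean((M - mean(M))^3) / sd(M)^3, 0)
  # mean ATP sits at the calibrated operating point (1.45 K), i.e. the
  # anchored HeLa mean in mM
  p <- modelParams(rec)
  expect_equal(mean(snapshotRecords(rec)$atp) * p@atpScale, 1.54,
               tolerance = 0.05)
  # sisters: same f at birth, volumes sum to the division volume
  both <- cy[cy$sisterComplete & cy$sisterId %in% cy$cellId, ]
  a <- both[both$cellId < both$sisterId, ]
  b <- both[match(a$sisterId, both$cellId), ]
  expect_true(all(abs(a$f - b$f) < 1e-12))
  expect_true(all(abs(a$birthV + b$birthV - p@VDiv) < 1e-6))
})

test_that("mass at birth predicts cycle length better than volume", {
  set.seed(13)
  rec <- simulateFixedPopulation(nCells = 400, nDivisions = 8000)
  r <- birthCorrelations(rec)
  # raw correlations: negative, mass dominant
  expect_lt(r[["rMassCycle"]], 0)
  expect_gt(abs(r[["rMassCycle"]]), abs(r[["rVolumeCycle"]]))
  # parent-daughter cycle lengths only weakly correlated
  expect_lt(abs(r[["rParentDaughter"]]), 0.4)
  # sister-ratio correlations agree with a direct recomputation
  s <- sisterRatioCorrelations(rec)
  o <- orderedSisterCors(rec)
  expect_equal(s[["rMassRatio"]], o[["mass"]])
  expect_equal(s[["rVolumeRatio"]], o[["volume"]])
  expect_gt(abs(s[["rMassRatio"]]), abs(s[["rVolumeRatio"]]))
  expect_error(birthCorrelations(rec, minCycles = 1e7), "completed cycles")
})

test_that("fixed-size and exponential protocols agree in distribution", {
  set.seed(14)
  fx <- simulateFixedPopulation(nCells = 400, nDivisions = 8000)
  ex <- simulateExponential(nMax = 4096)
  expect_equal(ex@nCells, 4096)
  snF <- snapshotRecords(fx); snE <- snapshotRecords(ex)
  iF <- sample(nrow(snF), 300); iE <- sample(nrow(snE), 300)
  for (v in c("V", "M", "f")) {
    pv <- suppressWarnings(ks.test(snF[[v]][iF], snE[[v]][iE])$p.value)
    expect_gt(pv, 0.01)
  }
  # exponential-growth volume distribution decays above the birth band
  p <- modelParams(ex)
  dens <- hist(snE$V, breaks = seq(0, p@VDiv, length.out = 13),
               plot = FALSE)$density
  upper <- dens[8:12]   # above ~0.58 VDiv, beyond the birth-volume band
  expect_true(all(diff(upper) < 0))
})

test_that("tiny exponential trees have the exact expected shape", {
  set.seed(15)
  ex2 <- simulateExponential(nMax = 2)
  expect_equal(ex2@nCells, 2)
  expect_equal(nrow(cycleRecords(ex2)), 1)   # exactly one division
  # zero noise: a perfect binary tree with equal cycle lengths per generation
  p0 <- mitoParams(sigmaV = 1e-12, sigmaF = 1e-12, alphaF = 0.5, betaF = 0.5,
                   vMito = 0.01)
  set.seed(16)
  ex0 <- simulateExponential(nMax = 16, params = p0)
  cy <- cycleRecords(ex0)
  # all post-founder cycles collapse to one length (binomial splitting of
  # the many tiny mitochondrial units leaves only sub-percent granularity)
  post <- cy$cycleLength[cy$birthTime > 0]
  expect_gt(length(post), 5)
  expect_lt(diff(range(post)) / mean(post), 0.05)
  expect_lt(noiseEta(post), 0.01)
})

test_that("oxidant treatments order cycle length and noise", {
  ox <- oxidantScan(nCells = 200, nDivisions = 4000, seed = 17)
  m <- setNames(ox$meanCycleLength, ox$treatment)
  e <- setNames(ox$etaTranscription, ox$treatment)
  expect_lt(m[["antioxidant"]], m[["control"]])
  expect_lt(m[["control"]], m[["prooxidant"]])
  expect_lt(e[["antioxidant"]], e[["control"]])
  expect_lt(e[["control"]], e[["prooxidant"]])
  # scaling betaF scales the stationary mean functionality proportionally
  f1 <- functionalityStationaryMoments(mitoParams(betaF = 0.5))[["mean"]]
  f2 <- functionalityStationaryMoments(mitoParams(betaF = 1.0))[["mean"]]
  expect_equal(f2 / f1, 2)
})

test_that("removing noise sources never increases eta (paired seeds)", {
  base <- noiseSurface(0.34, 30, nCells = 150, nDivisions = 3000, seed = 18)
  lowF <- noiseSurface(0.17, 30, nCells = 150, nDivisions = 3000, seed = 18)
  lowM <- noiseSurface(0.34, 15, nCells = 150, nDivisions = 3000, seed = 18)
  noV <- noiseSurface(0.34, 30, nCells = 150, nDivisions = 3000, seed = 18,
                      freezeVolumeNoise = TRUE)
  expect_lt(lowF[1, 1], base[1, 1])
  expect_lt(lowM[1, 1], base[1, 1])
  expect_lte(noV[1, 1], base[1, 1] * 1.02)
  expect_error(noiseSurface(0.34, 0.005, nCells = 50, nDivisions = 500),
               "1e8")
})

test_that("the calibration scaffold recovers a known growth constant", {
  p <- mitoParams()
  # self-consistency: targets generated at the default parameters
  truth <- calibrateModel(targets = NULL, freeParams = character(0),
                          params = p, seed = 19)
  tgt <- truth$summaries[["meanCycleLength"]]
  # perturb beta and ask the 1-D search to recover the cycle length
  pOff <- mitoParams(beta = p@beta * 1.6, alpha = p@beta * 1.6 / 0.1)
  fit <- calibrateModel(targets = c(meanCycleLength = tgt),
                        freeParams = "beta", params = pOff, seed = 19)
  expect_lt(abs(fit$params@beta - p@beta) / p@beta, 0.1)
  expect_lt(fit$loss, 1e-3)
  # empty free-parameter set returns the inputs unchanged
  same <- calibrateModel(targets = c(meanCycleLength = tgt),
                         freeParams = character(0), params = p, seed = 19)
  expect_identical(same$params, p)
})
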