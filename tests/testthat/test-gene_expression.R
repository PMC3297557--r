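test_that("analytic moments reduce to the known limits", {
  # constant rate, long times: Poisson stationary mean = variance = lambda/delta
  r <- linearRate(10, 0, 1000)
  m <- analyticMrnaMoments(r, 0.25, 0, 200)
  expect_equal(m$mean, 40, tolerance = 1e-10)
  expect_equal(m$variance, 40, tolerance = 1e-10)
  # pure death: binomial thinning of the initial molecules
  r0 <- linearRate(0, 0, 100)
  m0 <- analyticMrnaMoments(r0, 0.3, 5, 4)
  e <- exp(-0.3 * 4)
  expect_equal(m0$mean, 5 * e)
  expect_equal(m0$variance, 5 * e * (1 - e))
  expect_error(analyticMrnaMoments(linearRate(1, -0.5, 1.9), 0.2, 0, 1.95),
               "window")
})

test_that("analytic moments and distribution match the master-equation oracle", {
  r <- linearRate(8, 0.9, 10)
  for (tt in c(2.5, 7)) {
    pd <- analyticMrnaDistribution(r, 0.4, 3, tt)
    po <- masterEquationDistribution(r, 0.4, 3, tt, nMax = length(pd) - 1)
    expect_lt(0.5 * sum(abs(pd - po)), 1e-6)          # total variation
    # moments from the distribution equal the closed-form moments
    n <- as.numeric(names(pd))
    mom <- analyticMrnaMoments(r, 0.4, 3, tt)
    expect_equal(sum(n * pd), mom$mean, tolerance = 1e-8)
    expect_equal(sum(n^2 * pd) - sum(n * pd)^2, mom$variance,
                 tolerance = 1e-7)
    expect_true(all(pd >= 0))
    expect_equal(sum(pd), 1, tolerance = 1e-8)
  }
  # t = 0 from an empty cell: point mass at zero
  p0 <- analyticMrnaDistribution(r, 0.4, 0, 0, nMax = 5)
  expect_equal(unname(p0), c(1, 0, 0, 0, 0, 0))
  # constant-rate case is exactly Poisson
  rc <- linearRate(6, 0, 50)
  pc <- analyticMrnaDistribution(rc, 0.5, 0, 3, nMax = 40)
  expect_equal(unname(pc), dpois(0:40, 6 / 0.5 * (1 - exp(-0.5 * 3))),
               tolerance = 1e-12)
})

test_that("both inhomogeneous SSA methods are exact", {
  r <- linearRate(10, 0.8, 10)
  tpts <- c(2, 4, 6, 8, 10)
  mom <- analyticMrnaMoments(r, 0.25, 0, tpts)
  for (method in c("inversion", "thinning")) {
    set.seed(20)
    cc <- ssaBirthDeath(r, 0.25, 0, tpts, nReps = 5000, method = method)
    se <- sqrt(mom$variance / 5000)
    expect_true(all(abs(colMeans(cc) - mom$mean) < 3 * se))
    expect_true(all(abs(apply(cc, 2, var) / mom$variance - 1) < 0.15))
  }
  # the two samplers agree in distribution at a fixed time
  set.seed(21)
  a <- ssaBirthDeath(r, 0.25, 0, 6, nReps = 4000, method = "inversion")[, 1]
  b <- ssaBirthDeath(r, 0.25, 0, 6, nReps = 4000, method = "thinning")[, 1]
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
  # constant propensities reduce to the homogeneous Poisson process:
  # unit-interval increments of the birth-only count are iid Poisson(5)
  set.seed(22)
  birthsOnly <- ssaBirthDeath(linearRate(5, 0, 2000), 1e-12, 0,
                              seq(1, 2000, by = 1), nReps = 1,
                              method = "thinning")
  inc <- diff(c(0, birthsOnly[1, ]))
  expect_equal(mean(inc), 5, tolerance = 0.05)
  expect_gt(var(inc) / mean(inc), 0.9)
  expect_lt(var(inc) / mean(inc), 1.1)
  expect_lt(abs(cor(inc[-1], inc[-length(inc)])), 0.06)
  # zero propensities: nothing happens
  quiet <- ssaBirthDeath(linearRate(0, 0, 10), 0.5, 0, c(1, 5, 10),
                         nReps = 3)
  expect_true(all(quiet == 0))
})

test_that("stationary mRNA under constant rates is Poisson", {
  set.seed(23)
  cc <- ssaBirthDeath(linearRate(20, 0, 40), 0.5, 0, 40, nReps = 10000)[, 1]
  expect_gt(var(cc) / mean(cc), 0.95)
  expect_lt(var(cc) / mean(cc), 1.05)
})

test_that("extrinsic variability raises ensemble mRNA noise", {
  rec <- sharedPopulation()
  set.seed(24)
  intr <- mrnaNoiseExperiment(rec, mode = "intrinsic_only", nCells = 500,
                              sampleTimes = c(0, 4, 8, 12))
  set.seed(25)
  extr <- mrnaNoiseExperiment(rec, mode = "with_extrinsic", nCells = 500,
                              sampleTimes = c(0, 4, 8, 12))
  expect_true(is.na(intr$eta[1]))          # zero mean at t = 0
  # intrinsic-only noise is Poisson-like at late times
  late <- nrow(intr)
  expect_equal(intr$eta[late], 1 / sqrt(intr$mean[late]), tolerance = 0.15)
  # extrinsic noise dominates at every positive time
  expect_true(all(extr$eta[-1] > intr$eta[-1]))
  expect_gt(extr$eta[late] / intr$eta[late], 2)
})

test_that("dual-reporter scenarios separate noise sources", {
  rec <- sharedPopulation()
  set.seed(26)
  mito <- dualReporterSimulation(rec, nCells = 150, nCycles = 5,
                                 synchronised = FALSE,
                                 mitoVolumeNoise = TRUE)
  set.seed(27)
  cyc <- dualReporterSimulation(rec, nCells = 150, nCycles = 5,
                                synchronised = FALSE,
                                mitoVolumeNoise = FALSE)
  set.seed(28)
  syncQuiet <- dualReporterSimulation(rec, nCells = 120, nCycles = 5,
                                      synchronised = TRUE,
                                      mitoVolumeNoise = FALSE)
  spread <- function(d) unname(quantile(d$p1, 0.95) / quantile(d$p1, 0.05))
  # cycle-position alone spans about a two-fold range; mitochondrial noise
  # spreads expression far beyond it
  expect_lt(spread(cyc), 2.6)
  expect_gt(spread(mito), 2)
  expect_gt(spread(mito), spread(cyc))
  # with all extrinsic sources off and synchronised sampling the reporters
  # sit at the intrinsic-noise floor, tightly on the diagonal
  dec <- noiseDecomposition(syncQuiet$p1, syncQuiet$p2)
  expect_lt(dec[["etaTot"]], 0.1)
  expect_gt(cor(syncQuiet$p1, syncQuiet$p2), -0.5)  # no induced anticorrelation
  # cells with higher f*M express more protein
  expect_gt(cor(mito$fM, (mito$p1 + mito$p2) / 2, method = "spearman"), 0)
  # normalisation: highest expression level is 1
  expect_equal(max(mito$p1n, mito$p2n), 1)
})

test_that("the low-copy variant lowers copy number and raises intrinsic noise", {
  rec <- sharedPopulation()
  set.seed(29)
  ref <- dualReporterSimulation(rec, expressionParams("reference"),
                                nCells = 100, nCycles = 4,
                                mitoVolumeNoise = FALSE)
  set.seed(30)
  low <- dualReporterSimulation(rec, expressionParams("lowcopy"),
                                nCells = 100, nCycles = 4,
                                mitoVolumeNoise = FALSE)
  expect_lt(mean(low$p1), mean(ref$p1) / 20)
  expect_gt(noiseDecomposition(low$p1, low$p2)[["etaInt"]],
            noiseDecomposition(ref$p1, ref$p2)[["etaInt"]])
})

test_that("the dual-reporter decomposition recovers known mixtures", {
  set.seed(31)
  n <- 2e4
  # shared gamma-distributed rate: eta_ext^2 = 1/shape, eta_int^2 = 1/mean
  shape <- 4; scale <- 25
  lam <- rgamma(n, shape, scale = scale)          # mean 100
  p1 <- rpois(n, lam); p2 <- rpois(n, lam)
  d <- noiseDecomposition(p1, p2)
  expect_equal(d[["etaExt"]], sqrt(1 / shape), tolerance = 0.05)
  expect_equal(d[["etaInt"]], sqrt(1 / (shape * scale)), tolerance = 0.05)
  # identical reporters: all noise is extrinsic
  x <- rpois(n, 50) + 1
  dx <- noiseDecomposition(x, x)
  expect_equal(dx[["etaInt"]], 0)
  expect_equal(dx[["etaExt"]], dx[["etaTot"]])
  # independent identically distributed reporters: extrinsic vanishes
  di <- noiseDecomposition(rpois(n, 50), rpois(n, 50))
  expect_lt(di[["etaExt"]], 0.03)
  expect_error(noiseDecomposition(1:50, 1:50), "100")
})

test_that("rate scaling onto a reference is linear", {
  expect_equal(scaleRatesToReference(40, 40), 1)
  expect_equal(scaleRatesToReference(40, 80), 2)
  expect_equal(scaleRatesToReference(40, 20) * 2,
               scaleRatesToReference(40, 40))
  expect_error(scaleRatesToReference(0, 1), "positive")
  # after scaling, the simulated stationary mean matches lambda/delta
  rec <- sharedPopulation()
  meanT <- mean(snapshotRecords(rec)$transcriptionRate)
  sc <- scaleRatesToReference(meanT, 20)
  set.seed(32)
  cc <- ssaBirthDeath(linearRate(sc * meanT, 0, 60), 0.5, 0, 40,
                      nReps = 3000)[, 1]
  expect_equal(mean(cc), 20 / 0.5, tolerance = 0.03)
})
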