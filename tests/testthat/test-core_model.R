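test_that("ATP concentration follows the density law and its invariances", {
  p <- mitoParams(c = 1, vMito = 1)
  expect_equal(atpConcentration(list(V = 5, M = 10, f = 2), p), 4)
  expect_equal(atpConcentration(list(V = 7, M = 7, f = 1), p), 1)
  # homogeneous of degree 0 in (M, V)
  p2 <- mitoParams()
  a1 <- atpConcentration(list(V = 1500, M = 12, f = 1.3), p2)
  a2 <- atpConcentration(list(V = 3 * 1500, M = 3 * 12, f = 1.3), p2)
  expect_equal(a1, a2)
  # monotone in f and M, antitone in V
  expect_gt(atpConcentration(list(V = 1500, M = 13, f = 1), p2), a0 <-
              atpConcentration(list(V = 1500, M = 12, f = 1), p2))
  expect_gt(atpConcentration(list(V = 1500, M = 12, f = 1.1), p2), a0)
  expect_lt(atpConcentration(list(V = 1600, M = 12, f = 1), p2), a0)
  expect_error(atpConcentration(list(V = -1, M = 1, f = 1), p2), "positive")
})

test_that("transcription rate is a bounded monotone sigmoid", {
  p <- mitoParams()
  expect_equal(transcriptionRate(0, p), p@T0)
  expect_equal(transcriptionRate(p@K, p), p@T0 + p@TMax / 2)
  expect_lt(abs(transcriptionRate(1e6 * p@K, p) - (p@T0 + p@TMax)),
            1e-3 * p@TMax)
  atp <- seq(0, 300, by = 0.5)
  expect_true(all(diff(transcriptionRate(atp, p)) >= 0))
  expect_true(all(transcriptionRate(atp, p) <= p@T0 + p@TMax))
  expect_error(transcriptionRate(-1, p), "non-negative")
})

test_that("closed-form growth matches an RK4 oracle and has the density fixed point", {
  p <- mitoParams()
  st <- cellState(V = 1500, M = 20, f = 1.2)
  expect_equal(growCell(st, 0, p)@V, st@V)
  expect_equal(growCell(st, 0, p)@M, st@M)
  g <- growCell(st, 1, p)
  o <- rk4Growth(st@V, st@M * p@vMito, st@f, 1, p)
  expect_lt(abs(g@V - o$V) / o$V, 1e-6)
  expect_lt(abs(g@M * p@vMito - o$m) / o$m, 1e-6)
  # a full cycle
  L <- timeToDivision(st, p)
  g2 <- growCell(st, L, p)
  o2 <- rk4Growth(st@V, st@M * p@vMito, st@f, L, p, nSteps = 20000)
  expect_lt(abs(g2@V - o2$V) / o2$V, 1e-6)
  # density beta/alpha is a fixed point of the density dynamics
  rho <- densityTarget(p)
  stEq <- cellState(V = 1500, M = rho * 1500 / p@vMito, f = 1)
  gEq <- growCell(stEq, 7, p)
  expect_equal(gEq@M * p@vMito / gEq@V, rho, tolerance = 1e-12)
  # monotone approach to the fixed point from both sides
  stHi <- cellState(V = 1500, M = 2 * rho * 1500 / p@vMito, f = 1)
  dens <- sapply(c(0, 3, 6, 9), function(t) {
    g <- growCell(stHi, t, p); g@M * p@vMito / g@V
  })
  expect_true(all(diff(dens) < 0) && all(dens > rho))
  expect_error(growCell(st, -1, p), "non-negative")
})

test_that("division time inverts the growth solution", {
  p <- mitoParams()
  near <- cellState(V = p@VDiv * (1 - 1e-12), M = 25, f = 1)
  expect_lt(timeToDivision(near, p), 1e-9)
  st <- cellState(V = p@VDiv / 2,
                  M = densityTarget(p) * p@VDiv / 2 / p@vMito, f = 1)
  tstar <- timeToDivision(st, p)
  expect_equal(growCell(st, tstar, p)@V, p@VDiv, tolerance = 1e-9)
  expect_lt(abs(tstar - bisectDivisionTime(st, p)), 1e-6)
  # doubling f halves nothing else: division time strictly decreases in f
  st2 <- cellState(V = st@V, M = st@M, f = 2)
  expect_lt(timeToDivision(st2, p), tstar)
  expect_equal(timeToDivision(st2, p), tstar / 2, tolerance = 1e-12)
  expect_error(timeToDivision(cellState(V = p@VDiv, M = 10, f = 1), p),
               "threshold")
  expect_equal(timeToDivision(cellState(V = 100, M = 0, f = 1), p), Inf)
})

test_that("mitosis conserves volume and mass and shares functionality", {
  p <- mitoParams()
  set.seed(5)
  for (i in 1:200) {
    M <- sample(1:60, 1)
    st <- cellState(V = p@VDiv, M = M, f = runif(1, 0.3, 2))
    d <- divideCell(st, p)
    expect_identical(d@daughterA@V + d@daughterB@V, st@V)
    expect_identical(d@daughterA@M + d@daughterB@M, as.numeric(M))
    expect_identical(d@daughterA@f, d@daughterB@f)
    expect_gte(d@daughterA@f, p@fMin)
  }
  # binomial n = 1: one daughter gets the whole mitochondrion
  d1 <- divideCell(cellState(V = p@VDiv, M = 1, f = 1), p)
  expect_setequal(c(d1@daughterA@M, d1@daughterB@M), c(0, 1))
  expect_error(divideCell(cellState(V = p@VDiv / 2, M = 5, f = 1), p),
               "threshold")
})

test_that("binomial partitioning has the right moments and zero-noise limit", {
  p <- mitoParams()
  set.seed(6)
  M <- 40
  Ma <- replicate(2e4, {
    d <- divideCell(cellState(V = p@VDiv, M = M, f = 1), p)
    d@daughterA@M
  })
  expect_equal(mean(Ma), M / 2, tolerance = 0.01)
  expect_equal(var(Ma), M / 4, tolerance = 0.05)
  # zero-noise limit: deterministic symmetric division, f' = f
  p0 <- mitoParams(sigmaV = 1e-12, sigmaF = 1e-12, alphaF = 0.5,
                   betaF = 0.5)
  d <- divideCell(cellState(V = p0@VDiv, M = 30, f = 1), p0)
  expect_equal(d@daughterA@V, d@daughterB@V, tolerance = 1e-6)
  expect_equal(d@daughterA@f, 1, tolerance = 1e-6)
})

test_that("AR(1) stationary moments are exact and recovered by simulation", {
  expect_equal(
    functionalityStationaryMoments(mitoParams(alphaF = 0.5, betaF = 0.5)),
    c(mean = 1, variance = 0.34^2 / (1 - 0.25)))
  expect_equal(functionalityStationaryMoments(
    mitoParams(alphaF = 0.5, betaF = 0.69))[["mean"]], 1.38)
  expect_equal(functionalityStationaryMoments(
    mitoParams(alphaF = 0.5, betaF = 0.09))[["mean"]], 0.18)
  p <- mitoParams()
  set.seed(7)
  f <- numeric(1e5); f[1] <- 1
  for (i in 2:1e5) f[i] <- sampleFunctionality(f[i - 1], p)
  mom <- functionalityStationaryMoments(p)
  expect_equal(mean(f), mom[["mean"]], tolerance = 0.01)
  # the floor at fMin censors the lower tail, shaving a few percent off the
  # uncensored stationary variance
  expect_equal(var(f), mom[["variance"]], tolerance = 0.1)
  expect_lte(var(f), mom[["variance"]])
})

test_that("virtual-mitochondrion partitioning standard deviation", {
  expect_equal(virtualMitoSD(12, 12), 6)           # n = 1: half of one unit
  s1 <- virtualMitoSD(300, 12)                     # n = 25
  s2 <- virtualMitoSD(300, 3)                      # n = 100: quadrupled
  expect_equal(s1 / s2, 2)
  set.seed(8)
  draws <- rbinom(1e6, 25, 0.5) * 12
  expect_equal(sd(draws), s1, tolerance = 0.01)
  expect_error(virtualMitoSD(300, 0), "positive")
})
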