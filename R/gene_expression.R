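# Downstream mRNA/protein dynamics on growing cells.
#
# Within one cell cycle the transcription rate T(t) is well approximated by
# a straight line (the analytic growth solution is smooth and the cycle is
# short compared to the sigmoid's curvature scale), which makes the
# birth-death master equation for mRNA copy number solvable in closed form
# by the generating-function method and keeps the stochastic simulation
# exact via closed-form integrated-hazard inversion.

#' Linear within-cycle approximation of a cell's transcription rate
#'
#' Builds the [LinearRate-class] for the mRNA birth rate of one cell:
#' the transcription-rate trajectory along the closed-form growth solution,
#' anchored at birth and at division (slope from the endpoints), scaled by
#' \code{exprParams@lambdaMScale}.
#'
#' @param state a [CellState-class] at birth.
#' @param params a [MitoParams-class].
#' @param exprParams an [ExpressionParams-class].
#' @return a [LinearRate-class] valid over the cell's cycle.
#' @export
linearRateFromCell <- function(state, params = mitoParams(),
                               exprParams = expressionParams()) {
  L <- timeToDivision(state, params)
  T0 <- transcriptionRate(atpConcentration(state, params), params)
  atEnd <- growCell(state, L * (1 - 1e-9), params)
  T1 <- transcriptionRate(atpConcentration(atEnd, params), params)
  linearRate(lambda0 = exprParams@lambdaMScale * T0,
             slope = exprParams@lambdaMScale * (T1 - T0) / L, tMax = L)
}

#' Closed-form moments of mRNA copy number under a linear birth rate
#'
#' For the birth-death process with birth rate
#' \eqn{\lambda(t) = \lambda_0 + s t} and per-molecule death rate
#' \eqn{\delta}, started from a deterministic count \eqn{n_0}, the
#' generating-function solution factorises into a binomially thinned
#' initial population and a Poisson immigrant population with mean
#' \deqn{I(t) = \frac{\lambda_0}{\delta}(1 - e^{-\delta t}) +
#'   \frac{s}{\delta}\left(t - \frac{1 - e^{-\delta t}}{\delta}\right),}
#' giving mean \eqn{n_0 e^{-\delta t} + I(t)} and variance
#' \eqn{n_0 e^{-\delta t}(1 - e^{-\delta t}) + I(t)}.
#'
#' @param rate a [LinearRate-class] (must be valid at \code{t}).
#' @param deltaM mRNA degradation rate (per h), > 0.
#' @param n0 initial copy number.
#' @param t time (h); vectorised.
#' @return data frame with columns \code{t}, \code{mean}, \code{variance}.
#' @export
analyticMrnaMoments <- function(rate, deltaM, n0 = 0, t) {
  checkRateWindow(rate, t)
  e <- exp(-deltaM * t)
  I <- rate@lambda0 / deltaM * (1 - e) +
    rate@slope / deltaM * (t - (1 - e) / deltaM)
  data.frame(t = t, mean = n0 * e + I, variance = n0 * e * (1 - e) + I)
}

checkRateWindow <- function(rate, t) {
  if (any(t < 0)) stop("t must be non-negative")
  if (any(t > rate@tMax * (1 + 1e-9)))
    stop("t outside the validity window of the linear rate")
  if (min(rate@lambda0, rate@lambda0 + rate@slope * max(t)) < 0)
    stop("birth rate is negative on [0, t]")
  invisible(TRUE)
}

#' Closed-form mRNA copy-number distribution under a linear birth rate
#'
#' Evaluates \eqn{P(n, t)} for the process of [analyticMrnaMoments()]: the
#' exact solution is the convolution of \eqn{Binomial(n_0, e^{-\delta t})}
#' (surviving initial molecules) with \eqn{Poisson(I(t))} (immigrants), a
#' terminating confluent-hypergeometric (Kummer) series evaluated here in
#' its numerically stable convolution form.
#'
#' @inheritParams analyticMrnaMoments
#' @param nMax truncation: probabilities are returned for counts
#'   \code{0:nMax} (default mean + 10 standard deviations).
#' @return numeric vector of probabilities over counts \code{0:nMax}.
#' @export
analyticMrnaDistribution <- function(rate, deltaM, n0 = 0, t, nMax = NULL) {
  stopifnot(length(t) == 1L)
  mom <- analyticMrnaMoments(rate, deltaM, n0, t)
  if (is.null(nMax))
    nMax <- ceiling(mom$mean + 10 * sqrt(mom$variance)) + n0
  e <- exp(-deltaM * t)
  I <- mom$mean - n0 * e
  surv <- dbinom(0:min(n0, nMax), n0, e)
  imm <- dpois(0:nMax, I)
  p <- vapply(0:nMax, function(n) {
    k <- 0:min(n0, n)
    sum(surv[k + 1] * imm[n - k + 1])
  }, 0)
  names(p) <- 0:nMax
  p
}

#' Truncated master-equation oracle for the linear-rate birth-death process
#'
#' Integrates the (truncated) master equation
#' \deqn{dP_n/dt = \lambda(t) P_{n-1} + \delta (n+1) P_{n+1}
#'   - (\lambda(t) + \delta n) P_n}
#' with \pkg{deSolve}. Used as an independent numerical check of the
#' closed-form solution and of the stochastic samplers.
#'
#' @inheritParams analyticMrnaDistribution
#' @param rtol,atol integrator tolerances.
#' @return probability vector over counts \code{0:nMax} at time \code{t}.
#' @export
masterEquationDistribution <- function(rate, deltaM, n0 = 0, t, nMax = NULL,
                                       rtol = 1e-10, atol = 1e-12) {
  stopifnot(length(t) == 1L)
  mom <- analyticMrnaMoments(rate, deltaM, n0, t)
  if (is.null(nMax))
    nMax <- ceiling(mom$mean + 10 * sqrt(mom$variance)) + n0
  P0 <- numeric(nMax + 1)
  P0[n0 + 1] <- 1
  n <- 0:nMax
  rhs <- function(tt, P, parms) {
    lam <- rate@lambda0 + rate@slope * tt
    dP <- -(lam + deltaM * n) * P
    dP[-1] <- dP[-1] + lam * P[-length(P)]
    dP[-length(P)] <- dP[-length(P)] + deltaM * n[-1] * P[-1]
    # reflecting top boundary: no birth out of the last state
    dP[length(P)] <- dP[length(P)] + lam * 0
    list(dP)
  }
  out <- deSolve::ode(P0, c(0, t), rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  p <- pmax(out[nrow(out), -1], 0)
  names(p) <- n
  p / sum(p)
}

#' Exact stochastic simulation of the linear-rate birth-death channel
#'
#' Samples the time-inhomogeneous jump process with birth rate
#' \eqn{\lambda(t) = \lambda_0 + s t} and death rate \eqn{\delta n},
#' statistically exactly, by either of two methods: thinning against the
#' per-interval upper bound of the birth propensity, or closed-form
#' inversion of the integrated hazard (exact because the hazard integral is
#' quadratic in the waiting time). Both samplers draw from the same process
#' law and are cross-validated in the test suite.
#'
#' @param rate a [LinearRate-class]; must be non-negative over the sampled
#'   window (unbounded or negative propensities are refused).
#' @param deltaM death rate (per h).
#' @param n0 initial copy number.
#' @param sampleTimes increasing times at which counts are recorded.
#' @param nReps number of independent trajectories.
#' @param method \code{"inversion"} or \code{"thinning"}.
#' @return integer matrix \code{nReps x length(sampleTimes)} of counts.
#' @export
ssaBirthDeath <- function(rate, deltaM, n0 = 0, sampleTimes, nReps = 1,
                          method = c("inversion", "thinning")) {
  method <- match.arg(method)
  sampleTimes <- sort(sampleTimes)
  checkRateWindow(rate, sampleTimes)
  .ssaLinearBD(rate@lambda0, rate@slope, deltaM, as.integer(n0),
               as.numeric(sampleTimes), as.integer(nReps),
               if (method == "thinning") 0L else 1L)
}

# simulate one cell's mRNA trajectory: linear rate over its cycle, constant
# at the division-time value afterwards; returns counts at sampleTimes
mrnaCellTrajectory <- function(rate, deltaM, sampleTimes) {
  L <- rate@tMax
  inCycle <- sampleTimes <= L
  n <- integer(length(sampleTimes))
  nAtL <- 0L
  if (any(inCycle)) {
    ts <- c(sampleTimes[inCycle], L)
    counts <- .ssaLinearBD(rate@lambda0, rate@slope, deltaM, 0L, ts, 1L, 1L)
    n[inCycle] <- counts[1, seq_len(sum(inCycle))]
    nAtL <- counts[1, length(ts)]
  } else {
    nAtL <- .ssaLinearBD(rate@lambda0, rate@slope, deltaM, 0L, L, 1L, 1L)[1, 1]
  }
  if (any(!inCycle)) {
    lamEnd <- rateAt(rate, L)
    n[!inCycle] <- .ssaLinearBD(lamEnd, 0, deltaM, nAtL,
                                sampleTimes[!inCycle] - L, 1L, 1L)[1, ]
  }
  n
}

#' Ensemble mRNA noise with and without extrinsic variability
#'
#' Reproduces the mRNA-expression experiment: every cell starts with zero
#' mRNA at its birth and transcribes at its own (linearly approximated)
#' rate. In \code{mode = "intrinsic_only"}, all cells share the rate
#' trajectory of a reference cell fixed at the population means of (V, M,
#' f), so ensemble variability is purely intrinsic; in
#' \code{mode = "with_extrinsic"}, each cell's rate follows its own (V, M,
#' f) drawn from the stationary heterogeneous population, adding extrinsic
#' transcription-rate noise. Beyond a cell's own cycle the rate is held at
#' its division-time value.
#'
#' @param population a [PopulationRecord-class] with completed cycles.
#' @param exprParams an [ExpressionParams-class].
#' @param mode \code{"with_extrinsic"} or \code{"intrinsic_only"}.
#' @param sampleTimes observation times (h) from cell birth.
#' @param nCells ensemble size.
#' @return data frame (time, mean, sd, eta); eta is NA where the mean is 0.
#' @export
mrnaNoiseExperiment <- function(population, exprParams = expressionParams(),
                                mode = c("with_extrinsic", "intrinsic_only"),
                                sampleTimes = seq(0, 12, by = 1),
                                nCells = 1000) {
  mode <- match.arg(mode)
  cy <- population@cycles
  if (!nrow(cy)) stop("population has no completed cycles")
  params <- modelParams(population)
  if (mode == "intrinsic_only") {
    ref <- cellState(V = mean(cy$birthV), M = mean(cy$birthM),
                     f = mean(cy$f))
    rates <- rep(list(linearRateFromCell(ref, params, exprParams)), nCells)
  } else {
    idx <- sample.int(nrow(cy), nCells, replace = nrow(cy) < nCells)
    rates <- lapply(idx, function(i)
      linearRateFromCell(cellState(V = cy$birthV[i], M = max(cy$birthM[i], 1),
                                   f = cy$f[i]), params, exprParams))
  }
  counts <- vapply(rates, mrnaCellTrajectory, integer(length(sampleTimes)),
                   deltaM = exprParams@deltaM, sampleTimes = sampleTimes)
  counts <- matrix(counts, nrow = length(sampleTimes))
  mn <- rowMeans(counts)
  sdv <- apply(counts, 1, sd)
  data.frame(time = sampleTimes, mean = mn, sd = sdv,
             eta = ifelse(mn > 0, sdv / mn, NA_real_))
}

#' Dual-reporter expression simulation
#'
#' Tracks two identically regulated genes (two mRNAs, two proteins) in each
#' cell of a population. Each cell is a lineage simulated over several cell
#' cycles: the shared transcription rate follows the cell's growth
#' trajectory (linear within each cycle), proteins are translated at
#' \code{lambdaP} per mRNA (optionally scaled by the cell's relative ATP
#' level), all species degrade linearly, and every species is partitioned
#' binomially at mitosis. Expression is sampled in the final cycle at a
#' random phase (unsynchronised) or at a fixed phase (synchronised).
#'
#' With \code{mitoVolumeNoise = FALSE} all extrinsic inheritance noise is
#' removed: cells start at the population mean state, divide exactly in
#' half, and keep functionality at its stationary mean, so only cell-cycle
#' position (if unsynchronised) and intrinsic reaction noise remain.
#'
#' @param population a stationary [PopulationRecord-class].
#' @param exprParams an [ExpressionParams-class].
#' @param nCells number of independent lineages.
#' @param nCycles cycles simulated per lineage (expression equilibrates
#'   over the first few).
#' @param synchronised sample all cells at \code{phase} instead of a random
#'   cycle phase.
#' @param mitoVolumeNoise include mitochondrial/volume/functionality
#'   inheritance noise.
#' @param atpCoupledTranslation scale the translation rate by the cell's
#'   ATP level relative to the population operating point.
#' @param phase fixed sampling phase when \code{synchronised}.
#' @return data frame with per-cell counts (m1, m2, p1, p2), protein levels
#'   normalised to the population maximum (p1n, p2n), and the cell's
#'   mitochondrial mass-functionality product \code{fM}.
#' @export
dualReporterSimulation <- function(population,
                                   exprParams = expressionParams(),
                                   nCells = 300, nCycles = 6,
                                   synchronised = FALSE,
                                   mitoVolumeNoise = TRUE,
                                   atpCoupledTranslation = TRUE,
                                   phase = 0.5) {
  params <- modelParams(population)
  cy <- population@cycles
  if (!nrow(cy)) stop("population has no completed cycles")
  refAtp <- params@c * densityTarget(params) *
    functionalityStationaryMoments(params)[["mean"]]
  fbar <- functionalityStationaryMoments(params)[["mean"]]
  rho <- densityTarget(params)
  out <- vector("list", nCells)
  for (cell in seq_len(nCells)) {
    if (mitoVolumeNoise) {
      i <- sample.int(nrow(cy), 1)
      V <- cy$birthV[i]; M <- max(cy$birthM[i], 1); f <- cy$f[i]
    } else {
      V <- params@VDiv / 2; M <- rho * V / params@vMito; f <- fbar
    }
    lam0 <- slope <- L <- tf <- numeric(nCycles)
    for (k in seq_len(nCycles)) {
      st <- cellState(V = V, M = M, f = f)
      r <- linearRateFromCell(st, params, exprParams)
      L[k] <- r@tMax; lam0[k] <- r@lambda0; slope[k] <- r@slope
      mid <- growCell(st, L[k] / 2, params)
      tf[k] <- if (atpCoupledTranslation)
        atpConcentration(mid, params) / refAtp else 1
      # next generation: follow one daughter
      atDiv <- growCell(st, L[k] * (1 - 1e-12), params)
      Mdiv <- round(atDiv@M)
      if (mitoVolumeNoise) {
        q <- min(params@qClip[2], max(params@qClip[1],
                                      rnorm(1, 0.5, params@sigmaV)))
        M <- rbinom(1, Mdiv, 0.5)
        f <- sampleFunctionality(f, params)
        V <- q * params@VDiv
        if (M < 1) M <- 1   # lineage must stay viable
      } else {
        q <- 0.5; M <- Mdiv / 2; V <- params@VDiv / 2
      }
    }
    samplePhase <- if (synchronised) phase else runif(1)
    cnt <- .dualReporterLineage(lam0, slope, L, tf, exprParams@deltaM,
                                exprParams@lambdaP, exprParams@deltaP,
                                c(0L, 0L, 0L, 0L), samplePhase)
    out[[cell]] <- data.frame(m1 = cnt[1], m2 = cnt[2], p1 = cnt[3],
                              p2 = cnt[4], fM = f * M * params@vMito,
                              phase = samplePhase)
  }
  res <- do.call(rbind, out)
  pmax <- max(res$p1, res$p2, 1)
  res$p1n <- res$p1 / pmax
  res$p2n <- res$p2 / pmax
  res
}

#' Dual-reporter decomposition of expression noise
#'
#' The standard decomposition from paired measurements of two identically
#' regulated reporters:
#' \deqn{\eta_{int}^2 = \langle (p_1 - p_2)^2 \rangle /
#'   (2 \langle p_1 \rangle \langle p_2 \rangle), \quad
#'   \eta_{ext}^2 = cov(p_1, p_2) / (\langle p_1 \rangle \langle p_2
#'   \rangle), \quad \eta_{tot}^2 = \eta_{int}^2 + \eta_{ext}^2.}
#'
#' @param p1,p2 paired reporter levels (length >= 100).
#' @return named vector \code{c(etaInt, etaExt, etaTot)}.
#' @export
noiseDecomposition <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("p1 and p2 must be paired")
  if (length(p1) < 100) stop("need at least 100 paired observations")
  m1 <- mean(p1); m2 <- mean(p2)
  if (m1 == 0 || m2 == 0) stop("zero mean expression")
  etaInt2 <- mean((p1 - p2)^2) / (2 * m1 * m2)
  n <- length(p1)
  etaExt2 <- mean((p1 - m1) * (p2 - m2)) / (m1 * m2)
  c(etaInt = sqrt(max(etaInt2, 0)), etaExt = sqrt(max(etaExt2, 0)),
    etaTot = sqrt(max(etaInt2 + etaExt2, 0)))
}

#' Map the model's transcription-rate scale onto a reference birth rate
#'
#' Linear rescaling: the factor by which model transcription rates must be
#' multiplied so the population mean maps onto a reference mRNA birth rate.
#'
#' @param meanTranscriptionRate population mean transcription rate (a.u./h).
#' @param referenceBirthRate target mean mRNA birth rate (molecules/h).
#' @return the multiplicative scale factor.
#' @export
scaleRatesToReference <- function(meanTranscriptionRate, referenceBirthRate) {
  if (meanTranscriptionRate <= 0 || referenceBirthRate <= 0)
    stop("rates must be positive")
  referenceBirthRate / meanTranscriptionRate
}
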