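#' @import methods
#' @importFrom stats rnorm rbinom runif sd cor var optim optimise ks.test
#'   rpois dpois dbinom quantile setNames
#' @importFrom utils write.csv read.csv modifyList packageVersion
#' @useDynLib mitonoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Model parameters of the mitochondrial-variability growth model
#'
#' Holds every constant of the single-cell growth and inheritance model:
#' the growth couplings of volume and mitochondrial mass to ATP
#' concentration, the ATP proportionality constant, the mitosis volume
#' threshold, the stochastic-partitioning scales, the AR(1) parameters of
#' functionality inheritance, and the sigmoidal transcription-rate curve.
#'
#' Units: volumes in \eqn{\mu m^3}, times in hours, ATP concentration in the
#' units of the measured transcription-rate curve (multiply by
#' \code{atpScale} to convert to mM), transcription rate in arbitrary units
#' per hour.
#'
#' @slot alpha volume growth coupling (per ATP unit per h).
#' @slot beta mitochondrial growth coupling (per ATP unit per h). The
#'   population mitochondrial volume density relaxes to \code{beta/alpha}.
#' @slot c proportionality between \eqn{f M v_{mito} / V} and ATP
#'   concentration.
#' @slot atpScale mM per model ATP unit, anchoring the population mean to
#'   measured HeLa ATP levels.
#' @slot VDiv volume threshold for mitosis (\eqn{\mu m^3}).
#' @slot sigmaV standard deviation of the daughter volume fraction.
#' @slot qClip admissible range of the daughter volume fraction.
#' @slot vMito volume of one virtual mitochondrion (\eqn{\mu m^3}).
#' @slot alphaF AR(1) memory term of functionality inheritance.
#' @slot betaF AR(1) mean-setting term (0.5 control, 0.69 anti-oxidant,
#'   0.09 pro-oxidant).
#' @slot sigmaF AR(1) innovation standard deviation.
#' @slot fMin functionality floor; proposals below it are resampled.
#' @slot TMax,K,hillN,T0 sigmoid transcription-rate parameters: maximum
#'   rate, half-saturation ATP level, Hill exponent, and basal rate.
#' @slot stageFractions named fractions of cycle time spent in G1, S, G2.
#' @export
setClass("MitoParams", representation(
  alpha = "numeric", beta = "numeric", c = "numeric", atpScale = "numeric",
  VDiv = "numeric", sigmaV = "numeric", qClip = "numeric",
  vMito = "numeric", alphaF = "numeric", betaF = "numeric",
  sigmaF = "numeric", fMin = "numeric",
  TMax = "numeric", K = "numeric", hillN = "numeric", T0 = "numeric",
  stageFractions = "numeric"))

setValidity("MitoParams", function(object) {
  msg <- character()
  pos <- c(alpha = object@alpha, beta = object@beta, c = object@c,
           VDiv = object@VDiv, vMito = object@vMito, sigmaF = object@sigmaF,
           fMin = object@fMin, TMax = object@TMax, K = object@K,
           hillN = object@hillN, atpScale = object@atpScale)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("must be strictly positive:",
                                       paste(bad, collapse = ", ")))
  if (object@alphaF < 0 || object@alphaF >= 1)
    msg <- c(msg, "alphaF must lie in [0, 1)")
  if (object@sigmaV <= 0 || object@sigmaV >= 0.5)
    msg <- c(msg, "sigmaV must lie in (0, 0.5)")
  if (object@T0 < 0) msg <- c(msg, "T0 must be non-negative")
  if (length(object@qClip) != 2L || object@qClip[1] <= 0 ||
      object@qClip[2] >= 1 || object@qClip[1] >= object@qClip[2])
    msg <- c(msg, "qClip must be an increasing pair inside (0, 1)")
  sf <- object@stageFractions
  if (length(sf) != 3L || !all(names(sf) == c("G1", "S", "G2")) ||
      any(sf <= 0) || abs(sum(sf) - 1) > 1e-8)
    msg <- c(msg, "stageFractions must be named (G1, S, G2) and sum to 1")
  if (length(msg)) msg else TRUE
})

#' State of a single cell
#'
#' A cell is characterised by its volume, its mitochondrial mass expressed
#' as a count of fixed-volume virtual mitochondria (physical mitochondrial
#' volume is \code{M * vMito(params)}), and a functionality multiplier f
#' that scales mitochondrial ATP output and is redrawn only at division.
#'
#' @slot V cell volume (\eqn{\mu m^3}).
#' @slot M virtual-mitochondrion count (non-negative integer-valued).
#' @slot f mitochondrial functionality (dimensionless, > 0).
#' @slot birthTime simulation time of birth (h).
#' @slot cellId,parentId,sisterId lineage identifiers (NA when unknown).
#' @export
setClass("CellState", representation(
  V = "numeric", M = "numeric", f = "numeric", birthTime = "numeric",
  cellId = "integer", parentId = "integer", sisterId = "integer"))

setValidity("CellState", function(object) {
  msg <- character()
  if (!is.finite(object@V) || object@V <= 0) msg <- c(msg, "V must be > 0")
  if (!is.finite(object@M) || object@M < 0)
    msg <- c(msg, "M must be non-negative")
  if (!is.finite(object@f) || object@f <= 0) msg <- c(msg, "f must be > 0")
  if (length(msg)) msg else TRUE
})

#' Outcome of one mitosis event
#'
#' @slot daughterA,daughterB the two daughter cells. Daughter volumes sum to
#'   the parent volume and daughter mitochondrial masses to the parent mass;
#'   both daughters carry the same freshly drawn functionality.
#' @slot volumeFraction the drawn daughter volume fraction q.
#' @slot mitoCountToA virtual mitochondria assigned to daughter A.
#' @export
setClass("DivisionOutcome", representation(
  daughterA = "CellState", daughterB = "CellState",
  volumeFraction = "numeric", mitoCountToA = "numeric"))

#' Record of a simulated cell population
#'
#' @slot snapshots data frame of time-stamped per-cell states
#'   (time, cellId, V, M, f, atp, transcriptionRate, age, cyclePhase).
#' @slot cycles data frame of completed cell cycles (cellId, parentId,
#'   sisterId, birthTime, birthV, birthM, f, cycleLength, parentCycleLength,
#'   sisterComplete).
#' @slot protocol \code{"fixed_size_replacement"} or
#'   \code{"exponential_growth"}.
#' @slot params the \code{MitoParams} used.
#' @slot nCells population size (fixed protocol) or maximum size reached.
#' @slot burnIn time before which events are excluded from \code{cycles}.
#' @export
setClass("PopulationRecord", representation(
  snapshots = "data.frame", cycles = "data.frame", protocol = "character",
  params = "MitoParams", nCells = "numeric", burnIn = "numeric"))

setValidity("PopulationRecord", function(object) {
  msg <- character()
  if (!object@protocol %in% c("fixed_size_replacement", "exponential_growth"))
    msg <- c(msg, "unknown protocol")
  if (nrow(object@cycles) && any(object@cycles$cycleLength <= 0))
    msg <- c(msg, "cycle lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' Reaction-rate parameters for mRNA and protein expression
#'
#' Birth and death rates of the downstream expression model riding on the
#' growing cell. The mRNA birth rate is the cell's transcription rate times
#' \code{lambdaMScale}; mRNA and protein are degraded linearly and proteins
#' translated at \code{lambdaP} per mRNA. \code{degradationMultiplier}
#' scales both degradation rates to explore low-copy-number regimes.
#'
#' @slot lambdaMScale factor mapping model transcription rate (a.u./h) to
#'   mRNA birth rate (molecules/h).
#' @slot deltaM mRNA degradation rate (per h).
#' @slot lambdaP translation rate per mRNA (per h).
#' @slot deltaP protein degradation rate (per h).
#' @slot degradationMultiplier 1 for the reference parameterisation, 100
#'   for the low-copy variant.
#' @export
setClass("ExpressionParams", representation(
  lambdaMScale = "numeric", deltaM = "numeric", lambdaP = "numeric",
  deltaP = "numeric", degradationMultiplier = "numeric"))

setValidity("ExpressionParams", function(object) {
  v <- c(object@lambdaMScale, object@deltaM, object@lambdaP, object@deltaP,
         object@degradationMultiplier)
  if (any(!is.finite(v) | v < 0)) return("all rates must be non-negative")
  if (object@deltaM <= 0 || object@deltaP <= 0)
    return("degradation rates must be positive")
  TRUE
})

#' A linearly time-varying reaction rate
#'
#' \eqn{\lambda(t) = \lambda_0 + s t}, valid on \code{[0, tMax]}, used as
#' the within-cycle linear approximation of the transcription rate.
#'
#' @slot lambda0 rate at the start of the interval (per h).
#' @slot slope rate change (per h^2).
#' @slot tMax end of the validity interval (h).
#' @export
setClass("LinearRate", representation(
  lambda0 = "numeric", slope = "numeric", tMax = "numeric"))

setValidity("LinearRate", function(object) {
  if (object@tMax < 0) return("tMax must be non-negative")
  if (object@lambda0 < 0 || object@lambda0 + object@slope * object@tMax < 0)
    return("rate must be non-negative on [0, tMax]")
  TRUE
})

#' Basin-of-attraction map of a fate-decision ODE model
#'
#' @slot model \code{"huang"} or \code{"chickarmane"}.
#' @slot phi transcription-rate multiplier applied to production terms.
#' @slot grid data frame of initial conditions and attractor labels.
#' @slot fractions named basin fractions (sum to 1, including
#'   \code{unresolved}).
#' @slot fixedPoints matrix of stable fixed points located by root-finding.
#' @slot box upper corner of the integration bounding box.
#' @export
setClass("BasinMap", representation(
  model = "character", phi = "numeric", grid = "data.frame",
  fractions = "numeric", fixedPoints = "matrix", box = "numeric"))

setValidity("BasinMap", function(object) {
  if (abs(sum(object@fractions) - 1) > 1e-8)
    return("basin fractions must sum to 1")
  TRUE
})

setMethod("show", "MitoParams", function(object) {
  cat("MitoParams (mitochondrial-variability growth model)\n")
  cat(sprintf("  growth: alpha=%.4g beta=%.4g (density -> beta/alpha = %.3g)\n",
              object@alpha, object@beta, object@beta / object@alpha))
  cat(sprintf("  ATP: c=%.4g a.u. (%.3g mM per a.u.)\n",
              object@c, object@atpScale))
  cat(sprintf("  mitosis: VDiv=%.4g um^3, sigmaV=%.3g, vMito=%.3g um^3\n",
              object@VDiv, object@sigmaV, object@vMito))
  cat(sprintf("  functionality AR(1): alphaF=%.3g betaF=%.3g sigmaF=%.3g fMin=%.3g\n",
              object@alphaF, object@betaF, object@sigmaF, object@fMin))
  cat(sprintf("  transcription: T0=%.3g + TMax=%.4g * A^%g/(K^%g + A^%g), K=%.4g\n",
              object@T0, object@TMax, object@hillN, object@hillN,
              object@hillN, object@K))
  invisible(object)
})

setMethod("show", "CellState", function(object) {
  cat(sprintf("CellState: V=%.4g um^3, M=%g virtual mitochondria, f=%.4g\n",
              object@V, object@M, object@f))
  invisible(object)
})

setMethod("show", "PopulationRecord", function(object) {
  cat(sprintf("PopulationRecord (%s): %d cells, %d snapshot rows, %d completed cycles\n",
              object@protocol, object@nCells, nrow(object@snapshots),
              nrow(object@cycles)))
  invisible(object)
})

setMethod("show", "BasinMap", function(object) {
  cat(sprintf("BasinMap: %s model, phi=%g, %d grid points, box [0, %.3g]\n",
              object@model, object@phi, nrow(object@grid), object@box))
  print(round(object@fractions, 4))
  invisible(object)
})
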