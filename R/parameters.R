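#' Default model parameterisation
#'
#' Constructs a [MitoParams-class] object. Defaults reproduce, under the
#' fixed-size population protocol, the summary statistics used to
#' parameterise the model: a mean control cell-cycle length near 18-20 h, a
#' population mean ATP level on the upper shoulder of the measured
#' sigmoidal transcription-rate curve (1.4 times its half-saturation
#' constant, anchored to a mean HeLa ATP concentration of 1.54 mM via
#' \code{atpScale}), sister-pair segregation noise for volume and
#' mitochondrial mass, and transcription-rate noise of about 0.4 in each
#' cell-cycle stage.
#'
#' The AR(1) functionality parameters \code{alphaF = 0.5},
#' \code{betaF = 0.5}, \code{sigmaF = 0.34} give a stationary mean
#' functionality of 1 in the control condition; \code{betaF = 0.69} and
#' \code{betaF = 0.09} model anti- and pro-oxidant treatment. The sigmoid
#' fit values \code{TMax = 51.2} and \code{K = 44.7} come from the measured
#' transcription-rate/ATP relationship.
#'
#' @param ... named replacements for any slot, e.g.
#'   \code{mitoParams(betaF = 0.69)} for the anti-oxidant condition.
#' @return a validated \code{MitoParams} object.
#' @examples
#' p <- mitoParams()
#' functionalityStationaryMoments(p)   # mean 1 in the control condition
#' @export
mitoParams <- function(...) {
  cc <- 1.45 * 44.7 / 0.1         # population mean ATP at 1.45 K, density 0.1
  beta <- log(2) / (20 * cc)      # beta*c sets the ~20 h growth timescale
  defaults <- list(
    alpha = beta / 0.1, beta = beta, c = cc,
    atpScale = 1.54 / (1.45 * 44.7),
    VDiv = 3000, sigmaV = 0.04, qClip = c(0.1, 0.9),
    vMito = 12,
    alphaF = 0.5, betaF = 0.5, sigmaF = 0.34, fMin = 0.01,
    TMax = 51.2, K = 44.7, hillN = 4, T0 = 0,
    stageFractions = c(G1 = 0.5, S = 0.3, G2 = 0.2))
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown MitoParams field(s): ", paste(unknown, collapse = ", "))
  vals <- modifyList(defaults, user)
  do.call(new, c(list("MitoParams"), vals))
}

#' Construct a cell state
#'
#' @param V cell volume (\eqn{\mu m^3}).
#' @param M virtual-mitochondrion count.
#' @param f mitochondrial functionality.
#' @param birthTime time of birth (h).
#' @param cellId,parentId,sisterId lineage identifiers.
#' @return a validated [CellState-class] object.
#' @export
cellState <- function(V, M, f = 1, birthTime = 0, cellId = NA_integer_,
                      parentId = NA_integer_, sisterId = NA_integer_) {
  new("CellState", V = as.numeric(V), M = as.numeric(M), f = as.numeric(f),
      birthTime = as.numeric(birthTime),
      cellId = as.integer(cellId), parentId = as.integer(parentId),
      sisterId = as.integer(sisterId))
}

#' A cell at the stationary birth point
#'
#' Returns the deterministic birth state: half the division volume, at the
#' asymptotic mitochondrial density \code{beta/alpha}, functionality at the
#' stationary AR(1) mean.
#'
#' @param params a [MitoParams-class] object.
#' @return a [CellState-class].
#' @export
referenceBirthState <- function(params = mitoParams()) {
  V <- params@VDiv / 2
  M <- params@beta / params@alpha * V / params@vMito
  f <- functionalityStationaryMoments(params)[["mean"]]
  cellState(V = V, M = M, f = f)
}

#' Expression-model rate parameters
#'
#' Reference birth/death rates for the mRNA-and-protein model. The
#' reference set produces high protein copy numbers and hence very low
#' intrinsic noise; \code{variant = "lowcopy"} multiplies both degradation
#' rates by 100, lowering copy numbers about 100-fold and raising intrinsic
#' noise accordingly.
#'
#' @param variant \code{"reference"} or \code{"lowcopy"}.
#' @param ... named overrides of individual slots.
#' @return an [ExpressionParams-class] object.
#' @export
expressionParams <- function(variant = c("reference", "lowcopy"), ...) {
  variant <- match.arg(variant)
  mult <- if (variant == "lowcopy") 100 else 1
  defaults <- list(lambdaMScale = 0.5, deltaM = 0.25 * mult,
                   lambdaP = 10, deltaP = 0.05 * mult,
                   degradationMultiplier = mult)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ExpressionParams field(s): ", paste(unknown, collapse = ", "))
  vals <- modifyList(defaults, user)
  do.call(new, c(list("ExpressionParams"), vals))
}

#' @rdname linearRate
#' @export
linearRate <- function(lambda0, slope = 0, tMax = Inf) {
  new("LinearRate", lambda0 = lambda0, slope = slope, tMax = tMax)
}

#' Linearly time-varying rate
#'
#' \code{linearRate()} builds a [LinearRate-class];
#' \code{rateAt()} evaluates it.
#'
#' @param lambda0 rate at t = 0 (per h).
#' @param slope rate change (per h^2).
#' @param tMax validity horizon (h).
#' @param rate a \code{LinearRate}.
#' @param t time (h).
#' @name linearRate
#' @export
rateAt <- function(rate, t) rate@lambda0 + rate@slope * t

# --- simple accessors -------------------------------------------------------

#' Accessors for model objects
#'
#' Small read-only accessors for the S4 containers: mitochondrial volume
#' density target, virtual mitochondrion volume, division threshold,
#' completed-cycle and snapshot tables of a population record, and basin
#' fractions of a basin map.
#'
#' @param x a model object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
densityTarget <- function(x) x@beta / x@alpha

#' @rdname accessors
#' @export
vMito <- function(x) x@vMito

#' @rdname accessors
#' @export
divisionVolume <- function(x) x@VDiv

#' @rdname accessors
#' @export
cycleRecords <- function(x) x@cycles

#' @rdname accessors
#' @export
snapshotRecords <- function(x) x@snapshots

#' @rdname accessors
#' @export
modelParams <- function(x) x@params

#' @rdname accessors
#' @export
basinFractions <- function(x) x@fractions
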