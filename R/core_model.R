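#' ATP concentration of a cell
#'
#' ATP concentration is proportional to the product of mitochondrial
#' functionality and mitochondrial volume density:
#' \deqn{A = c \, f \, M v_{mito} / V.}
#' It is strictly increasing in f and M, strictly decreasing in V, and
#' invariant under joint scaling of M and V.
#'
#' @param state a [CellState-class], or a list/data frame with columns
#'   \code{V}, \code{M}, \code{f} (vectorised).
#' @param params a [MitoParams-class].
#' @return ATP concentration in model units (multiply by
#'   \code{params@atpScale} for mM).
#' @export
atpConcentration <- function(state, params = mitoParams()) {
  if (is(state, "CellState"))
    state <- list(V = state@V, M = state@M, f = state@f)
  if (any(state$V <= 0)) stop("cell volume must be positive")
  params@c * state$f * state$M * params@vMito / state$V
}

#' Transcription rate as a sigmoidal function of ATP
#'
#' \deqn{T(A) = T_0 + T_{max} A^h / (K^h + A^h)}
#' A monotone non-decreasing Hill curve bounded by \eqn{T_0 + T_{max}},
#' approximating the measured dependence of whole-nucleus transcription
#' rate on ATP concentration (which folds in ATP-dependent chromatin
#' remodelling).
#'
#' @param atp ATP concentration (model units, >= 0); vectorised.
#' @param params a [MitoParams-class].
#' @return transcription rate (a.u. per h).
#' @export
transcriptionRate <- function(atp, params = mitoParams()) {
  if (any(atp < 0)) stop("ATP concentration must be non-negative")
  h <- params@hillN
  params@T0 + params@TMax * atp^h / (params@K^h + atp^h)
}

# closed-form (V, m) advance; m is physical mitochondrial volume.
# dm/dt = beta*A*V = beta*c*f*m  and  dV/dt = alpha*A*V = (alpha/beta) dm/dt,
# so m grows exponentially and V gains (alpha/beta) of the mass increment.
growVm <- function(V, m, f, dt, params) {
  m1 <- m * exp(params@beta * params@c * f * dt)
  V1 <- V + (params@alpha / params@beta) * (m1 - m)
  list(V = V1, m = m1)
}

#' Deterministic growth of a cell between divisions
#'
#' Advances volume and mitochondrial mass by the closed-form solution of
#' the coupled growth dynamics
#' \deqn{dM/dt = \beta A V / v_{mito}, \quad dV/dt = \alpha A V,}
#' with \eqn{A = c f M v_{mito} / V}: mitochondrial mass grows
#' exponentially at rate \eqn{\beta c f} and volume gains
#' \eqn{\alpha/\beta} of every unit of mitochondrial volume added.
#' Mitochondrial volume density therefore relaxes monotonically towards
#' \eqn{\beta/\alpha}. Functionality stays constant within a cycle.
#'
#' The continuous-mass solution is used within a cycle; \code{M} is kept
#' real-valued during growth and the division operation re-discretises the
#' virtual-mitochondrion count.
#'
#' @param state a [CellState-class].
#' @param dt duration (h), >= 0. The caller is responsible for keeping
#'   V(t+dt) at or below the division threshold (use [timeToDivision()]).
#' @param params a [MitoParams-class].
#' @return the advanced [CellState-class].
#' @export
growCell <- function(state, dt, params = mitoParams()) {
  if (dt < 0) stop("dt must be non-negative")
  g <- growVm(state@V, state@M * params@vMito, state@f, dt, params)
  initialize(state, V = g$V, M = g$m / params@vMito)
}

#' Time until the division threshold is reached
#'
#' Inverts the closed-form growth solution: the unique t* with
#' \eqn{V(t^*) = V_{div}},
#' \deqn{t^* = \frac{1}{\beta c f}
#'   \log\!\left(1 + \frac{\beta}{\alpha}\,\frac{V_{div} - V}{M v_{mito}}\right).}
#' Finite for every valid state with positive mitochondrial mass; infinite
#' for a cell with no mitochondria, which cannot grow.
#'
#' @param state a [CellState-class] with \code{V < VDiv}.
#' @param params a [MitoParams-class].
#' @return time to mitosis (h).
#' @export
timeToDivision <- function(state, params = mitoParams()) {
  if (state@V >= params@VDiv) stop("cell is already at the division threshold")
  m <- state@M * params@vMito
  if (m <= 0) return(Inf)
  x <- (params@beta / params@alpha) * (params@VDiv - state@V) / m
  log1p(x) / (params@beta * params@c * state@f)
}

# vectorised division-time kernel used by the population simulators
timeToDivisionVec <- function(V, M, f, params) {
  m <- M * params@vMito
  x <- (params@beta / params@alpha) * (params@VDiv - V) / m
  out <- log1p(x) / (params@beta * params@c * f)
  out[m <= 0] <- Inf
  out
}

#' Draw the next functionality value
#'
#' One step of the AR(1) inheritance process
#' \eqn{f' = \alpha_f f + \beta_f + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma_f^2)}, resampled until \eqn{f' \ge f_{min}} (at most 1e6 draws).
#'
#' @param f parent functionality; vectorised.
#' @param params a [MitoParams-class].
#' @return the daughter functionality (shared by both daughters).
#' @export
sampleFunctionality <- function(f, params = mitoParams()) {
  out <- params@alphaF * f + params@betaF + rnorm(length(f), 0, params@sigmaF)
  tries <- 0L
  while (any(bad <- out < params@fMin)) {
    tries <- tries + 1L
    if (tries > 1e6L) stop("functionality resampling failed to terminate")
    out[bad] <- params@alphaF * f[bad] + params@betaF +
      rnorm(sum(bad), 0, params@sigmaF)
  }
  out
}

#' Stochastic partitioning at mitosis
#'
#' The parent (at the division threshold) splits into two daughters:
#' \itemize{
#'   \item volume fraction \eqn{q \sim N(0.5, \sigma_V^2)} clipped to
#'     \code{qClip}; daughter volumes \eqn{qV} and \eqn{(1-q)V};
#'   \item each of the \code{round(M)} virtual mitochondria assigned to
#'     either daughter with probability 1/2 (binomial partitioning),
#'     independent of the volume draw;
#'   \item both daughters inherit the same new functionality drawn from the
#'     AR(1) process ([sampleFunctionality()]).
#' }
#' Volume and mass are conserved exactly.
#'
#' @param state parent [CellState-class] with \code{V} at the division
#'   threshold (relative tolerance \code{tol}).
#' @param params a [MitoParams-class].
#' @param tol relative tolerance on \code{V == VDiv}.
#' @return a [DivisionOutcome-class].
#' @export
divideCell <- function(state, params = mitoParams(), tol = 1e-6) {
  if (abs(state@V - params@VDiv) > tol * params@VDiv)
    stop("cell volume must equal the division threshold at mitosis")
  if (state@M < 0) stop("mitochondrial mass must be non-negative")
  Mtot <- round(state@M)
  q <- min(params@qClip[2], max(params@qClip[1], rnorm(1, 0.5, params@sigmaV)))
  Ma <- rbinom(1, Mtot, 0.5)
  fNew <- sampleFunctionality(state@f, params)
  id <- state@cellId
  da <- cellState(V = q * state@V, M = Ma, f = fNew,
                  birthTime = state@birthTime, parentId = id)
  db <- cellState(V = (1 - q) * state@V, M = Mtot - Ma, f = fNew,
                  birthTime = state@birthTime, parentId = id)
  new("DivisionOutcome", daughterA = da, daughterB = db,
      volumeFraction = q, mitoCountToA = Ma)
}

#' Stationary moments of the functionality AR(1) process
#'
#' For the uncensored process \eqn{f' = \alpha_f f + \beta_f + \epsilon}:
#' mean \eqn{\beta_f/(1-\alpha_f)} and variance
#' \eqn{\sigma_f^2/(1-\alpha_f^2)}. The floor at \code{fMin} makes the
#' simulated process very slightly different; the censoring correction is
#' negligible when \code{fMin} is far below the mean.
#'
#' @param params a [MitoParams-class] (requires \code{alphaF < 1}).
#' @return named vector \code{c(mean, variance)}.
#' @export
functionalityStationaryMoments <- function(params = mitoParams()) {
  if (params@alphaF >= 1) stop("AR(1) process is non-stationary for alphaF >= 1")
  c(mean = params@betaF / (1 - params@alphaF),
    variance = params@sigmaF^2 / (1 - params@alphaF^2))
}

#' Standard deviation of inherited mitochondrial volume
#'
#' With n = M/v virtual mitochondria of volume v partitioned binomially,
#' the standard deviation of the inherited mitochondrial volume is
#' \eqn{v \sqrt{n} / 2}: at fixed total mass, more and smaller
#' mitochondrial units mean less partitioning noise.
#'
#' @param mitoVolume total mitochondrial volume at mitosis (\eqn{\mu m^3}).
#' @param vMito volume of one virtual mitochondrion (\eqn{\mu m^3}).
#' @return standard deviation of daughter mitochondrial volume.
#' @export
virtualMitoSD <- function(mitoVolume, vMito) {
  if (any(vMito <= 0)) stop("vMito must be positive")
  if (any(mitoVolume <= 0)) stop("mitoVolume must be positive")
  vMito * sqrt(mitoVolume / vMito) / 2
}
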