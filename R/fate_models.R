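# GATA1/PU.1 lineage-decision ODE systems and basin-of-attraction analysis.
#
# Two architectures are analysed under a multiplicative transcription-rate
# factor phi applied to all production terms:
#  * a symmetric two-gene system with Hill self-activation and
#    cross-repression (the classic bistable-plus-progenitor switch);
#  * an asymmetric three-species extension in which a species X, driven by
#    GATA1, represses all PU.1 production, so the GATA1 arm strengthens
#    with transcription rate.

#' Parameters of the symmetric two-gene fate model
#'
#' @param a self-activation rate (both genes).
#' @param b cross-repression (repression-relief) rate.
#' @param k linear decay rate.
#' @param theta Hill threshold.
#' @param n Hill exponent.
#' @return named list of class \code{huangParams}.
#' @export
huangParams <- function(a = 1, b = 1, k = 1, theta = 0.5, n = 4) {
  stopifnot(a > 0, b > 0, k > 0, theta > 0, n > 0)
  structure(list(a = a, b = b, k = k, theta = theta, n = n),
            class = "huangParams")
}

#' Parameters of the asymmetric three-species fate model
#'
#' A symmetric core (as in [huangParams()]) for GATA1 (G) and PU.1 (P),
#' plus a species X that is promoted by GATA1 (production
#' \eqn{\phi a_X G^2}, non-saturating, so the GATA1-X arm strengthens with
#' transcription rate) and represses all PU.1 production through a factor
#' \eqn{1/(1 + c_X X)}. External signals: \code{sG} and \code{sP} promote
#' GATA1 and PU.1 production additively and \code{sX} represses X. The
#' default analysis uses \code{sG = sX = 0} with \code{sP > 0} so PU.1 can
#' be expressed at all.
#'
#' @param a,b,k,theta,n symmetric-core parameters as in [huangParams()].
#' @param sG,sP,sX external signal terms.
#' @param aX production coupling of X to GATA1.
#' @param cX repression strength of X on PU.1.
#' @param kX decay rate of X.
#' @return named list of class \code{chickarmaneParams}.
#' @export
chickarmaneParams <- function(a = 1, b = 1, k = 1, theta = 0.5, n = 4,
                              sG = 0, sP = 0.35, sX = 0,
                              aX = 0.3, cX = 0.6, kX = 1) {
  stopifnot(a > 0, b >= 0, k > 0, theta > 0, n > 0, aX > 0, cX >= 0, kX > 0,
            sG >= 0, sP >= 0, sX >= 0)
  structure(list(a = a, b = b, k = k, theta = theta, n = n, sG = sG,
                 sP = sP, sX = sX, aX = aX, cX = cX, kX = kX),
            class = "chickarmaneParams")
}

#' Right-hand side of the symmetric fate model
#'
#' \deqn{dx/dt = \phi\,[a x^n/(\theta^n + x^n) +
#'   b \theta^n/(\theta^n + y^n)] - k x,} and symmetrically for y.
#'
#' @param x,y expression levels (>= 0) of the two lineage regulators.
#' @param params a [huangParams()] list.
#' @param phi transcription-rate multiplier on the production terms.
#' @return numeric \code{c(dx, dy)}.
#' @export
huangRHS <- function(x, y, params = huangParams(), phi = 1) {
  if (x < 0 || y < 0) stop("expression levels must be non-negative")
  with(params, {
    thn <- theta^n
    c(phi * (a * x^n / (thn + x^n) + b * thn / (thn + y^n)) - k * x,
      phi * (a * y^n / (thn + y^n) + b * thn / (thn + x^n)) - k * y)
  })
}

#' Right-hand side of the asymmetric three-species fate model
#'
#' @param G,P,X concentrations (>= 0) of GATA1, PU.1 and the intermediate
#'   species.
#' @param params a [chickarmaneParams()] list.
#' @param phi transcription-rate multiplier on the production terms.
#' @return numeric \code{c(dG, dP, dX)}.
#' @export
chickarmaneRHS <- function(G, P, X, params = chickarmaneParams(), phi = 1) {
  if (G < 0 || P < 0 || X < 0) stop("concentrations must be non-negative")
  with(params, {
    thn <- theta^n
    c(phi * (a * G^n / (thn + G^n) + b * thn / (thn + P^n) + sG) - k * G,
      phi * (a * P^n / (thn + P^n) + b * thn / (thn + G^n) + sP) /
        (1 + cX * X) - k * P,
      phi * aX * G^2 / (1 + sX) - kX * X)
  })
}

fateParsVector <- function(model, params) {
  if (model == "huang")
    with(params, c(a, b, k, theta, n))
  else
    with(params, c(a, b, k, theta, n, sG, sP, sX, aX, cX, kX))
}

fateDim <- function(model) if (model == "huang") 2L else 3L

fateRhsFun <- function(model, params, phi) {
  if (model == "huang")
    function(s) huangRHS(s[1], s[2], params, phi)
  else
    function(s) chickarmaneRHS(s[1], s[2], s[3], params, phi)
}

#' Classify a converged trajectory endpoint
#'
#' A cell state is undifferentiated when the two lineage regulators are
#' within \code{ratioThreshold}-fold of one another
#' (\eqn{|\log(x/y)| < \log(\mathrm{ratioThreshold})}); otherwise the
#' dominant regulator names the lineage. Non-converged trajectories are
#' labelled \code{unresolved}.
#'
#' @param endpoint numeric state vector (first two components are the
#'   lineage regulators).
#' @param converged logical convergence flag from the integrator.
#' @param ratioThreshold fold-difference separating balanced from dominant
#'   expression (default 3).
#' @return one of \code{"undifferentiated"}, \code{"lineage_1"},
#'   \code{"lineage_2"}, \code{"unresolved"}.
#' @export
classifyAttractor <- function(endpoint, converged = TRUE,
                              ratioThreshold = 3) {
  if (!converged) return("unresolved")
  x <- max(endpoint[1], 1e-12)
  y <- max(endpoint[2], 1e-12)
  if (abs(log(x / y)) < log(ratioThreshold)) "undifferentiated"
  else if (x > y) "lineage_1" else "lineage_2"
}

#' Locate stable fixed points by root-finding
#'
#' Damped Newton iteration with a finite-difference Jacobian from a set of
#' multistart points (corners, axis states and the diagonal), de-duplicated
#' and filtered for stability by the eigenvalues of the Jacobian.
#' Serves as the independent cross-check of the trajectory endpoints.
#'
#' @param model \code{"huang"} or \code{"chickarmane"}.
#' @param params model parameter list.
#' @param phi transcription-rate multiplier.
#' @param starts optional matrix of start states.
#' @param tol root tolerance on the max-norm of the right-hand side.
#' @return matrix of stable fixed points (possibly zero rows).
#' @export
findFixedPoints <- function(model = c("huang", "chickarmane"),
                            params = NULL, phi = 1, starts = NULL,
                            tol = 1e-10) {
  model <- match.arg(model)
  if (is.null(params))
    params <- if (model == "huang") huangParams() else chickarmaneParams()
  d <- fateDim(model)
  f <- fateRhsFun(model, params, phi)
  scale <- phi * (params$a + params$b + max(c(0, params$sP)))
  if (is.null(starts)) {
    g <- c(0.01, 0.3, 1, 2) * scale
    starts <- as.matrix(expand.grid(rep(list(g), d)))
  }
  jac <- function(s) {
    h <- 1e-6 * pmax(abs(s), 1)
    J <- matrix(0, d, d)
    f0 <- f(s)
    for (j in seq_len(d)) {
      sp <- s; sp[j] <- sp[j] + h[j]
      J[, j] <- (f(sp) - f0) / h[j]
    }
    J
  }
  roots <- list()
  for (r in seq_len(nrow(starts))) {
    s <- pmax(as.numeric(starts[r, ]), 0)
    ok <- FALSE
    for (it in 1:100) {
      fv <- f(s)
      if (max(abs(fv)) < tol) { ok <- TRUE; break }
      step <- tryCatch(solve(jac(s), -fv), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        s2 <- pmax(s + lambda * step, 0)
        if (max(abs(f(s2))) < max(abs(fv)) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      s <- pmax(s + lambda * step, 0)
    }
    if (ok && all(Re(eigen(jac(s), only.values = TRUE)$values) < 1e-6))
      roots[[length(roots) + 1]] <- s
  }
  if (!length(roots)) return(matrix(numeric(), 0, d))
  R <- do.call(rbind, roots)
  keep <- !duplicated(round(R, 5))
  unique(R[keep, , drop = FALSE])
}

#' Basin-of-attraction map
#'
#' Integrates every point of a regular grid of initial conditions to
#' convergence (adaptive embedded Runge-Kutta, stopping when the
#' right-hand side's max norm falls below \code{rhsTol} or \eqn{t >
#' t_{max}}) and labels each endpoint with [classifyAttractor()]. The
#' bounding box defaults to 1.5 times the largest stable fixed-point
#' coordinate at the given \code{phi}. The map is deterministic: identical
#' grid, parameters and tolerances give identical labels.
#'
#' @param model \code{"huang"} or \code{"chickarmane"}.
#' @param params model parameter list (defaults per model).
#' @param phi transcription-rate multiplier.
#' @param gridN grid points per axis (101 for the two-gene model, 21 for
#'   the three-species model by default).
#' @param box upper corner of the grid box; default from the fixed points.
#' @param tMax integration horizon.
#' @param rhsTol convergence threshold on the right-hand side.
#' @param ratioThreshold classification threshold, see
#'   [classifyAttractor()].
#' @return a [BasinMap-class].
#' @export
basinMap <- function(model = c("huang", "chickarmane"), params = NULL,
                     phi = 1, gridN = NULL, box = NULL, tMax = 1000,
                     rhsTol = 1e-8, ratioThreshold = 3) {
  model <- match.arg(model)
  if (is.null(params))
    params <- if (model == "huang") huangParams() else chickarmaneParams()
  d <- fateDim(model)
  if (is.null(gridN)) gridN <- if (model == "huang") 101L else 21L
  fp <- findFixedPoints(model, params, phi)
  if (is.null(box)) {
    if (!nrow(fp)) stop("no stable fixed points located; supply a box")
    # box from the lineage-regulator coordinates (the plotted plane)
    box <- 1.5 * max(fp[, 1:2])
  } else if (nrow(fp) && max(fp[, 1:2]) > box) {
    warning("stable fixed points lie outside the grid box")
  }
  g <- seq(0, box, length.out = gridN)
  inits <- as.matrix(expand.grid(rep(list(g), d)))
  res <- .fateEndpoints(if (model == "huang") 0L else 1L, phi,
                        fateParsVector(model, params), inits, tMax, rhsTol,
                        1e-9)
  labels <- vapply(seq_len(nrow(inits)), function(i)
    classifyAttractor(res$endpoints[i, ], res$converged[i], ratioThreshold),
    "")
  lv <- c("undifferentiated", "lineage_1", "lineage_2", "unresolved")
  fr <- table(factor(labels, levels = lv)) / length(labels)
  grid <- data.frame(inits, label = labels)
  names(grid)[seq_len(d)] <- c("x", "y", "z")[seq_len(d)]
  new("BasinMap", model = model, phi = phi, grid = grid,
      fractions = setNames(as.numeric(fr), lv),
      fixedPoints = fp, box = box)
}

#' Stability of the undifferentiated state under transcription-rate scans
#'
#' For each combination of the transcription multiplier \code{phi} and the
#' PU.1-promoting signal \code{sP} (three-species model only), computes the
#' basin fractions and whether an undifferentiated attractor exists. For
#' the three-species model the derived quantity of interest is the range
#' of \code{sP} supporting a stable undifferentiated state, which shrinks
#' as \code{phi} grows.
#'
#' @param model \code{"huang"} or \code{"chickarmane"}.
#' @param phiValues transcription multipliers to scan.
#' @param signalValues \code{sP} values (ignored for the two-gene model).
#' @param params baseline parameters.
#' @param gridN grid resolution per axis.
#' @param ... passed to [basinMap()].
#' @return data frame with one row per (phi, signal) combination.
#' @export
transcriptionStabilityScan <- function(model = c("huang", "chickarmane"),
                                       phiValues = c(1, 2, 4),
                                       signalValues = NULL, params = NULL,
                                       gridN = NULL, ...) {
  model <- match.arg(model)
  if (is.null(params))
    params <- if (model == "huang") huangParams() else chickarmaneParams()
  if (model == "huang" || is.null(signalValues))
    signalValues <- if (model == "huang") NA else params$sP
  rows <- list()
  for (phi in phiValues) for (sv in signalValues) {
    p <- params
    if (model == "chickarmane" && !is.na(sv)) p$sP <- sv
    bm <- tryCatch(basinMap(model, p, phi, gridN = gridN, ...),
                   error = function(e) NULL)
    fr <- if (is.null(bm))
      c(undifferentiated = NA, lineage_1 = NA, lineage_2 = NA,
        unresolved = NA) else bm@fractions
    rows[[length(rows) + 1]] <- data.frame(
      phi = phi, signal = sv,
      undifferentiated = fr[["undifferentiated"]],
      lineage1 = fr[["lineage_1"]], lineage2 = fr[["lineage_2"]],
      unresolved = fr[["unresolved"]],
      undiffStable = isTRUE(fr[["undifferentiated"]] > 0))
  }
  do.call(rbind, rows)
}
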