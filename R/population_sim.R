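# Event-driven population engine.
#
# Cells are stored in parallel vectors (birth V, birth M, f, birth time) and
# the population advances division by division: the cell with the earliest
# division time divides, its two daughters are placed, and bookkeeping for
# completed cycles and sister pairs is updated. Growth between events is the
# closed-form solution, so no time stepping is needed.

popEngine <- function(params, nCells, nDivisions, burnIn,
                      protocol = c("fixed", "exponential"),
                      snapshotTimes = NULL, fixedPhase = NA_real_) {
  protocol <- match.arg(protocol)
  rho <- params@beta / params@alpha
  cap <- if (protocol == "exponential") nDivisions + 1L else nCells
  V0 <- M0 <- ff <- tb <- td <- bCL <- pCL <- rep(NA_real_, cap)
  id <- pid <- sid <- rep(NA_integer_, cap)
  # founders: spread over the cycle to avoid synchronisation artefacts
  nInit <- if (protocol == "exponential") 1L else nCells
  V0[1:nInit] <- runif(nInit, params@VDiv / 2, params@VDiv * 0.95)
  M0[1:nInit] <- pmax(1, round(rho * V0[1:nInit] / params@vMito))
  ff[1:nInit] <- sampleFunctionality(rep(1, nInit), params)
  tb[1:nInit] <- 0
  id[1:nInit] <- seq_len(nInit)
  td[1:nInit] <- timeToDivisionVec(V0[1:nInit], M0[1:nInit], ff[1:nInit],
                                   params)
  nAlive <- nInit
  nextId <- nInit + 1L
  cyc <- matrix(NA_real_, nDivisions, 10)
  colnames(cyc) <- c("cellId", "parentId", "sisterId", "birthTime", "birthV",
                     "birthM", "f", "cycleLength", "parentCycleLength",
                     "completedAt")
  snaps <- list(); snapIdx <- 1L
  for (ev in seq_len(nDivisions)) {
    i <- which.min(td[seq_len(nAlive)])
    tnow <- td[i]
    # snapshots strictly before this event time
    if (!is.null(snapshotTimes)) {
      while (snapIdx <= length(snapshotTimes) && snapshotTimes[snapIdx] <= tnow) {
        ts <- snapshotTimes[snapIdx]
        idx <- which(tb[seq_len(nAlive)] <= ts)
        dt <- ts - tb[idx]
        m0 <- M0[idx] * params@vMito
        m <- m0 * exp(params@beta * params@c * ff[idx] * dt)
        V <- V0[idx] + (params@alpha / params@beta) * (m - m0)
        atp <- params@c * ff[idx] * m / V
        snaps[[length(snaps) + 1L]] <- data.frame(
          time = ts, cellId = id[idx], V = V, M = m / params@vMito,
          f = ff[idx], atp = atp,
          transcriptionRate = transcriptionRate(atp, params),
          age = dt, cyclePhase = dt / (td[idx] - tb[idx]),
          birthV = V0[idx], birthM = M0[idx],
          cycleLength = td[idx] - tb[idx])
        snapIdx <- snapIdx + 1L
      }
    }
    L <- tnow - tb[i]
    cyc[ev, ] <- c(id[i], pid[i], sid[i], tb[i], V0[i], M0[i], ff[i], L,
                   pCL[i], tnow)
    # mass at division consistent with the volume increment
    Mdiv <- round(M0[i] + (params@beta / params@alpha) *
                    (params@VDiv - V0[i]) / params@vMito)
    q <- min(params@qClip[2], max(params@qClip[1],
                                  rnorm(1, 0.5, params@sigmaV)))
    Ma <- rbinom(1, Mdiv, 0.5)
    fNew <- sampleFunctionality(ff[i], params)
    ida <- nextId; idb <- nextId + 1L; nextId <- nextId + 2L
    place <- function(slot, Vb, Mb, myId, sisId) {
      V0[slot] <<- Vb; M0[slot] <<- Mb; ff[slot] <<- fNew; tb[slot] <<- tnow
      id[slot] <<- myId; pid[slot] <<- id0; sid[slot] <<- sisId
      pCL[slot] <<- L
      td[slot] <<- tnow + timeToDivisionVec(Vb, Mb, fNew, params)
    }
    id0 <- id[i]
    if (protocol == "fixed") {
      j <- sample.int(nAlive, 1L)           # random resident replaced
      place(i, q * params@VDiv, Ma, ida, if (j != i) idb else NA_integer_)
      if (j != i)
        place(j, (1 - q) * params@VDiv, Mdiv - Ma, idb, ida)
    } else {
      place(i, q * params@VDiv, Ma, ida, idb)
      nAlive <- nAlive + 1L
      place(nAlive, (1 - q) * params@VDiv, Mdiv - Ma, idb, ida)
      if (nAlive >= cap) break
    }
  }
  cyc <- as.data.frame(cyc[!is.na(cyc[, "cellId"]), , drop = FALSE])
  cyc$sisterComplete <- cyc$sisterId %in% cyc$cellId
  cyc <- cyc[cyc$birthTime >= burnIn, , drop = FALSE]
  snapshots <- if (length(snaps)) do.call(rbind, snaps) else
    data.frame(time = numeric(), cellId = numeric(), V = numeric(),
               M = numeric(), f = numeric(), atp = numeric(),
               transcriptionRate = numeric(), age = numeric(),
               cyclePhase = numeric(), birthV = numeric(),
               birthM = numeric(), cycleLength = numeric())
  state <- list(V0 = V0[seq_len(nAlive)], M0 = M0[seq_len(nAlive)],
                f = ff[seq_len(nAlive)], tb = tb[seq_len(nAlive)],
                td = td[seq_len(nAlive)])
  list(cycles = cyc, snapshots = snapshots, state = state, nAlive = nAlive)
}

#' Simulate a fixed-size cell population
#'
#' Constant-size population under the replacement protocol: whenever a cell
#' reaches the division volume it divides, one daughter takes the parent's
#' slot and the other replaces a uniformly chosen resident cell. Completed
#' cycles and time-stamped snapshots are collected after a burn-in period;
#' sister pairs are flagged complete only when both sisters finished an
#' entire cycle without being replaced.
#'
#' @param nCells population size (>= 2).
#' @param params a [MitoParams-class].
#' @param nDivisions total division events to simulate. The default gives
#'   roughly 20 generations of a 500-cell population.
#' @param burnInCycles burn-in, in units of the nominal mean cycle length;
#'   events and snapshots before it are discarded.
#' @param nSnapshots number of evenly spaced population snapshots collected
#'   after burn-in.
#' @return a [PopulationRecord-class].
#' @examples
#' set.seed(1)
#' rec <- simulateFixedPopulation(nCells = 100, nDivisions = 2000)
#' stageResolvedNoise(rec)
#' @export
simulateFixedPopulation <- function(nCells = 500, params = mitoParams(),
                                    nDivisions = 20L * nCells,
                                    burnInCycles = 10, nSnapshots = 12) {
  if (nCells < 2) stop("need at least two cells")
  nominal <- nominalCycleLength(params)
  burnIn <- burnInCycles * nominal
  # conservative horizon: selection makes realised cycles ~10% shorter than
  # the reference cell's, so snapshot times must not overshoot the last event
  horizon <- 0.85 * nominal * nDivisions / nCells
  if (horizon <= burnIn + nominal)
    stop("nDivisions too small for the requested burn-in: increase nDivisions")
  snapshotTimes <- seq(burnIn, horizon, length.out = nSnapshots)
  eng <- popEngine(params, nCells, nDivisions, burnIn, "fixed", snapshotTimes)
  new("PopulationRecord", snapshots = eng$snapshots, cycles = eng$cycles,
      protocol = "fixed_size_replacement", params = params,
      nCells = nCells, burnIn = burnIn)
}

#' Simulate an exponentially growing population
#'
#' Grows a lineage tree from a single founder with no cell removal until
#' the population reaches \code{nMax} cells. All cells are retained, so the
#' record contains the full tree.
#'
#' @param nMax population size at which growth stops (>= 2).
#' @param params a [MitoParams-class].
#' @param burnInCycles completed cycles born before this many nominal cycle
#'   lengths are excluded from \code{cycles} (the founder generations).
#' @param snapshotAtEnd collect one snapshot of all living cells at the
#'   time the population reaches \code{nMax}.
#' @return a [PopulationRecord-class].
#' @export
simulateExponential <- function(nMax = 1024, params = mitoParams(),
                                burnInCycles = 0, snapshotAtEnd = TRUE) {
  if (nMax < 2) stop("need nMax >= 2")
  nominal <- nominalCycleLength(params)
  burnIn <- burnInCycles * nominal
  eng <- popEngine(params, nMax, nMax - 1L, burnIn, "exponential")
  snapshots <- eng$snapshots
  if (snapshotAtEnd && eng$nAlive >= 2) {
    st <- eng$state
    ts <- max(st$tb)
    dt <- pmax(0, ts - st$tb)
    m0 <- st$M0 * params@vMito
    m <- m0 * exp(params@beta * params@c * st$f * dt)
    V <- st$V0 + (params@alpha / params@beta) * (m - m0)
    atp <- params@c * st$f * m / V
    snapshots <- data.frame(
      time = ts, cellId = seq_along(V), V = V, M = m / params@vMito,
      f = st$f, atp = atp,
      transcriptionRate = transcriptionRate(atp, params),
      age = dt, cyclePhase = dt / (st$td - st$tb),
      birthV = st$V0, birthM = st$M0, cycleLength = st$td - st$tb)
  }
  new("PopulationRecord", snapshots = snapshots, cycles = eng$cycles,
      protocol = "exponential_growth", params = params,
      nCells = eng$nAlive, burnIn = burnIn)
}

# cycle length of the deterministic reference cell (birth at VDiv/2,
# density beta/alpha, f at its stationary mean)
nominalCycleLength <- function(params) {
  timeToDivision(referenceBirthState(params), params)
}

#' Coefficient of variation (noise)
#'
#' The population noise measure: standard deviation divided by mean
#' (population standard deviation, i.e. normalised by n, so that
#' \code{noiseEta(c(1, 3))} is exactly 0.5).
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return the dimensionless noise eta.
#' @export
noiseEta <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("noise is undefined for zero mean")
  sqrt(mean((values - m)^2)) / m
}

#' Assign a cell-cycle stage from cell volume
#'
#' Stages are assigned by volume thresholds chosen so that, along the
#' stationary growth trajectory (pure exponential volume growth from
#' V_div/2 to V_div), the expected fraction of cycle time spent in each
#' stage equals \code{params@stageFractions}: the G1/S boundary sits at
#' \eqn{2^{g_1} V_{div}/2} and the S/G2 boundary at
#' \eqn{2^{g_1+g_S} V_{div}/2}.
#'
#' @param V cell volume(s), within the growth range
#'   (\code{[qClip[1] * VDiv, VDiv]}).
#' @param params a [MitoParams-class].
#' @return factor with levels G1, S, G2.
#' @export
assignCycleStage <- function(V, params = mitoParams()) {
  if (any(V < params@qClip[1] * params@VDiv - 1e-9) ||
      any(V > params@VDiv * (1 + 1e-9)))
    stop("volume outside the growth range")
  cum <- cumsum(params@stageFractions)
  thr <- params@VDiv / 2 * 2^cum[1:2]
  cut(V, breaks = c(0, thr, params@VDiv * (1 + 1e-9)),
      labels = c("G1", "S", "G2"))
}

#' Transcription-rate noise by cell-cycle stage
#'
#' Computes the noise (std/mean) of the transcription rate within each
#' volume-assigned stage subset of the pooled snapshots, and over the whole
#' population.
#'
#' @param record a [PopulationRecord-class] with snapshots.
#' @param minCells minimum cells per stage; smaller subsets are flagged
#'   with a warning and returned as NA rather than silently dropped.
#' @return data frame with columns \code{grouping}, \code{eta}, \code{n}.
#' @export
stageResolvedNoise <- function(record, minCells = 100) {
  sn <- record@snapshots
  if (!nrow(sn)) stop("record contains no snapshots")
  stage <- assignCycleStage(pmin(sn$V, modelParams(record)@VDiv), modelParams(record))
  out <- lapply(levels(stage), function(sg) {
    x <- sn$transcriptionRate[stage == sg]
    if (length(x) < minCells) {
      warning("stage ", sg, " has fewer than ", minCells, " cells")
      data.frame(grouping = sg, eta = NA_real_, n = length(x))
    } else data.frame(grouping = sg, eta = noiseEta(x), n = length(x))
  })
  rbind(do.call(rbind, out),
        data.frame(grouping = "all", eta = noiseEta(sn$transcriptionRate),
                   n = nrow(sn)))
}

#' Birth-state correlations with cycle length
#'
#' Pearson correlations, over completed cycles, of (i) mitochondrial mass
#' at birth with the subsequent cycle length, (ii) cell volume at birth
#' with cycle length, and (iii) parent cycle length with daughter cycle
#' length. In this model, a daughter born with more mitochondria (or more
#' volume) completes its cycle sooner, so the raw correlations are
#' negative.
#'
#' @param record a [PopulationRecord-class].
#' @param minCycles required number of completed cycles.
#' @return named vector \code{c(rMassCycle, rVolumeCycle, rParentDaughter)}.
#' @export
birthCorrelations <- function(record, minCycles = 500) {
  cy <- record@cycles
  if (nrow(cy) < minCycles)
    stop("need at least ", minCycles, " completed cycles, have ", nrow(cy))
  pd <- cy[!is.na(cy$parentCycleLength), ]
  c(rMassCycle = cor(cy$birthM, cy$cycleLength),
    rVolumeCycle = cor(cy$birthV, cy$cycleLength),
    rParentDaughter = cor(pd$parentCycleLength, pd$cycleLength))
}

#' Sister-pair ratio correlations
#'
#' For sister pairs in which both cells completed a full cycle, correlates
#' the ratio of birth mitochondrial masses (and, separately, of birth
#' volumes) between the sisters with the ratio of their cycle lengths.
#' Because sisters share the same functionality, these ratio statistics
#' isolate the effect of partitioning noise and are the quantities
#' measured in sister-pair segregation experiments.
#'
#' Two conventions are returned: the larger/smaller convention of the
#' experimental scatter plots (pairs ordered so the mass -- or volume --
#' ratio is >= 1, cycle-length ratio taken in the same cell order;
#' \code{rMassRatio}, \code{rVolumeRatio}), and Pearson correlations of
#' the unordered log ratios (\code{rMassRatioLog},
#' \code{rVolumeRatioLog}). The sister with more mitochondria completes
#' its cycle sooner, so all of these are negative.
#'
#' @param record a [PopulationRecord-class].
#' @param minPairs required number of complete sister pairs.
#' @return named vector \code{c(rMassRatio, rVolumeRatio, rMassRatioLog,
#'   rVolumeRatioLog, nPairs)}.
#' @export
sisterRatioCorrelations <- function(record, minPairs = 200) {
  cy <- record@cycles
  cy <- cy[cy$sisterComplete & !is.na(cy$sisterId), ]
  cy <- cy[cy$sisterId %in% cy$cellId, ]
  first <- cy[cy$cellId < cy$sisterId, ]
  other <- cy[match(first$sisterId, cy$cellId), ]
  keep <- first$birthM > 0 & other$birthM > 0
  first <- first[keep, ]; other <- other[keep, ]
  if (nrow(first) < minPairs)
    stop("need at least ", minPairs, " complete sister pairs, have ",
         nrow(first))
  orderedRatio <- function(xa, xb, La, Lb) {
    big <- xa >= xb
    xr <- ifelse(big, xa / xb, xb / xa)
    Lr <- ifelse(big, La / Lb, Lb / La)
    cor(xr, Lr)
  }
  c(rMassRatio = orderedRatio(first$birthM, other$birthM,
                              first$cycleLength, other$cycleLength),
    rVolumeRatio = orderedRatio(first$birthV, other$birthV,
                                first$cycleLength, other$cycleLength),
    rMassRatioLog = cor(log(first$birthM / other$birthM),
                        log(first$cycleLength / other$cycleLength)),
    rVolumeRatioLog = cor(log(first$birthV / other$birthV),
                          log(first$cycleLength / other$cycleLength)),
    nPairs = nrow(first))
}

#' Cycle-length and noise response to oxidant treatment
#'
#' Re-runs the fixed-population simulation with the AR(1) mean-setting
#' term at its anti-oxidant (0.69), control (0.5) and pro-oxidant (0.09)
#' values, using the same seed for each treatment (common random numbers),
#' and tabulates mean and standard deviation of the cycle length and the
#' transcription-rate noise. Anti-oxidants raise mean functionality, which
#' raises ATP and growth rate, shortening cycles and reducing noise;
#' pro-oxidants do the opposite.
#'
#' @param params baseline [MitoParams-class] (its \code{betaF} is ignored).
#' @param betaF named treatment values of the mean-setting term.
#' @param nCells,nDivisions population size and length of each simulation.
#' @param seed seed applied before each treatment run.
#' @return data frame with one row per treatment.
#' @export
oxidantScan <- function(params = mitoParams(),
                        betaF = c(antioxidant = 0.69, control = 0.5,
                                  prooxidant = 0.09),
                        nCells = 300, nDivisions = 6000, seed = 1) {
  rows <- lapply(names(betaF), function(tr) {
    p <- mitoParamsFrom(params, betaF = betaF[[tr]])
    set.seed(seed)
    rec <- simulateFixedPopulation(nCells = nCells, params = p,
                                   nDivisions = nDivisions)
    cy <- rec@cycles
    data.frame(treatment = tr, betaF = betaF[[tr]],
               meanCycleLength = mean(cy$cycleLength),
               sdCycleLength = sd(cy$cycleLength),
               etaTranscription = noiseEta(rec@snapshots$transcriptionRate),
               meanF = mean(rec@snapshots$f))
  })
  do.call(rbind, rows)
}

# rebuild a MitoParams with some slots replaced
mitoParamsFrom <- function(params, ...) {
  repl <- list(...)
  for (nm in names(repl)) slot(params, nm) <- repl[[nm]]
  validObject(params)
  params
}

#' Transcription-rate noise surface over inheritance-noise scales
#'
#' Maps the population transcription-rate noise eta as a function of the
#' functionality innovation scale sigma_f and the mitochondrial
#' mass-partitioning scale sigma_M. sigma_M is realised physically by
#' changing the volume of the virtual mitochondrion at fixed total
#' mitochondrial mass (sigma_M = sqrt(v n)/2 per unit volume), so larger
#' sigma_M means fewer, larger mitochondrial units. Each grid point is
#' simulated with the same seed (common random numbers).
#'
#' @param sigmaFGrid,sigmaMGrid grid values; sigma_M in units of
#'   mitochondrial volume at mitosis (\eqn{\mu m^3}).
#' @param params baseline [MitoParams-class].
#' @param freezeVolumeNoise if TRUE, daughter volumes split exactly in half.
#' @param synchroniseSampling if TRUE, eta is computed over completed
#'   cycles sampled at a fixed cycle phase instead of over asynchronous
#'   snapshots, removing cell-cycle stage as a noise source.
#' @param phase cycle phase used when \code{synchroniseSampling}.
#' @param nCells,nDivisions simulation size per grid point.
#' @param seed common seed.
#' @return matrix of eta values (rows: sigmaFGrid, cols: sigmaMGrid).
#' @export
noiseSurface <- function(sigmaFGrid, sigmaMGrid, params = mitoParams(),
                         freezeVolumeNoise = FALSE,
                         synchroniseSampling = FALSE, phase = 0.5,
                         nCells = 200, nDivisions = 4000, seed = 1) {
  mTot <- densityTarget(params) * params@VDiv   # mito volume at mitosis
  out <- matrix(NA_real_, length(sigmaFGrid), length(sigmaMGrid),
                dimnames = list(paste0("sigmaF=", sigmaFGrid),
                                paste0("sigmaM=", sigmaMGrid)))
  for (a in seq_along(sigmaFGrid)) for (b in seq_along(sigmaMGrid)) {
    v <- 4 * sigmaMGrid[b]^2 / mTot            # invert sigma_M = sqrt(v n)/2
    if (mTot / v > 1e8)
      stop("sigmaM grid value implies more than 1e8 virtual mitochondria")
    p <- mitoParamsFrom(params,
                        sigmaF = max(sigmaFGrid[a], 1e-12),
                        vMito = v,
                        sigmaV = if (freezeVolumeNoise) 1e-12 else
                          params@sigmaV)
    if (freezeVolumeNoise) p@qClip <- c(0.5 - 1e-9, 0.5 + 1e-9)
    set.seed(seed)
    rec <- simulateFixedPopulation(nCells = nCells, params = p,
                                   nDivisions = nDivisions)
    out[a, b] <- if (synchroniseSampling)
      noiseEta(phaseTranscriptionRates(rec, phase)) else
      noiseEta(rec@snapshots$transcriptionRate)
  }
  out
}

# transcription rates of the snapshot population, with every resident cell
# evaluated at the same fixed phase of its own cycle (rather than at its
# sampled age), removing cell-cycle position as a source of variability
# without changing the population sampling measure
phaseTranscriptionRates <- function(record, phase = 0.5) {
  sn <- record@snapshots
  p <- modelParams(record)
  m0 <- sn$birthM * p@vMito
  m <- m0 * exp(p@beta * p@c * sn$f * phase * sn$cycleLength)
  V <- sn$birthV + (p@alpha / p@beta) * (m - m0)
  transcriptionRate(p@c * sn$f * m / V, p)
}

#' Calibration scaffold: fit parameters to summary-statistic targets
#'
#' Minimises the weighted squared relative deviation of simulated summary
#' statistics from target values by derivative-free Nelder-Mead search
#' with common random numbers (the same seed for every evaluation).
#' Available summaries: \code{meanCycleLength}, \code{sdCycleLength},
#' \code{etaTranscription}, \code{meanAtp}, \code{etaCycleLength}.
#'
#' @param targets named numeric vector of target summary values.
#' @param freeParams character vector of MitoParams slot names to fit.
#' @param params starting [MitoParams-class].
#' @param lower,upper named bounds on the free parameters (search is in
#'   log space inside the bounds).
#' @param weights optional named weights, default equal.
#' @param nCells,nDivisions simulation size per evaluation.
#' @param seed common-random-number seed.
#' @param maxit Nelder-Mead iteration cap.
#' @return list with \code{params} (fitted), \code{loss}, \code{summaries}.
#' @export
calibrateModel <- function(targets, freeParams, params = mitoParams(),
                           lower = NULL, upper = NULL, weights = NULL,
                           nCells = 150, nDivisions = 2500, seed = 1,
                           maxit = 60) {
  summarise <- function(p) {
    set.seed(seed)
    rec <- simulateFixedPopulation(nCells = nCells, params = p,
                                   nDivisions = nDivisions, nSnapshots = 6)
    cy <- rec@cycles
    c(meanCycleLength = mean(cy$cycleLength),
      sdCycleLength = sd(cy$cycleLength),
      etaCycleLength = sd(cy$cycleLength) / mean(cy$cycleLength),
      etaTranscription = noiseEta(rec@snapshots$transcriptionRate),
      meanAtp = mean(rec@snapshots$atp))
  }
  unknown <- setdiff(names(targets),
                     c("meanCycleLength", "sdCycleLength", "etaCycleLength",
                       "etaTranscription", "meanAtp"))
  if (length(unknown))
    stop("uncomputable target(s): ", paste(unknown, collapse = ", "))
  if (is.null(weights)) weights <- setNames(rep(1, length(targets)),
                                            names(targets))
  if (!length(freeParams)) {
    s <- summarise(params)
    loss <- sum(weights * ((s[names(targets)] - targets) / targets)^2)
    return(list(params = params, loss = loss, summaries = s))
  }
  if (length(targets) < length(freeParams))
    warning("fewer targets than free parameters; fit may not be identifiable")
  start <- log(vapply(freeParams, function(nm) slot(params, nm), 0))
  build <- function(theta) {
    p <- params
    for (k in seq_along(freeParams)) {
      v <- exp(theta[k])
      if (!is.null(lower)) v <- max(v, lower[[freeParams[k]]])
      if (!is.null(upper)) v <- min(v, upper[[freeParams[k]]])
      slot(p, freeParams[k]) <- v
    }
    validObject(p)
    p
  }
  fn <- function(theta) {
    s <- summarise(build(theta))
    sum(weights * ((s[names(targets)] - targets) / targets)^2)
  }
  opt <- if (length(freeParams) == 1L)
    stats::optim(start, fn, method = "Brent",
                 lower = start - log(4), upper = start + log(4)) else
    stats::optim(start, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit))
  best <- build(opt$par)
  list(params = best, loss = opt$value, summaries = summarise(best))
}
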