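# Independent numerical oracles used to check closed-form implementations.

# fixed-step RK4 integration of the raw growth ODEs
#   dV/dt = alpha * A * V, dm/dt = beta * A * V,  A = c f m / V
rk4Growth <- function(V, m, f, dt, params, nSteps = 4000) {
  h <- dt / nSteps
  rhs <- function(s) {
    A <- params@c * f * s[2] / s[1]
    c(params@alpha * A * s[1], params@beta * A * s[1])
  }
  s <- c(V, m)
  for (i in seq_len(nSteps)) {
    k1 <- rhs(s); k2 <- rhs(s + h / 2 * k1)
    k3 <- rhs(s + h / 2 * k2); k4 <- rhs(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(V = s[1], m = s[2])
}

# bisection on the RK4 trajectory for the division time
bisectDivisionTime <- function(state, params, tol = 1e-8) {
  m0 <- state@M * params@vMito
  fV <- function(t) rk4Growth(state@V, m0, state@f, t, params)$V - params@VDiv
  lo <- 0; hi <- 2 * timeToDivision(state, params) + 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fV(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ordered larger/smaller sister-ratio correlations, recomputed directly
# from the cycle table (independent of sisterRatioCorrelations internals)
orderedSisterCors <- function(record) {
  cy <- cycleRecords(record)
  cy <- cy[cy$sisterComplete & !is.na(cy$sisterId), ]
  cy <- cy[cy$sisterId %in% cy$cellId, ]
  a <- cy[cy$cellId < cy$sisterId, ]
  b <- cy[match(a$sisterId, cy$cellId), ]
  keep <- a$birthM > 0 & b$birthM > 0
  a <- a[keep, ]; b <- b[keep, ]
  ord <- function(xa, xb, La, Lb) {
    big <- xa >= xb
    cor(ifelse(big, xa / xb, xb / xa),
        ifelse(big, La / Lb, Lb / La))
  }
  c(mass = ord(a$birthM, b$birthM, a$cycleLength, b$cycleLength),
    volume = ord(a$birthV, b$birthV, a$cycleLength, b$cycleLength))
}

# cluster-bootstrap standard error of the transcription-rate eta of a
# population record (resampling whole cells, since snapshot rows of one
# cell are strongly correlated)
etaClusterSE <- function(record, nBoot = 200) {
  sn <- snapshotRecords(record)
  ids <- unique(sn$cellId)
  rows <- split(seq_len(nrow(sn)), sn$cellId)
  reps <- replicate(nBoot, {
    pick <- sample(length(ids), replace = TRUE)
    noiseEta(sn$transcriptionRate[unlist(rows[pick], use.names = FALSE)])
  })
  sd(reps)
}

# a small stationary population shared by several expression tests
sharedPopulation <- local({
  rec <- NULL
  function() {
    if (is.null(rec)) {
      set.seed(424242)
      rec <<- simulateFixedPopulation(nCells = 250, nDivisions = 5000)
    }
    rec
  }
})
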