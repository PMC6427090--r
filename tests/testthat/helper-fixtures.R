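# Independent brute-force oracles and small fixtures, built in code.

# exhaustive double loop over (m, l): the definition of the lagged
# co-activation count, with out-of-range terms skipped
oracleCoactivationCount <- function(bi, bj, lo, hi) {
  m <- length(bi)
  total <- 0L
  for (mm in seq_len(m)) {
    for (l in lo:hi) {
      if (mm + l <= m && bi[[mm]] == 1L && bj[[mm + l]] == 1L)
        total <- total + 1L
    }
  }
  total
}

# exhaustive triple loop over every tensor cell
oracleCoactivationTensor <- function(states, ivMatrix) {
  n <- ncol(states)
  nt <- nrow(ivMatrix)
  out <- array(0L, c(n, n, nt))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (t in seq_len(nt)) {
        out[i, j, t] <- oracleCoactivationCount(states[, i], states[, j],
                                                ivMatrix[t, 1L], ivMatrix[t, 2L])
      }
    }
  }
  out
}

# small deterministic RoiTimeSeries
makeTs <- function(values, id = "toy") {
  RoiTimeSeries(as.matrix(values), subjectID = id)
}

# SyntheticSpec for a small, fast cohort (couplings fit in 10 regions)
smallSpec <- function(seed = 1L, nPatients = 8L, nControls = 8L,
                      nRegions = 10L, nTimepoints = 80L,
                      couplings = defaultCouplings(), ...) {
  SyntheticSpec(nPatients = nPatients, nControls = nControls,
                nRegions = nRegions, nTimepoints = nTimepoints,
                couplings = couplings, seed = seed, ...)
}

# identical generative parameters for both groups: couplings shared
nullSpec <- function(seed = 1L, ...) {
  cp <- defaultCouplings()
  cp$group <- "both"
  smallSpec(seed = seed, couplings = cp, ...)
}
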