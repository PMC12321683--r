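# shared fixtures, built in code

# a small cohort configuration; scheme = name of a single forced b-value scheme
tinyCohortConfig <- function(nPatients = 6L, nCenters = 2L, nBoth = 4L,
                             nDiagOnly = 2L, nRespOnly = 0L, nMuscle = 2L,
                             noiseSigma = 0.02, scheme = NULL,
                             missingProb = 0) {
  cfg <- defaultCohortConfig()
  cfg$nPatients <- as.integer(nPatients)
  cfg$nCenters <- as.integer(nCenters)
  cfg$nBoth <- as.integer(nBoth)
  cfg$nDiagOnly <- as.integer(nDiagOnly)
  cfg$nRespOnly <- as.integer(nRespOnly)
  cfg$nMusclePatients <- as.integer(nMuscle)
  cfg$noiseSigma <- noiseSigma
  cfg$missingProb <- missingProb
  if (!is.null(scheme)) {
    w <- cfg$acquisition$schemeWeights
    w[] <- 0; w[scheme] <- 1
    cfg$acquisition$schemeWeights <- w
  }
  cfg
}

# hand-built scan with known tissue states (bypasses the cohort machinery)
makeScan <- function(tumorState, bv = c(0, 100, 500, 1000),
                     necState = NULL, muscleState = NULL,
                     g = c(24L, 24L, 6L), s0 = 100, sigma = 0, seed = 1) {
  tumor <- adcvar:::ellipsoidMask(g, c(11, 11, 2.5), c(6, 6, 1.5))
  excl <- if (!is.null(necState))
    adcvar:::ellipsoidMask(g, c(11, 11, 2.5), c(2.5, 2.5, 0.8)) & tumor
  else array(FALSE, dim = g)
  muscle <- array(FALSE, dim = g)
  if (!is.null(muscleState)) muscle[2:4, 18:21, 2:3] <- TRUE
  set.seed(seed)
  vols <- lapply(bv, function(b) {
    v <- array(0, dim = g)
    v[tumor] <- ivimSignal(b, tumorState, s0)
    if (!is.null(necState)) v[excl] <- ivimSignal(b, necState, s0)
    if (!is.null(muscleState)) v[muscle] <- ivimSignal(b, muscleState, s0)
    addRicianNoise(v, sigma * s0)
  })
  gt <- list(tumor = tumorState)
  if (!is.null(necState)) gt$necrotic <- necState
  if (!is.null(muscleState)) gt$muscle <- muscleState
  new("SyntheticScan", scanId = "T001", patientId = "P001", centerId = "C01",
      timepoint = "diagnosis", bvalues = as.numeric(bv), volumes = vols,
      tumorMask = tumor, exclusionMask = excl, muscleMask = muscle,
      acquisition = list(), qualityScore = 2L, hasDWI = TRUE, inFov = TRUE,
      hasMeasurableTumor = TRUE, groundTruth = gt)
}

# an ADCMap directly from a voxel vector (for ROI-summary unit tests)
mapFromValues <- function(values, g = c(length(values), 1L, 1L)) {
  adc <- array(values, dim = g)
  new("ADCMap", adc = adc, bvalues = c(0, 1000),
      invalid = array(is.na(adc), dim = g), scanId = "M001")
}

maskFromIndices <- function(idx, g) {
  m <- array(FALSE, dim = g)
  m[idx] <- TRUE
  m
}

# brute-force Mann-Whitney U by pair counting (independent oracle)
bruteForceU <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}
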