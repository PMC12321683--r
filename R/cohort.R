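# Synthetic multicenter DWI cohort generator.
#
# The generator emulates the statistical structure of a multicenter pediatric
# sarcoma DWI cohort: 114 patients in 22 centers, 195 scans (81 patients with
# both a diagnosis and a response scan, 31 diagnosis-only, 2 response-only),
# per-center acquisition-parameter distributions whose pooled coefficients of
# variation match the reported multicenter values, tumor/muscle ADC marginals
# matching the reported means/SDs, and a bi-exponential signal model that
# makes the fitted ADC depend on the highest b-value used.

# predefined b-value schemes (s/mm2); every scheme contains b = 0
.bvalueSchemes <- list(
  b2_1000 = c(0, 1000),
  b2_800  = c(0, 800),
  b3a_1000 = c(0, 100, 1000),
  b3b_1000 = c(0, 500, 1000),
  b3_800  = c(0, 500, 800),
  b6_1000 = c(0, 100, 200, 500, 800, 1000),
  b7_1000 = c(0, 50, 100, 200, 500, 800, 1000),
  b7_800  = c(0, 50, 100, 200, 400, 600, 800)
)

# global scheme weights, derived in closed form from the categorical moments
# so that CV(number of b-values) = 0.55 and CV(highest b-value) = 0.09:
# P(highest = 800) = 0.242 and P(n = 2/3/6/7) = 0.49/0.28/0.10/0.13
.defaultSchemeWeights <- c(
  b2_1000 = 0.368, b2_800 = 0.122,
  b3a_1000 = 0.110, b3b_1000 = 0.100, b3_800 = 0.070,
  b6_1000 = 0.100, b7_1000 = 0.080, b7_800 = 0.050
)

#' Predefined b-value schemes
#'
#' @return Named list of b-value vectors (s/mm2) the generator draws from;
#'   each contains the non-weighted image b = 0.
#' @export
listBValueSchemes <- function() .bvalueSchemes

#' Default synthetic-cohort configuration
#'
#' The defaults encode the study conditions the package is calibrated to:
#' cohort shape (114 patients / 22 centers / 195 scans; 16-patient muscle
#' subset), tumor and muscle ADC marginals (diagnosis 1.09 (0.30), response
#' 1.58 (0.38); muscle 1.20 (0.14) and 1.24 (0.16) um^2/ms), two-level
#' acquisition-parameter distributions reproducing the pooled CVs (echo time
#' 0.18, pixel spacing 0.31, slice thickness 0.22, number of b-values 0.55,
#' highest b-value 0.09), a 5-10% missing-metadata rate, and the
#' bi-exponential tissue mechanism (tumor perfusion fraction 0.065,
#' pseudo-diffusion 20 um^2/ms) behind the highest-b-value dependence of ADC.
#'
#' @return Nested named list; see the package vignette for every knob.
#' @export
defaultCohortConfig <- function() {
  list(
    seed = 42L,
    nPatients = 114L, nCenters = 22L,
    nBoth = 81L, nDiagOnly = 31L, nRespOnly = 2L,
    nMusclePatients = 16L,
    tumor = list(meanDiag = 1.09, sdDiag = 0.30,
                 meanResp = 1.58, sdResp = 0.38, rho = 0.5,
                 bounds = c(0.3, 2.8), f = 0.065, dPseudo = 20),
    muscle = list(meanDiag = 1.20, sdDiag = 0.14,
                  meanResp = 1.24, sdResp = 0.16, rho = 0.5,
                  bounds = c(0.3, 2.8), f = 0, dPseudo = 20),
    necrotic = list(targetADC = 2.5, f = 0, dPseudo = 20, presenceProb = 0.6),
    referenceB = 1000,
    acquisition = list(
      te = list(mean = 75, cvAll = 0.18, cvWithin = 0.13, floor = 5),
      pixelSpacing = list(mean = 1.4, cvAll = 0.31, cvWithin = 0.22, floor = 0.2),
      sliceThickness = list(mean = 5, cvAll = 0.22, cvWithin = 0.14, floor = 0.5),
      schemeWeights = .defaultSchemeWeights,
      schemeConcentration = 1.5
    ),
    missingProb = 0.075,
    exclusionRates = list(noTumor = 0, poorQuality = 0, noDWI = 0,
                          outsideFOV = 0),
    noiseSigma = 0.02,
    s0 = 100,
    grid = c(32L, 32L, 8L),
    geometry = list(tumorSemiXY = c(5, 9), tumorSemiZ = c(1.2, 2.2),
                    necroticScale = 0.45)
  )
}

#' Validate a cohort configuration
#'
#' Checks structural consistency (unknown keys rejected, patient counts add
#' up, weights over known schemes summing to 1, rates and bounds sane).
#'
#' @param config a configuration list as from \code{\link{defaultCohortConfig}}.
#' @return The config, invisibly, or an error.
#' @export
validateCohortConfig <- function(config) {
  ref <- defaultCohortConfig()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(ref), names(config))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "))
  with(config, {
    if (nBoth + nDiagOnly + nRespOnly != nPatients)
      stop("nBoth + nDiagOnly + nRespOnly must equal nPatients")
    if (nCenters > nPatients)
      stop("nCenters must not exceed nPatients")
    if (nCenters < 1 || nPatients < 1)
      stop("nCenters and nPatients must be at least 1")
    if (nMusclePatients > nPatients)
      stop("nMusclePatients must not exceed nPatients")
  })
  w <- config$acquisition$schemeWeights
  if (length(w) == 0 || is.null(names(w)) ||
      !all(names(w) %in% names(.bvalueSchemes)))
    stop("schemeWeights must be named after known b-value schemes")
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
    stop("schemeWeights must be non-negative and sum to 1")
  for (p in c("te", "pixelSpacing", "sliceThickness")) {
    a <- config$acquisition[[p]]
    if (a$cvWithin > a$cvAll)
      stop(p, ": cvWithin must not exceed cvAll (two-level decomposition)")
  }
  if (any(unlist(config$exclusionRates) < 0) ||
      any(unlist(config$exclusionRates) > 1))
    stop("exclusionRates must be probabilities")
  if (config$missingProb < 0 || config$missingProb > 1)
    stop("missingProb must be a probability")
  if (config$noiseSigma < 0) stop("noiseSigma must be non-negative")
  if (length(config$grid) != 3L || any(config$grid < c(24, 24, 6)))
    stop("grid must be three dimensions of at least 24 x 24 x 6 voxels")
  invisible(config)
}

# between-center SD from the two-level CV decomposition
.betweenSD <- function(a) sqrt((a$cvAll * a$mean)^2 - (a$cvWithin * a$mean)^2)

#' Sample center acquisition profiles
#'
#' Builds one profile per center: center means for echo time, pixel spacing
#' and slice thickness, and a per-center categorical weight vector over the
#' b-value schemes. Center means are placed at scaled normal quantiles of the
#' between-center distribution (so the between-center sample variance matches
#' the two-level decomposition exactly) and assigned to centers by random
#' permutation; scheme weights are Dirichlet draws centred on the global
#' weights, with a concentration parameter controlling within-center
#' protocol homogeneity. Uses the current RNG state.
#'
#' @param config a cohort configuration.
#' @param scanCounts optional integer vector of scans per center; when given,
#'   the center-mean deviations are standardized under scan weighting, so the
#'   pooled (scan-level) between-center variance matches the two-level
#'   decomposition exactly rather than only on average.
#' @return A list with a data.frame \code{centers} (center_id and the three
#'   parameter means) and a matrix \code{schemeWeights} (centers x schemes).
#' @export
sampleCenterProfiles <- function(config, scanCounts = NULL) {
  nC <- config$nCenters
  acq <- config$acquisition
  cnt <- if (is.null(scanCounts)) rep(1, nC) else as.numeric(scanCounts)
  stopifnot(length(cnt) == nC)
  strat <- function(a) {
    if (nC == 1L) return(a$mean)
    z <- stats::qnorm((seq_len(nC) - 0.5) / nC)[sample.int(nC)]
    w <- cnt / sum(cnt)
    z <- z - sum(w * z)
    z <- z / sqrt(sum(cnt * z^2) / (sum(cnt) - 1))
    pmax(a$mean + .betweenSD(a) * z, a$floor)
  }
  centers <- data.frame(
    center_id = sprintf("C%02d", seq_len(nC)),
    te_mean = strat(acq$te),
    pixel_spacing_mean = strat(acq$pixelSpacing),
    slice_thickness_mean = strat(acq$sliceThickness),
    stringsAsFactors = FALSE
  )
  w <- acq$schemeWeights
  conc <- acq$schemeConcentration
  sw <- t(vapply(seq_len(nC), function(i) {
    g <- stats::rgamma(length(w), shape = conc * w + 1e-9)
    g / sum(g)
  }, numeric(length(w))))
  dimnames(sw) <- list(centers$center_id, names(w))
  list(centers = centers, schemeWeights = sw)
}

#' Sample acquisition parameters for scans of one center
#'
#' Draws echo time, pixel spacing and slice thickness from the center's
#' within-center (truncated) normal distributions and a b-value scheme from
#' the center's categorical weights. Uses the current RNG state.
#'
#' @param profile one-row slice of the \code{centers} data.frame from
#'   \code{\link{sampleCenterProfiles}}.
#' @param schemeWeights named numeric weights over the schemes for this center.
#' @param n number of scans to draw.
#' @param acq the \code{acquisition} block of the cohort configuration.
#' @return data.frame with te_ms, pixel_spacing_mm, slice_thickness_mm,
#'   scheme, n_bvalues, highest_bvalue.
#' @export
sampleAcquisitionParameters <- function(profile, schemeWeights, n = 1,
                                        acq = defaultCohortConfig()$acquisition) {
  draw <- function(centerMean, a)
    rtruncNorm(n, centerMean, a$cvWithin * a$mean, lower = a$floor)
  scheme <- sample(names(schemeWeights), n, replace = TRUE,
                   prob = schemeWeights)
  data.frame(
    te_ms = draw(profile$te_mean, acq$te),
    pixel_spacing_mm = draw(profile$pixel_spacing_mean, acq$pixelSpacing),
    slice_thickness_mm = draw(profile$slice_thickness_mean, acq$sliceThickness),
    scheme = scheme,
    n_bvalues = vapply(scheme, function(s) length(.bvalueSchemes[[s]]), 0),
    highest_bvalue = vapply(scheme, function(s) max(.bvalueSchemes[[s]]), 0),
    stringsAsFactors = FALSE
  )
}

# correlated truncated bivariate normal pairs (rejection on the box)
.rBivariate <- function(n, mean1, sd1, mean2, sd2, rho, bounds) {
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    z1 <- stats::rnorm(length(todo))
    z2 <- stats::rnorm(length(todo))
    xi <- mean1 + sd1 * z1
    yi <- mean2 + sd2 * (rho * z1 + sqrt(1 - rho^2) * z2)
    ok <- xi > bounds[1] & xi < bounds[2] & yi > bounds[1] & yi < bounds[2]
    x[todo[ok]] <- xi[ok]; y[todo[ok]] <- yi[ok]
    todo <- todo[!ok]
  }
  cbind(x, y)
}

# cohort-level scheme allocation: total counts fixed by largest-remainder
# rounding of the global weights, distributed to scans with probability
# proportional to (center weight) x (remaining pool)
.allocateSchemes <- function(centerIdx, schemeW, globalW) {
  n <- length(centerIdx)
  pool <- largestRemainderCounts(n, globalW[colnames(schemeW)])
  names(pool) <- colnames(schemeW)
  out <- character(n)
  for (i in sample.int(n)) {
    p <- schemeW[centerIdx[i], ] * pool
    if (sum(p) <= 0) p <- pool
    out[i] <- sample(names(pool), 1, prob = p)
    pool[out[i]] <- pool[out[i]] - 1L
  }
  out
}

# per-scan volume synthesis under the scan's own RNG stream
.buildScanVolumes <- function(bvalues, states, hasMuscle, config) {
  g <- config$grid
  geo <- config$geometry
  # geometry relative to the grid centre; semi-axes capped so the tumor fits
  cx <- stats::runif(1, g[1] / 2 - 2, g[1] / 2 + 1)
  cy <- stats::runif(1, g[2] / 2 - 2, g[2] / 2 + 1)
  cz <- stats::runif(1, g[3] / 2 - 0.8, g[3] / 2 + 0.3)
  hiXY <- min(geo$tumorSemiXY[2], min(g[1], g[2]) / 2 - 4)
  semi <- c(stats::runif(2, min(geo$tumorSemiXY[1], hiXY), hiXY),
            stats::runif(1, geo$tumorSemiZ[1], geo$tumorSemiZ[2]))
  tumor <- ellipsoidMask(g, c(cx, cy, cz), semi)
  necrotic <- if (stats::runif(1) < config$necrotic$presenceProb)
    ellipsoidMask(g, c(cx, cy, cz), semi * geo$necroticScale) & tumor
  else emptyMask(g)
  muscle <- emptyMask(g)
  if (hasMuscle) {
    zc <- max(1L, min(g[3] - 1L, as.integer(round(cz)) + 1L))
    muscle[4:7, (g[2] - 11):(g[2] - 4), zc:(zc + 1L)] <- TRUE
    muscle <- muscle & !tumor  # a muscle ROI never overlaps the tumor ROI
  }
  s0 <- config$s0
  sigma <- config$noiseSigma * s0
  vols <- lapply(bvalues, function(b) {
    v <- array(0, dim = g)
    v[tumor] <- ivimSignal(b, states$tumor, s0)
    if (any(necrotic)) v[necrotic] <- ivimSignal(b, states$necrotic, s0)
    if (any(muscle)) v[muscle] <- ivimSignal(b, states$muscle, s0)
    addRicianNoise(v, sigma)
  })
  list(volumes = vols, tumor = tumor, necrotic = necrotic, muscle = muscle)
}

#' Generate a synthetic multicenter DWI cohort
#'
#' Draws center profiles, patients with correlated diagnosis/response tumor
#' ADC (and muscle ADC for a subset), per-scan acquisition parameters and --
#' optionally -- multi-b signal volumes with Rician noise and tumor /
#' necrotic-exclusion / muscle masks. Deterministic for a fixed seed and
#' config; per-scan volume streams are derived by stable hashing of the scan
#' id, so the manifest is identical whether or not volumes are generated.
#'
#' @param config cohort configuration (see \code{\link{defaultCohortConfig}}).
#' @param seed integer master seed; defaults to \code{config$seed}.
#' @param volumes logical; generate voxel volumes and masks (TRUE) or a
#'   manifest-only cohort (FALSE, much faster, for statistical simulations).
#' @return A list with \code{manifest} (one row per scan: identifiers,
#'   timepoint, acquisition parameters -- with configured metadata
#'   missingness --, quality and inclusion flags), \code{scans} (named list of
#'   \code{SyntheticScan}), \code{patients} (ground-truth per-patient ADC
#'   table), \code{profiles} (center profiles) and the resolved \code{config}.
#' @examples
#' cfg <- defaultCohortConfig()
#' cfg$nPatients <- 6L; cfg$nCenters <- 2L
#' cfg$nBoth <- 4L; cfg$nDiagOnly <- 2L; cfg$nRespOnly <- 0L
#' cfg$nMusclePatients <- 2L
#' coh <- generateCohort(cfg, seed = 1, volumes = FALSE)
#' head(coh$manifest)
#' @export
generateCohort <- function(config = defaultCohortConfig(),
                           seed = config$seed, volumes = TRUE) {
  validateCohortConfig(config)
  config$seed <- as.integer(seed)
  set.seed(config$seed)

  nC <- config$nCenters; nP <- config$nPatients

  # patients: center assignment (every center gets at least one patient)
  sizeW <- stats::rgamma(nC, shape = 2); sizeW <- sizeW / sum(sizeW)
  centerOfPatient <- c(seq_len(nC),
                       sample.int(nC, nP - nC, replace = TRUE, prob = sizeW))
  centerOfPatient <- centerOfPatient[sample.int(nP)]

  pattern <- sample(rep(c("both", "diag", "resp"),
                        times = c(config$nBoth, config$nDiagOnly,
                                  config$nRespOnly)))
  scansPerPatient <- ifelse(pattern == "both", 2L, 1L)
  scanCounts <- vapply(seq_len(nC), function(cc)
    sum(scansPerPatient[centerOfPatient == cc]), 0L)
  profiles <- sampleCenterProfiles(config, scanCounts)
  tum <- config$tumor
  adc <- .rBivariate(nP, tum$meanDiag, tum$sdDiag, tum$meanResp, tum$sdResp,
                     tum$rho, tum$bounds)
  bothIdx <- which(pattern == "both")
  musclePool <- if (length(bothIdx) >= config$nMusclePatients) bothIdx
                else seq_len(nP)
  muscleIdx <- sort(sample(musclePool, config$nMusclePatients))
  mus <- config$muscle
  madc <- matrix(NA_real_, nP, 2)
  if (config$nMusclePatients > 0)
    madc[muscleIdx, ] <- .rBivariate(length(muscleIdx), mus$meanDiag,
                                     mus$sdDiag, mus$meanResp, mus$sdResp,
                                     mus$rho, mus$bounds)

  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(nP)),
    center_id = profiles$centers$center_id[centerOfPatient],
    pattern = pattern,
    adc_diag_true = adc[, 1], adc_resp_true = adc[, 2],
    muscle_adc_diag_true = madc[, 1], muscle_adc_resp_true = madc[, 2],
    has_muscle = seq_len(nP) %in% muscleIdx,
    stringsAsFactors = FALSE
  )
  patients$adc_diag_true[pattern == "resp"] <- NA_real_
  patients$adc_resp_true[pattern == "diag"] <- NA_real_

  # scan skeleton
  rows <- do.call(rbind, lapply(seq_len(nP), function(i) {
    tps <- switch(patients$pattern[i], both = c("diagnosis", "response"),
                  diag = "diagnosis", resp = "response")
    data.frame(patient = i, timepoint = tps, stringsAsFactors = FALSE)
  }))
  nS <- nrow(rows)
  rows$scan_id <- sprintf("S%03d", seq_len(nS))
  rows$center <- centerOfPatient[rows$patient]

  # acquisition parameters: continuous per center, schemes pool-allocated
  acqDf <- data.frame(te_ms = numeric(nS), pixel_spacing_mm = numeric(nS),
                      slice_thickness_mm = numeric(nS),
                      scheme = character(nS), n_bvalues = numeric(nS),
                      highest_bvalue = numeric(nS), stringsAsFactors = FALSE)
  for (cc in sort(unique(rows$center))) {
    idx <- which(rows$center == cc)
    acqDf[idx, ] <- sampleAcquisitionParameters(
      profiles$centers[cc, ], profiles$schemeWeights[cc, ],
      length(idx), config$acquisition)
  }
  acqDf$scheme <- .allocateSchemes(rows$center, profiles$schemeWeights,
                                   config$acquisition$schemeWeights)
  acqDf$n_bvalues <- vapply(acqDf$scheme,
                            function(s) length(.bvalueSchemes[[s]]), 0)
  acqDf$highest_bvalue <- vapply(acqDf$scheme,
                                 function(s) max(.bvalueSchemes[[s]]), 0)

  quality <- sample(2:3, nS, replace = TRUE)
  hasTumorFlag <- rep(TRUE, nS); hasDWI <- rep(TRUE, nS); inFov <- rep(TRUE, nS)
  er <- config$exclusionRates
  if (er$noTumor > 0) hasTumorFlag <- stats::runif(nS) >= er$noTumor
  if (er$poorQuality > 0)
    quality[stats::runif(nS) < er$poorQuality] <- 1L
  if (er$noDWI > 0) hasDWI <- stats::runif(nS) >= er$noDWI
  if (er$outsideFOV > 0) inFov <- stats::runif(nS) >= er$outsideFOV

  # ground-truth tissue states
  necState <- tissueState(config$necrotic$f,
                          solveTissueD(config$necrotic$targetADC,
                                       config$necrotic$f,
                                       config$necrotic$dPseudo,
                                       config$referenceB)@dTissue,
                          config$necrotic$dPseudo, config$necrotic$targetADC)
  scanStates <- lapply(seq_len(nS), function(i) {
    p <- rows$patient[i]
    tp <- rows$timepoint[i]
    tTarget <- if (tp == "diagnosis") patients$adc_diag_true[p]
               else patients$adc_resp_true[p]
    st <- list(tumor = solveTissueD(tTarget, tum$f, tum$dPseudo,
                                    config$referenceB),
               necrotic = necState)
    if (patients$has_muscle[p]) {
      mTarget <- if (tp == "diagnosis") patients$muscle_adc_diag_true[p]
                 else patients$muscle_adc_resp_true[p]
      st$muscle <- solveTissueD(mTarget, mus$f, mus$dPseudo, config$referenceB)
    }
    st
  })

  manifest <- data.frame(
    scan_id = rows$scan_id,
    patient_id = patients$patient_id[rows$patient],
    center_id = profiles$centers$center_id[rows$center],
    timepoint = rows$timepoint,
    te_ms = acqDf$te_ms,
    pixel_spacing_mm = acqDf$pixel_spacing_mm,
    slice_thickness_mm = acqDf$slice_thickness_mm,
    n_bvalues = acqDf$n_bvalues,
    highest_bvalue = acqDf$highest_bvalue,
    bvalues = vapply(acqDf$scheme, function(s)
      paste(.bvalueSchemes[[s]], collapse = ";"), ""),
    quality_score = quality,
    has_dwi = hasDWI,
    has_measurable_tumor = hasTumorFlag,
    in_fov = inFov,
    paths = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(manifest) <- NULL

  # metadata missingness (manifest-level only; scans keep their true values)
  if (config$missingProb > 0) {
    for (col in c("te_ms", "pixel_spacing_mm", "slice_thickness_mm",
                  "n_bvalues", "highest_bvalue"))
      manifest[[col]][stats::runif(nS) < config$missingProb] <- NA
  }

  scans <- vector("list", nS)
  names(scans) <- rows$scan_id
  for (i in seq_len(nS)) {
    bv <- .bvalueSchemes[[acqDf$scheme[i]]]
    st <- scanStates[[i]]
    if (volumes && hasDWI[i]) {
      set.seed(scanSeed(config$seed, rows$scan_id[i]))
      built <- .buildScanVolumes(bv, st, patients$has_muscle[rows$patient[i]],
                                 config)
      vols <- built$volumes; tm <- built$tumor; em <- built$necrotic
      mm <- built$muscle
    } else {
      vols <- list(); tm <- emptyMask(c(1L, 1L, 1L))
      em <- tm; mm <- tm
    }
    scans[[i]] <- new("SyntheticScan",
      scanId = rows$scan_id[i],
      patientId = patients$patient_id[rows$patient[i]],
      centerId = profiles$centers$center_id[rows$center[i]],
      timepoint = rows$timepoint[i],
      bvalues = bv, volumes = vols,
      tumorMask = tm, exclusionMask = em, muscleMask = mm,
      acquisition = as.list(acqDf[i, ]),
      qualityScore = as.integer(quality[i]),
      hasDWI = hasDWI[i], inFov = inFov[i],
      hasMeasurableTumor = hasTumorFlag[i],
      groundTruth = st)
  }

  list(manifest = manifest, scans = scans, patients = patients,
       profiles = profiles, config = config)
}
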