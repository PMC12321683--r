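# synthetic cohort generator: determinism, invariants, calibration

test_that("identical seeds and config produce identical cohorts", {
  cfg <- tinyCohortConfig(nPatients = 3L, nCenters = 1L, nBoth = 2L,
                          nDiagOnly = 1L, nMuscle = 1L)
  a <- generateCohort(cfg, seed = 9)
  b <- generateCohort(cfg, seed = 9)
  expect_identical(a$manifest, b$manifest)
  expect_identical(dwiVolumes(a$scans[[1]]), dwiVolumes(b$scans[[1]]))
  c3 <- generateCohort(cfg, seed = 10)
  expect_false(identical(a$manifest$te_ms, c3$manifest$te_ms))
  # manifest does not depend on whether volumes are generated
  d <- generateCohort(cfg, seed = 9, volumes = FALSE)
  expect_identical(a$manifest, d$manifest)
})

test_that("generated scans satisfy the structural invariants", {
  cfg <- tinyCohortConfig(nPatients = 5L, nCenters = 2L, nBoth = 3L,
                          nDiagOnly = 2L, nMuscle = 2L)
  coh <- generateCohort(cfg, seed = 2)
  expect_equal(nrow(coh$manifest), 3L * 2L + 2L)
  for (s in coh$scans) {
    b <- bValues(s)
    expect_identical(b[1], 0)
    expect_true(all(diff(b) > 0))
    expect_true(all(!(exclusionMask(s) & !tumorMask(s))))
    expect_false(any(muscleMask(s) & tumorMask(s)))
    expect_true(all(vapply(dwiVolumes(s), function(v) all(v >= 0),
                           logical(1))))
    expect_length(dwiVolumes(s), length(b))
    expect_true(s@qualityScore %in% 1:3)
  }
  # true per-patient ADC values live in the physiologic band
  tr <- coh$patients
  expect_true(all(tr$adc_diag_true > 0.2 & tr$adc_diag_true < 3,
                  na.rm = TRUE))
  expect_true(all(tr$adc_resp_true > 0.2 & tr$adc_resp_true < 3,
                  na.rm = TRUE))
})

test_that("inconsistent configurations are rejected", {
  cfg <- tinyCohortConfig()
  cfg$nBoth <- 5L
  expect_error(generateCohort(cfg), "must equal nPatients")
  cfg <- tinyCohortConfig(); cfg$nCenters <- 99L
  expect_error(generateCohort(cfg), "exceed nPatients")
  cfg <- tinyCohortConfig(); cfg$unknownKnob <- 1
  expect_error(generateCohort(cfg), "unknown config keys")
  cfg <- tinyCohortConfig()
  cfg$acquisition$schemeWeights <- c(b2_1000 = 0.7, b2_800 = 0.7)
  expect_error(generateCohort(cfg), "sum to 1")
  cfg <- tinyCohortConfig(); cfg$grid <- c(8L, 8L, 4L)
  expect_error(generateCohort(cfg), "grid")
})

test_that("noise-free scans return each patient's true ADC at {0, bRef}", {
  cfg <- tinyCohortConfig(nPatients = 4L, nCenters = 1L, nBoth = 0L,
                          nDiagOnly = 4L, nMuscle = 0L, noiseSigma = 0,
                          scheme = "b7_1000")
  coh <- generateCohort(cfg, seed = 21)
  for (i in seq_len(nrow(coh$manifest))) {
    scan <- coh$scans[[coh$manifest$scan_id[i]]]
    truth <- coh$patients$adc_diag_true[coh$patients$patient_id ==
                                          scan@patientId]
    vox <- which(tumorMask(scan) & !exclusionMask(scan))[1]
    s0 <- dwiVolumes(scan)[[1]][vox]
    s1 <- dwiVolumes(scan)[[which(bValues(scan) == 1000)]][vox]
    expect_equal(log(s0 / s1) / 1000 * 1e3, truth, tolerance = 1e-6)
  }
})

test_that("per-scan degenerate center profiles give identical parameters", {
  acq <- defaultCohortConfig()$acquisition
  acq$te$cvWithin <- 0; acq$pixelSpacing$cvWithin <- 0
  acq$sliceThickness$cvWithin <- 0
  prof <- data.frame(te_mean = 80, pixel_spacing_mean = 1.2,
                     slice_thickness_mean = 5)
  set.seed(1)
  draws <- sampleAcquisitionParameters(prof, c(b2_1000 = 1), n = 8,
                                       acq = acq)
  expect_equal(draws$te_ms, rep(80, 8))
  expect_equal(draws$pixel_spacing_mm, rep(1.2, 8))
  expect_equal(draws$slice_thickness_mm, rep(5, 8))
  expect_equal(unique(draws$scheme), "b2_1000")
})

test_that("patient ADC marginals converge to the configured distributions", {
  set.seed(77)
  tum <- defaultCohortConfig()$tumor
  x <- adcvar:::.rBivariate(10000, tum$meanDiag, tum$sdDiag, tum$meanResp,
                            tum$sdResp, tum$rho, tum$bounds)
  expect_lt(abs(mean(x[, 1]) - 1.09), 0.02)
  expect_lt(abs(sd(x[, 1]) - 0.30), 0.02)
  expect_lt(abs(mean(x[, 2]) - 1.58), 0.02)
  expect_lt(abs(sd(x[, 2]) - 0.38), 0.02)
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.5), 0.05)
})

test_that("two-level acquisition draws reproduce the pooled echo-time CV", {
  # 22 stratified center means, 455 scans each: pooled CV -> 0.18
  set.seed(42)
  cfg <- defaultCohortConfig()
  prof <- sampleCenterProfiles(cfg)
  draws <- unlist(lapply(seq_len(cfg$nCenters), function(i)
    sampleAcquisitionParameters(prof$centers[i, ],
                                prof$schemeWeights[i, ], 455,
                                cfg$acquisition)$te_ms))
  expect_equal(sd(draws) / mean(draws), 0.18, tolerance = 0.02)
})

test_that("scheme weights reproduce the categorical CV targets exactly", {
  w <- adcvar:::.defaultSchemeWeights
  sch <- listBValueSchemes()[names(w)]
  nb <- vapply(sch, length, 0)
  hb <- vapply(sch, max, 0)
  cvOf <- function(v) {
    m <- sum(w * v); sqrt(sum(w * (v - m)^2)) / m
  }
  expect_equal(cvOf(nb), 0.55, tolerance = 0.01)
  expect_equal(cvOf(hb), 0.09, tolerance = 0.005)
})

test_that("configured exclusion rates populate the inclusion flags", {
  cfg <- tinyCohortConfig(nPatients = 40L, nCenters = 2L, nBoth = 20L,
                          nDiagOnly = 20L, nMuscle = 0L)
  cfg$exclusionRates <- list(noTumor = 0.2, poorQuality = 0.15,
                             noDWI = 0.1, outsideFOV = 0.05)
  coh <- generateCohort(cfg, seed = 6, volumes = FALSE)
  m <- coh$manifest
  expect_gt(sum(!m$has_measurable_tumor), 0)
  expect_gt(sum(m$quality_score == 1), 0)
  expect_gt(sum(!m$has_dwi), 0)
  flow <- applyInclusionFlow(m)
  expect_lt(flow$report$n_included, nrow(m))
})

test_that("metadata missingness hits the manifest but not the scans", {
  cfg <- tinyCohortConfig(nPatients = 60L, nCenters = 3L, nBoth = 40L,
                          nDiagOnly = 20L, nMuscle = 0L, missingProb = 0.3)
  coh <- generateCohort(cfg, seed = 8, volumes = FALSE)
  expect_gt(sum(is.na(coh$manifest$te_ms)), 0)
  expect_gt(sum(is.na(coh$manifest$highest_bvalue)), 0)
  # scans keep full acquisition information
  expect_true(all(vapply(coh$scans, function(s)
    is.finite(s@acquisition$te_ms), logical(1))))
})
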