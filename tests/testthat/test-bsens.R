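# b-value combination analysis, highest-b grouping, slopes, longitudinal deltas

test_that("enumerateCombinations lists every subset containing b = 0", {
  expect_equal(enumerateCombinations(c(0, 1000)), list(c(0, 1000)))
  cmb <- enumerateCombinations(c(0, 100, 500, 1000))
  expect_length(cmb, 7L)  # 2^3 - 1
  key <- vapply(cmb, paste, "", collapse = ";")
  expect_setequal(key, c("0;100", "0;500", "0;1000", "0;100;500",
                         "0;100;1000", "0;500;1000", "0;100;500;1000"))
  expect_error(enumerateCombinations(c(0)), "two b-values")
  expect_error(enumerateCombinations(c(100, 200)), "b = 0")
})

test_that("combination counts follow the 2^m - 1 law with unique ascending members", {
  for (m in 1:8) {
    bv <- c(0, seq(100, by = 100, length.out = m))
    cmb <- enumerateCombinations(bv)
    expect_length(cmb, 2^m - 1)
    key <- vapply(cmb, paste, "", collapse = ";")
    expect_equal(anyDuplicated(key), 0L)
    expect_true(all(vapply(cmb, function(x)
      x[1] == 0 && all(diff(x) > 0), logical(1))))
  }
})

test_that("groupByHighestB averages within highest-b groups", {
  cb <- data.frame(highest_b = c(1000, 1000, 500),
                   median_adc = c(1.0, 1.2, 1.5))
  g <- groupByHighestB(cb)
  expect_equal(g$highest_b, c(500, 1000))
  expect_equal(g$mean_adc, c(1.5, 1.1))
  expect_true(is.na(g$se_adc[1]))                     # singleton group
  expect_equal(g$se_adc[2], sd(c(1, 1.2)) / sqrt(2))  # ~0.1
  expect_equal(sum(g$n_combinations), nrow(cb))       # groups partition
})

test_that("adcOverCombinations matches the map-level route and the count law", {
  ts <- tissueState(0.065, 1.1, 20)
  scan <- makeScan(ts, bv = c(0, 100, 500, 1000), sigma = 0)
  cb <- adcOverCombinations(scan)
  expect_equal(nrow(cb), length(enumerateCombinations(bValues(scan))))
  # one combination cross-checked against computeADCMap + roiMedianADC
  sub <- c(0, 100, 1000)
  viaMap <- roiMedianADC(computeADCMap(scan, sub), tumorMask(scan),
                         exclusionMask(scan))$median_adc
  expect_equal(cb$median_adc[cb$combination == "0;100;1000"], viaMap,
               tolerance = 1e-12)
})

test_that("noise-free scans show the null and the perfusion-driven trend", {
  # mono-exponential null: every combination gives the same ADC
  mono <- makeScan(tissueState(0, 1.2, 20),
                   bv = c(0, 50, 100, 200, 500, 800, 1000), sigma = 0)
  cbM <- adcOverCombinations(mono)
  expect_equal(max(cbM$median_adc) - min(cbM$median_adc), 0,
               tolerance = 1e-10)
  gM <- groupByHighestB(cbM)
  expect_equal(slopePer100(gM), 0, tolerance = 1e-8)
  # perfused tissue: group means strictly decreasing in highest b
  set.seed(23)
  for (i in 1:5) {
    ts <- tissueState(runif(1, 0.03, 0.15), runif(1, 0.6, 1.8),
                      runif(1, 10, 40))
    sig <- ivimSignal(c(0, 50, 100, 200, 500, 800, 1000), ts)
    cmb <- enumerateCombinations(c(0, 50, 100, 200, 500, 800, 1000))
    adc <- vapply(cmb, function(cb)
      fitADC(cb, sig[match(cb, c(0, 50, 100, 200, 500, 800, 1000))]), 0)
    g <- groupByHighestB(data.frame(highest_b = vapply(cmb, max, 0),
                                    median_adc = adc))
    expect_true(all(diff(g$mean_adc) < 0))
  }
})

test_that("slopePer100 matches the closed-form two-group log fit", {
  g <- data.frame(highest_b = c(200, 1000), mean_adc = c(1.614, 1.2054),
                  se_adc = NA, n_combinations = 1L)
  # ln-ratio over 8 steps of 100: 100 * (1 - (1.2054/1.614)^(1/8)) ~= 3.58
  expect_equal(slopePer100(g), 100 * (1 - (1.2054 / 1.614)^(1 / 8)),
               tolerance = 1e-10)
  expect_equal(slopePer100(g), 3.583, tolerance = 1e-3)
  expect_error(slopePer100(g[1, ]), "insufficient")
  expect_error(slopePer100(g, fitRange = c(900, 1000)), "insufficient")
  # relative-linear alternative is close for small slopes
  expect_equal(slopePer100(g, method = "relative"),
               (1.614 - 1.2054) / 8 / mean(c(1.614, 1.2054)) * 100,
               tolerance = 1e-10)
})

test_that("longitudinalFourCombinations reproduces hand arithmetic", {
  mkg <- function(h, s) data.frame(highest_b = c(800, 1000),
                                   mean_adc = c(s, h),
                                   se_adc = c(0.02, 0.02),
                                   n_combinations = c(8L, 16L))
  dl <- longitudinalFourCombinations(mkg(1.0, 1.1), mkg(1.5, 1.7))
  expect_equal(nrow(dl), 4L)
  key <- paste(dl$diag_choice, dl$resp_choice)
  expect_equal(dl$percent_change[key == "highest highest"], 50)
  expect_equal(dl$percent_change[key == "highest second_highest"], 70)
  expect_equal(dl$percent_change[key == "second_highest highest"],
               100 * 0.4 / 1.1, tolerance = 1e-9)  # 36.36
  expect_equal(dl$percent_change[key == "second_highest second_highest"],
               100 * 0.6 / 1.1, tolerance = 1e-9)  # 54.55
  expect_true(all(dl$se_percent > 0))
  # n_eff = mean of the two groups' combination counts, per pairing
  neff <- function(dc, rc) dl$n_eff[dl$diag_choice == dc & dl$resp_choice == rc]
  expect_equal(neff("highest", "highest"), 16)
  expect_equal(neff("highest", "second_highest"), 12)
  expect_equal(neff("second_highest", "second_highest"), 8)
  # equal group means at both timepoints: all four deltas are zero
  flat <- data.frame(highest_b = c(800, 1000), mean_adc = c(1.2, 1.2),
                     se_adc = c(0.01, 0.01), n_combinations = c(8L, 16L))
  expect_equal(longitudinalFourCombinations(flat, flat)$percent_change,
               rep(0, 4))
  # identical group tables: the matched-choice deltas are zero
  z <- longitudinalFourCombinations(mkg(1.0, 1.1), mkg(1.0, 1.1))
  expect_equal(z$percent_change[z$diag_choice == z$resp_choice], rep(0, 2))
  # swapping timepoints satisfies delta' = -100 * delta / (100 + delta)
  sw <- longitudinalFourCombinations(mkg(1.5, 1.7), mkg(1.0, 1.1))
  lookup <- function(d, dc, rc)
    d$percent_change[d$diag_choice == dc & d$resp_choice == rc]
  for (a in c("highest", "second_highest"))
    for (b in c("highest", "second_highest")) {
      fwd <- lookup(dl, a, b); bwd <- lookup(sw, b, a)
      expect_equal(bwd, -100 * fwd / (100 + fwd), tolerance = 1e-9)
    }
  expect_error(longitudinalFourCombinations(mkg(1, 1.1)[1, ], mkg(1.5, 1.7)),
               "insufficient")
})

test_that("welchTFromSummaries agrees with the raw-data Welch test", {
  same <- welchTFromSummaries(1, 0.1, 5, 1, 0.1, 5)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # closed form: t = -0.5 / sqrt(0.02) ~= -3.536, Welch df = 8
  r <- welchTFromSummaries(1.0, 0.1, 5, 1.5, 0.1, 5)
  expect_equal(r$t, -0.5 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(r$df, 8)
  sw <- welchTFromSummaries(1.5, 0.1, 5, 1.0, 0.1, 5)
  expect_equal(sw$t, -r$t); expect_equal(sw$p, r$p)
  # oracle: summaries computed from raw samples reproduce t.test
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1), 0.5)
    ref <- t.test(x, y)
    got <- welchTFromSummaries(mean(x), sd(x) / sqrt(length(x)), length(x),
                               mean(y), sd(y) / sqrt(length(y)), length(y))
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(welchTFromSummaries(1, 0, 5, 2, 0.1, 5), "positive")
  expect_error(welchTFromSummaries(1, 0.1, 1, 2, 0.1, 5), "at least 2")
})

test_that("cohort drivers tie the combination analysis together", {
  cfg <- tinyCohortConfig(nPatients = 2L, nCenters = 1L, nBoth = 2L,
                          nDiagOnly = 0L, nMuscle = 0L, noiseSigma = 0,
                          scheme = "b6_1000")
  coh <- generateCohort(cfg, seed = 14)
  bs <- bvalueSensitivity(coh$scans, coh$manifest)
  expect_equal(length(unique(bs$combinations$scan_id)), 4L)
  expect_equal(nrow(bs$slopes), 4L)
  expect_equal(bs$meanSlope, mean(bs$slopes$percent_per_100))
  lg <- longitudinalAnalysis(coh$scans, coh$manifest)
  expect_equal(nrow(lg$deltas), 4L * 2L)   # 4 deltas per eligible patient
  expect_equal(nrow(lg$tests), 6L * 2L)    # 6 pairwise tests per patient
  # ineligible cohorts return empty results
  cfg2 <- tinyCohortConfig(nPatients = 2L, nCenters = 1L, nBoth = 2L,
                           nDiagOnly = 0L, nMuscle = 0L, scheme = "b2_1000")
  coh2 <- generateCohort(cfg2, seed = 14)
  expect_true(is.na(bvalueSensitivity(coh2$scans, coh2$manifest)$meanSlope))
  expect_null(longitudinalAnalysis(coh2$scans, coh2$manifest)$deltas)
})
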