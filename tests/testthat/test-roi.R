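# ROI medians, the inclusion flow, cohort summary tables

test_that("roiMedianADC summarizes the effective mask", {
  g <- c(4L, 1L, 1L)
  map <- mapFromValues(c(1, 2, 3, 10), g)
  mask <- maskFromIndices(1:4, g)
  # single voxel
  one <- roiMedianADC(mapFromValues(1.37, c(1L, 1L, 1L)),
                      maskFromIndices(1, c(1L, 1L, 1L)))
  expect_equal(one$median_adc, 1.37)
  expect_equal(one$n_voxels, 1L)
  # exclusion removes the outlier; hand-enumerated median of {1,2,3} = 2
  excl <- maskFromIndices(4, g)
  res <- roiMedianADC(map, mask, excl)
  expect_equal(res$median_adc, 2)
  expect_equal(res$n_voxels, 3L)
  expect_equal(res$n_excluded_voxels, 1L)
  # even count: midpoint of the central values
  expect_equal(roiMedianADC(map, mask)$median_adc, 2.5)
  # permutation invariance
  perm <- mapFromValues(c(10, 3, 1, 2), g)
  expect_equal(roiMedianADC(perm, mask, maskFromIndices(1, g))$median_adc, 2)
})

test_that("roiMedianADC is robust to excluded and invalid voxels", {
  g <- c(5L, 1L, 1L)
  mask <- maskFromIndices(1:4, g)
  excl <- maskFromIndices(4, g)
  base <- roiMedianADC(mapFromValues(c(1, 2, 3, 5, 9), g), mask, excl)
  blown <- roiMedianADC(mapFromValues(c(1, 2, 3, 50, 9), g), mask, excl)
  expect_identical(base$median_adc, blown$median_adc)
  # invalid voxels drop out of the median
  withNA <- mapFromValues(c(1, 2, NA, 5, 9), g)
  expect_equal(roiMedianADC(withNA, mask, excl)$median_adc, 1.5)
  # empty effective mask errors
  expect_error(roiMedianADC(withNA, maskFromIndices(3, g)), "no evaluable")
  expect_error(roiMedianADC(withNA, mask, maskFromIndices(1:5, g)),
               "no evaluable")
})

test_that("inclusion flow excludes by fixed priority with unique reasons", {
  man <- data.frame(
    scan_id = sprintf("S%02d", 1:10),
    quality_score = c(2, 2, 1, 2, 3, 2, 2, 3, 2, 2),
    has_dwi = c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 6)),
    has_measurable_tumor = c(FALSE, FALSE, rep(TRUE, 8)),
    in_fov = rep(TRUE, 10))
  res <- applyInclusionFlow(man)
  expect_equal(res$report$n_included, 6L)
  expect_equal(unlist(res$report$n_excluded_by_reason),
               c(no_measurable_tumor = 2L, poor_quality = 1L, no_dwi = 1L,
                 outside_fov = 0L))
  # all-pass manifest comes back unchanged
  ok <- man; ok$quality_score <- 2; ok$has_dwi <- TRUE
  ok$has_measurable_tumor <- TRUE
  expect_identical(applyInclusionFlow(ok)$manifest, ok)
  # a scan that is both tumor-free and poor-quality counts once, as tumor-free
  both <- man; both$quality_score[1] <- 1
  r2 <- applyInclusionFlow(both)$report$n_excluded_by_reason
  expect_equal(r2$no_measurable_tumor, 2L)
  expect_equal(r2$poor_quality, 1L)
  # missing flags are a row-level validation error naming the scan
  bad <- man; bad$has_dwi[7] <- NA
  expect_error(applyInclusionFlow(bad), "S07")
})

test_that("inclusion counts are conserved for random flag patterns", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    man <- data.frame(
      scan_id = sprintf("S%03d", seq_len(n)),
      quality_score = sample(1:3, n, replace = TRUE),
      has_dwi = runif(n) > 0.2,
      has_measurable_tumor = runif(n) > 0.2,
      in_fov = runif(n) > 0.1)
    rep <- applyInclusionFlow(man)$report
    expect_equal(rep$n_included + sum(unlist(rep$n_excluded_by_reason)),
                 rep$n_input_scans)
  }
})

test_that("summarizeCohort reports mean/SD cells and leaves absent cells out", {
  sm <- data.frame(scan_id = c("a", "b"), patient_id = c("p1", "p2"),
                   center_id = "c", timepoint = "diagnosis",
                   region = "tumor", median_adc = c(1, 2),
                   n_voxels = 10L, n_excluded_voxels = 0L)
  tab <- summarizeCohort(sm)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mean_adc, 1.5)
  expect_equal(tab$sd_adc, sqrt(0.5), tolerance = 1e-12)  # 0.7071
  expect_false("muscle" %in% tab$region)
  # mean/SD agree with brute-force recomputation on random summaries
  set.seed(31)
  big <- data.frame(scan_id = sprintf("s%d", 1:60),
                    patient_id = sprintf("p%d", 1:60), center_id = "c",
                    timepoint = sample(c("diagnosis", "response"), 60, TRUE),
                    region = sample(c("tumor", "muscle"), 60, TRUE),
                    median_adc = runif(60, 0.5, 2.5),
                    n_voxels = 5L, n_excluded_voxels = 0L)
  tab2 <- summarizeCohort(big)
  for (i in seq_len(nrow(tab2))) {
    v <- big$median_adc[big$region == tab2$region[i] &
                          big$timepoint == tab2$timepoint[i]]
    expect_equal(tab2$mean_adc[i], sum(v) / length(v), tolerance = 1e-12)
    expect_equal(tab2$sd_adc[i],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("roiSummaries separates tumor and muscle regions per scan", {
  scan <- makeScan(tissueState(0, 1.4, 20),
                   muscleState = tissueState(0, 1.1, 20), sigma = 0)
  man <- data.frame(scan_id = "T001", patient_id = "P001",
                    center_id = "C01", timepoint = "diagnosis")
  sm <- roiSummaries(list(T001 = scan), man)
  expect_setequal(sm$region, c("tumor", "muscle"))
  expect_equal(sm$median_adc[sm$region == "tumor"], 1.4, tolerance = 1e-9)
  expect_equal(sm$median_adc[sm$region == "muscle"], 1.1, tolerance = 1e-9)
})
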