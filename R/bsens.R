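# B-value subset sensitivity: ADC over all b-value combinations containing
# b = 0, grouped by the highest b-value used; the percent-change-per-100
# slope; and the four-combination longitudinal-change analysis.

#' Enumerate all b-value combinations containing b = 0
#'
#' All subsets of a b-value set that contain the non-weighted image and at
#' least one nonzero b-value: 2^m - 1 combinations for m nonzero b-values,
#' each in canonical ascending order, in a deterministic enumeration order
#' (binary counting over the nonzero values).
#'
#' @param bvalues b-value set: strictly increasing, first element 0.
#' @return list of numeric vectors.
#' @examples
#' enumerateCombinations(c(0, 100, 1000))
#' @export
enumerateCombinations <- function(bvalues) {
  b <- .checkBValueSet(as.numeric(bvalues))
  nz <- b[b > 0]
  m <- length(nz)
  if (m == 0L) stop("at least one nonzero b-value is required")
  if (m > 16L) stop("too many b-values to enumerate (m > 16)")
  lapply(seq_len(2^m - 1), function(mask) {
    bits <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    c(0, nz[bits])
  })
}

#' ROI-median ADC for every b-value combination of a scan
#'
#' For each combination from \code{\link{enumerateCombinations}}, fits the
#' log-linear ADC on the ROI voxels (mask minus exclusion mask) and takes the
#' ROI median. Fitting is restricted to the masked voxels, which is
#' equivalent to fitting the full map and summarizing inside the mask.
#'
#' @param scan a \code{SyntheticScan} with volumes.
#' @param mask ROI mask; defaults to the scan's tumor mask.
#' @param excludeMask voxels removed before the median; defaults to the
#'   scan's exclusion mask.
#' @return data.frame with scan_id, combination (semicolon-joined b-values),
#'   n_bvalues, highest_b, median_adc, n_voxels.
#' @export
adcOverCombinations <- function(scan, mask = tumorMask(scan),
                                excludeMask = exclusionMask(scan)) {
  stopifnot(is(scan, "SyntheticScan"))
  if (!length(dwiVolumes(scan)))
    stop("scan ", scanId(scan), " has no DWI volumes")
  eff <- mask & !excludeMask
  if (!any(eff)) stop("empty ROI after exclusion")
  combos <- enumerateCombinations(bValues(scan))
  Y <- vapply(dwiVolumes(scan), function(v) v[eff], numeric(sum(eff)))
  out <- lapply(combos, function(cb) {
    idx <- match(cb, bValues(scan))
    fit <- .fitADCMatrix(cb, Y[, idx, drop = FALSE])
    ok <- !fit$invalid
    data.frame(scan_id = scanId(scan),
               combination = paste(cb, collapse = ";"),
               n_bvalues = length(cb), highest_b = max(cb),
               median_adc = if (any(ok)) stats::median(fit$adc[ok]) else NA_real_,
               n_voxels = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group combination ADCs by their highest b-value
#'
#' Arithmetic mean and standard error (sample SD / sqrt(n)) of the
#' combination ADCs sharing each distinct highest b-value, sorted ascending;
#' the SE is NA for singleton groups.
#'
#' @param comboADC data.frame from \code{\link{adcOverCombinations}} (columns
#'   highest_b and median_adc).
#' @return data.frame with highest_b, mean_adc, se_adc, n_combinations.
#' @export
groupByHighestB <- function(comboADC) {
  if (!nrow(comboADC)) stop("no combinations to group")
  sp <- split(comboADC$median_adc, comboADC$highest_b)
  out <- data.frame(
    highest_b = as.numeric(names(sp)),
    mean_adc = vapply(sp, mean, 0),
    se_adc = vapply(sp, function(v)
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    n_combinations = vapply(sp, length, 0L),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$highest_b), ]
  rownames(out) <- NULL
  out
}

#' Percent ADC decrease per 100 s/mm2 of highest b-value
#'
#' Fits the grouped mean ADC against the highest b-value over a fit range
#' and reports the percent decrease per 100 s/mm2. The default log-linear
#' convention fits OLS of ln(mean ADC) on highest_b and reports
#' 100 * (1 - exp(slope * 100)), so that "X percent per 100" compounds
#' consistently across the range; the simple relative-linear alternative
#' (OLS of ADC on highest_b, slope over the range-mean ADC) is also
#' available.
#'
#' @param groups data.frame from \code{\link{groupByHighestB}}.
#' @param fitRange numeric length-2: groups with highest_b inside
#'   [fitRange[1], fitRange[2]] enter the fit.
#' @param method "loglinear" (default) or "relative".
#' @return percent decrease per 100 s/mm2 (positive = ADC decreases as the
#'   highest b-value increases).
#' @export
slopePer100 <- function(groups, fitRange = c(200, 1000),
                        method = c("loglinear", "relative")) {
  method <- match.arg(method)
  sub <- groups[groups$highest_b >= fitRange[1] &
                  groups$highest_b <= fitRange[2], ]
  if (nrow(sub) < 2L)
    stop("insufficient data: fewer than 2 highest-b groups in the fit range")
  if (method == "loglinear") {
    fit <- stats::lm(log(mean_adc) ~ highest_b, data = sub)
    100 * (1 - exp(stats::coef(fit)[[2]] * 100))
  } else {
    fit <- stats::lm(mean_adc ~ highest_b, data = sub)
    -stats::coef(fit)[[2]] * 100 / mean(sub$mean_adc) * 100
  }
}

# the highest and second-highest b groups of one timepoint
.topTwoGroups <- function(groups) {
  if (nrow(groups) < 2L)
    stop("insufficient data: fewer than 2 distinct highest-b groups")
  g <- groups[order(groups$highest_b, decreasing = TRUE), ]
  list(highest = g[1, ], second_highest = g[2, ])
}

#' Longitudinal ADC change in four highest-b combinations
#'
#' Using either the highest or the second-highest b-value group at diagnosis
#' and at response gives four ways to compute the longitudinal percent
#' change 100 * (ADC_resp - ADC_diag) / ADC_diag. The SE of each percent
#' change is propagated from the two group SEs by the first-order delta
#' method, and n_eff is the mean of the two groups' combination counts.
#'
#' @param diagGroups,respGroups \code{\link{groupByHighestB}} tables for the
#'   diagnosis and response scans of one patient; each needs at least two
#'   distinct highest-b groups.
#' @return data.frame of exactly 4 rows: diag_choice, resp_choice,
#'   diag_highest_b, resp_highest_b, adc_diag, adc_resp, percent_change,
#'   se_percent, n_eff.
#' @export
longitudinalFourCombinations <- function(diagGroups, respGroups) {
  dg <- .topTwoGroups(diagGroups)
  rg <- .topTwoGroups(respGroups)
  choices <- expand.grid(diag_choice = c("highest", "second_highest"),
                         resp_choice = c("highest", "second_highest"),
                         stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(choices)), function(i) {
    d <- dg[[choices$diag_choice[i]]]
    r <- rg[[choices$resp_choice[i]]]
    ad <- d$mean_adc; ar <- r$mean_adc
    sed <- if (is.na(d$se_adc)) 0 else d$se_adc
    ser <- if (is.na(r$se_adc)) 0 else r$se_adc
    data.frame(
      diag_choice = choices$diag_choice[i],
      resp_choice = choices$resp_choice[i],
      diag_highest_b = d$highest_b, resp_highest_b = r$highest_b,
      adc_diag = ad, adc_resp = ar,
      percent_change = 100 * (ar - ad) / ad,
      se_percent = 100 * sqrt(ser^2 / ad^2 + ar^2 * sed^2 / ad^4),
      n_eff = mean(c(d$n_combinations, r$n_combinations)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Welch t-test from summary statistics
#'
#' t = (mean1 - mean2) / sqrt(se1^2 + se2^2) with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Equivalent to a raw-data
#' Welch test when the summaries (mean, SE = SD/sqrt(n), n) derive from the
#' same samples.
#'
#' @param mean1,se1,n1 summary of the first group (se1 > 0, n1 >= 2).
#' @param mean2,se2,n2 summary of the second group.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchTFromSummaries <- function(mean1, se1, n1, mean2, se2, n2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  if (n1 < 2 || n2 < 2) stop("both n must be at least 2")
  v <- se1^2 + se2^2
  t <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pairwise Welch tests among the four longitudinal deltas
#'
#' All 6 pairwise comparisons of the four percent-change estimates, using
#' each delta's propagated SE and effective n.
#'
#' @param deltas data.frame from \code{\link{longitudinalFourCombinations}}.
#' @return data.frame with the pair labels, t, df and p.
#' @export
pairwiseDeltaTests <- function(deltas) {
  stopifnot(nrow(deltas) == 4L)
  lab <- paste(substr(deltas$diag_choice, 1, 1),
               substr(deltas$resp_choice, 1, 1), sep = "-")
  pairs <- utils::combn(4, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    wt <- welchTFromSummaries(deltas$percent_change[i], deltas$se_percent[i],
                              max(2, deltas$n_eff[i]),
                              deltas$percent_change[j], deltas$se_percent[j],
                              max(2, deltas$n_eff[j]))
    data.frame(pair = paste(lab[i], "vs", lab[j]),
               t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' B-value sensitivity analysis over a cohort
#'
#' Selects scans with at least \code{minBValues} b-values and available DWI,
#' runs the combination analysis on each, groups by highest b-value and fits
#' the percent-per-100 slope per scan.
#'
#' @param scans named list of \code{SyntheticScan}.
#' @param manifest included-scan manifest.
#' @param minBValues eligibility threshold on the number of b-values
#'   (default 6, i.e. "more than five").
#' @param fitRange highest-b fit range passed to \code{\link{slopePer100}}.
#' @return list with \code{combinations}, \code{groups} (both row-bound over
#'   scans), \code{slopes} (per scan) and \code{meanSlope} (average percent
#'   decrease per 100 s/mm2 over the eligible scans).
#' @export
bvalueSensitivity <- function(scans, manifest, minBValues = 6,
                              fitRange = c(200, 1000)) {
  eligible <- manifest$scan_id[vapply(manifest$scan_id, function(sid) {
    s <- scans[[sid]]
    !is.null(s) && length(dwiVolumes(s)) > 0 &&
      length(bValues(s)) >= minBValues
  }, logical(1))]
  if (!length(eligible))
    return(list(combinations = NULL, groups = NULL, slopes = NULL,
                meanSlope = NA_real_))
  combos <- list(); groups <- list(); slopes <- list()
  for (sid in eligible) {
    cb <- adcOverCombinations(scans[[sid]])
    gr <- groupByHighestB(cb)
    gr <- cbind(scan_id = sid, gr, stringsAsFactors = FALSE)
    combos[[sid]] <- cb
    groups[[sid]] <- gr
    slopes[[sid]] <- data.frame(
      scan_id = sid,
      percent_per_100 = slopePer100(gr, fitRange),
      stringsAsFactors = FALSE)
  }
  combinations <- do.call(rbind, combos)
  groupsDf <- do.call(rbind, groups)
  slopesDf <- do.call(rbind, slopes)
  rownames(combinations) <- rownames(groupsDf) <- rownames(slopesDf) <- NULL
  list(combinations = combinations, groups = groupsDf, slopes = slopesDf,
       meanSlope = mean(slopesDf$percent_per_100))
}

#' Longitudinal four-combination analysis over a cohort
#'
#' Patients with eligible scans (>= \code{minBValues} b-values) at both
#' diagnosis and response get the four-combination percent-change analysis
#' plus all 6 pairwise Welch tests.
#'
#' @inheritParams bvalueSensitivity
#' @return list with \code{deltas} (4 rows per eligible patient) and
#'   \code{tests} (6 rows per eligible patient); NULL when no patient is
#'   eligible.
#' @export
longitudinalAnalysis <- function(scans, manifest, minBValues = 6) {
  elig <- manifest[vapply(manifest$scan_id, function(sid) {
    s <- scans[[sid]]
    !is.null(s) && length(dwiVolumes(s)) > 0 &&
      length(bValues(s)) >= minBValues
  }, logical(1)), ]
  pts <- intersect(elig$patient_id[elig$timepoint == "diagnosis"],
                   elig$patient_id[elig$timepoint == "response"])
  if (!length(pts)) return(list(deltas = NULL, tests = NULL))
  deltas <- list(); tests <- list()
  for (p in pts) {
    dSid <- elig$scan_id[elig$patient_id == p &
                           elig$timepoint == "diagnosis"][1]
    rSid <- elig$scan_id[elig$patient_id == p &
                           elig$timepoint == "response"][1]
    dg <- groupByHighestB(adcOverCombinations(scans[[dSid]]))
    rg <- groupByHighestB(adcOverCombinations(scans[[rSid]]))
    dl <- longitudinalFourCombinations(dg, rg)
    deltas[[p]] <- cbind(patient_id = p, dl, stringsAsFactors = FALSE)
    tests[[p]] <- cbind(patient_id = p, pairwiseDeltaTests(dl),
                        stringsAsFactors = FALSE)
  }
  deltasDf <- do.call(rbind, deltas); testsDf <- do.call(rbind, tests)
  rownames(deltasDf) <- rownames(testsDf) <- NULL
  list(deltas = deltasDf, tests = testsDf)
}
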