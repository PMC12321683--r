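# Cohort comparisons: median-split Mann-Whitney tests, Bonferroni
# correction, per-parameter regressions and diagnosis-vs-response tests.

#' Split records at the median of a parameter
#'
#' Records with value <= median go to the low group, values > median to the
#' high group; records with a missing parameter are dropped.
#'
#' @param values numeric vector (the acquisition parameter, possibly with NA).
#' @return list with \code{low} and \code{high} (indices into \code{values}),
#'   and \code{split_value} (the median of the non-missing values).
#' @export
medianSplit <- function(values) {
  idx <- which(!is.na(values))
  if (length(idx) < 2L)
    stop("at least 2 non-missing values are required for a median split")
  m <- stats::median(values[idx])
  low <- idx[values[idx] <= m]
  high <- idx[values[idx] > m]
  if (!length(low) || !length(high))
    stop("degenerate split: all values fall on one side of the median")
  list(low = low, high = high, split_value = m)
}

#' Mann-Whitney U test
#'
#' U counts pairs with x > y plus half the tied pairs. The p-value is exact
#' (full permutation null, via the Wilcoxon count recursion) when
#' n_x * n_y <= 400 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y numeric samples, both non-empty.
#' @return list with \code{u}, \code{p} (two-sided) and \code{exact}.
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  exact <- (length(x) * length(y) <= 400) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Bonferroni adjustment with an explicit test count
#'
#' @param p numeric vector of raw p-values.
#' @param m total number of tests in the family; must be at least
#'   \code{length(p)}.
#' @return \code{pmin(1, m * p)}.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, m * p)
}

#' Median-split Mann-Whitney tests per acquisition parameter and timepoint
#'
#' For each of the five acquisition parameters and each timepoint, splits the
#' scans at the parameter median and compares the tumor median ADC between
#' the low and high groups with a Mann-Whitney U test; Bonferroni-corrects
#' over \code{m} tests.
#'
#' @param manifest included-scan manifest.
#' @param summaries ROI summaries (\code{\link{roiSummaries}}); only tumor
#'   rows are used.
#' @param m Bonferroni family size (default 10 = 5 parameters x 2 timepoints).
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame, one row per parameter x timepoint with split value,
#'   group sizes, U, raw and adjusted p, and significance flag; parameter x
#'   timepoint cells with a degenerate split are skipped with a warning.
#' @export
medianSplitTests <- function(manifest, summaries, m = 10, alpha = 0.05) {
  tum <- summaries[summaries$region == "tumor", ]
  merged <- merge(manifest, tum[c("scan_id", "median_adc")], by = "scan_id")
  out <- list()
  for (tp in c("diagnosis", "response")) {
    sub <- merged[merged$timepoint == tp, ]
    for (param in .acqParameters) {
      res <- tryCatch({
        sp <- medianSplit(sub[[param]])
        mw <- mannWhitneyU(sub$median_adc[sp$low], sub$median_adc[sp$high])
        data.frame(parameter = param, timepoint = tp,
                   split_value = sp$split_value,
                   n_low = length(sp$low), n_high = length(sp$high),
                   u_statistic = mw$u, p_raw = mw$p,
                   p_bonferroni = bonferroniAdjust(mw$p, m),
                   significant = bonferroniAdjust(mw$p, m) < alpha,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("skipping ", param, " at ", tp, ": ", conditionMessage(e))
        NULL
      })
      out[[paste(param, tp)]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-parameter simple linear regression of tumor ADC
#'
#' Ordinary least squares of the per-scan tumor median ADC on one
#' acquisition parameter at a time, separately per timepoint (a check that
#' the median split did not hide a continuous effect).
#'
#' @inheritParams medianSplitTests
#' @return data.frame with parameter, timepoint, n, slope, intercept,
#'   p_slope (two-sided t-test on the slope).
#' @export
adcRegression <- function(manifest, summaries) {
  tum <- summaries[summaries$region == "tumor", ]
  merged <- merge(manifest, tum[c("scan_id", "median_adc")], by = "scan_id")
  out <- list()
  for (tp in c("diagnosis", "response")) {
    sub <- merged[merged$timepoint == tp, ]
    for (param in .acqParameters) {
      ok <- !is.na(sub[[param]])
      if (sum(ok) < 3L || stats::var(sub[[param]][ok]) == 0) next
      fit <- stats::lm(sub$median_adc[ok] ~ sub[[param]][ok])
      cf <- summary(fit)$coefficients
      out[[paste(param, tp)]] <- data.frame(
        parameter = param, timepoint = tp, n = sum(ok),
        slope = cf[2, 1], intercept = cf[1, 1], p_slope = cf[2, 4],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare ROI median ADC between diagnosis and response
#'
#' Paired mode applies the Wilcoxon signed-rank procedure to per-patient
#' differences over patients with both timepoints; unpaired mode applies the
#' Mann-Whitney U test to the two timepoint samples.
#'
#' @param summaries ROI summaries.
#' @param region "tumor" or "muscle".
#' @param paired logical.
#' @return list with \code{p}, \code{effect} (median paired difference, or
#'   difference of group medians when unpaired), \code{n} (pairs, or the two
#'   group sizes) and \code{method}.
#' @export
compareTimepoints <- function(summaries, region = c("tumor", "muscle"),
                              paired = TRUE) {
  region <- match.arg(region)
  sub <- summaries[summaries$region == region, ]
  d <- sub$median_adc[sub$timepoint == "diagnosis"]
  r <- sub$median_adc[sub$timepoint == "response"]
  names(d) <- sub$patient_id[sub$timepoint == "diagnosis"]
  names(r) <- sub$patient_id[sub$timepoint == "response"]
  if (!length(d) || !length(r))
    stop("both timepoints must have ", region, " summaries")
  if (paired) {
    common <- intersect(names(d), names(r))
    if (length(common) < 2L)
      stop("fewer than 2 patients have both timepoints for ", region)
    diff <- r[common] - d[common]
    if (all(diff == 0)) return(list(p = 1, effect = 0, n = length(common),
                                    method = "signed-rank (degenerate)"))
    wt <- suppressWarnings(stats::wilcox.test(r[common], d[common],
                                              paired = TRUE))
    list(p = wt$p.value, effect = stats::median(diff), n = length(common),
         method = "Wilcoxon signed-rank, paired")
  } else {
    mw <- mannWhitneyU(r, d)
    list(p = mw$p, effect = stats::median(r) - stats::median(d),
         n = c(length(r), length(d)), method = "Mann-Whitney U, unpaired")
  }
}
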