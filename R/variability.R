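# Acquisition-parameter variability: coefficients of variation overall and
# within centers.

.acqParameters <- c("te_ms", "pixel_spacing_mm", "slice_thickness_mm",
                    "n_bvalues", "highest_bvalue")

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean; missing
#' values are dropped first.
#'
#' @param values numeric vector of positive values (possibly with NA).
#' @return CV, dimensionless.
#' @examples
#' coefficientOfVariation(c(1, 2, 3))  # 0.5
#' @export
coefficientOfVariation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L)
    stop("insufficient data: at least 2 non-missing values are required")
  m <- mean(v)
  if (m <= 0) stop("CV requires a positive mean")
  stats::sd(v) / m
}

#' CV of one acquisition parameter, overall and within centers
#'
#' Overall CV over all non-missing values; within-center CVs for every
#' center contributing at least two non-missing values, summarized by their
#' median and range.
#'
#' @param manifest manifest data.frame with a \code{center_id} column.
#' @param parameter one of te_ms, pixel_spacing_mm, slice_thickness_mm,
#'   n_bvalues, highest_bvalue.
#' @return one-row data.frame: parameter, cv_all_centers,
#'   cv_within_centers_median, cv_within_min, cv_within_max, n_centers_used,
#'   n_used, n_missing. Within-center fields are NA when no center qualifies.
#' @export
cvByCenter <- function(manifest, parameter) {
  if (!parameter %in% .acqParameters)
    stop("parameter must be one of: ", paste(.acqParameters, collapse = ", "))
  x <- manifest[[parameter]]
  nUsed <- sum(!is.na(x)); nMissing <- sum(is.na(x))
  cvAll <- coefficientOfVariation(x)
  within <- vapply(split(x, manifest$center_id), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / mean(v)
  }, numeric(1))
  within <- within[!is.na(within)]
  data.frame(
    parameter = parameter,
    cv_all_centers = cvAll,
    cv_within_centers_median = if (length(within)) stats::median(within) else NA_real_,
    cv_within_min = if (length(within)) min(within) else NA_real_,
    cv_within_max = if (length(within)) max(within) else NA_real_,
    n_centers_used = length(within),
    n_used = nUsed, n_missing = nMissing,
    stringsAsFactors = FALSE
  )
}

#' Variability table over all five acquisition parameters
#'
#' @param manifest manifest data.frame.
#' @return data.frame, one row per parameter, mirroring the multicenter
#'   CV table (overall CV; within-center median and range).
#' @export
variabilityTable <- function(manifest) {
  out <- do.call(rbind, lapply(.acqParameters, cvByCenter,
                               manifest = manifest))
  rownames(out) <- NULL
  out
}
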