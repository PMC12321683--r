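# ROI summaries and the scan inclusion/exclusion flow.

#' Median ADC within an ROI, with exclusion regions removed
#'
#' Summarizes an ADC map over \code{mask} minus \code{exclusionMask} minus the
#' map's invalid voxels. The median of an even count is the midpoint of the
#' two central values (stats::median).
#'
#' @param adcMap an \code{\link{ADCMap}}.
#' @param mask logical array on the map grid (tumor or muscle ROI).
#' @param exclusionMask optional logical array of voxels to remove (e.g.
#'   necrotic/cystic/hemorrhagic annotations); NULL for none.
#' @return list with \code{median_adc}, \code{n_voxels} (voxels entering the
#'   median) and \code{n_excluded_voxels} (mask voxels removed by the
#'   exclusion mask or invalidity).
#' @export
roiMedianADC <- function(adcMap, mask, exclusionMask = NULL) {
  stopifnot(is(adcMap, "ADCMap"))
  if (!identical(dim(mask), dim(adcValues(adcMap))))
    stop("mask must live on the ADC map grid")
  eff <- mask & !invalidMask(adcMap)
  if (!is.null(exclusionMask)) eff <- eff & !exclusionMask
  if (!any(eff))
    stop("no evaluable ROI: the mask is empty after removing excluded ",
         "and invalid voxels")
  vals <- adcValues(adcMap)[eff]
  list(median_adc = stats::median(vals),
       n_voxels = sum(eff),
       n_excluded_voxels = sum(mask) - sum(eff))
}

#' Apply the scan inclusion/exclusion flow
#'
#' Excludes scans in a fixed priority order -- no measurable tumor, then poor
#' quality (score 1), then no DWI data, then tumor outside the field of view
#' -- assigning each excluded scan a single reason (first matching reason
#' wins), and reports counts per reason.
#'
#' @param manifest manifest data.frame carrying \code{quality_score},
#'   \code{has_dwi}, \code{has_measurable_tumor} and \code{in_fov}.
#' @return list with \code{manifest} (included rows) and \code{report}
#'   (n_input_scans, n_excluded_by_reason, n_included).
#' @export
applyInclusionFlow <- function(manifest) {
  need <- c("quality_score", "has_dwi", "has_measurable_tumor", "in_fov")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest lacks inclusion flags: ", paste(miss, collapse = ", "))
  bad <- manifest$scan_id[rowSums(is.na(manifest[need])) > 0]
  if (length(bad))
    stop("missing inclusion flags for scans: ", paste(bad, collapse = ", "))
  reason <- rep(NA_character_, nrow(manifest))
  reason[!manifest$has_measurable_tumor] <- "no_measurable_tumor"
  reason[is.na(reason) & manifest$quality_score == 1L] <- "poor_quality"
  reason[is.na(reason) & !manifest$has_dwi] <- "no_dwi"
  reason[is.na(reason) & !manifest$in_fov] <- "outside_fov"
  counts <- vapply(c("no_measurable_tumor", "poor_quality", "no_dwi",
                     "outside_fov"),
                   function(r) sum(reason == r, na.rm = TRUE), 0L)
  list(manifest = manifest[is.na(reason), , drop = FALSE],
       report = list(n_input_scans = nrow(manifest),
                     n_excluded_by_reason = as.list(counts),
                     n_included = sum(is.na(reason))))
}

#' ROI summaries for a cohort of scans
#'
#' Fits the full-b-value ADC map of every included scan and computes the
#' tumor median (necrotic exclusion region removed) and, where a muscle mask
#' is present, the muscle median.
#'
#' @param scans named list of \code{SyntheticScan} with volumes.
#' @param manifest manifest restricted to the scans to summarize (e.g. the
#'   included rows from \code{\link{applyInclusionFlow}}).
#' @return data.frame with scan_id, patient_id, center_id, timepoint, region
#'   ("tumor"/"muscle"), median_adc, n_voxels, n_excluded_voxels.
#' @export
roiSummaries <- function(scans, manifest) {
  out <- lapply(manifest$scan_id, function(sid) {
    scan <- scans[[sid]]
    if (is.null(scan) || !length(dwiVolumes(scan))) return(NULL)
    map <- computeADCMap(scan)
    row <- manifest[manifest$scan_id == sid, c("scan_id", "patient_id",
                                               "center_id", "timepoint")]
    tum <- roiMedianADC(map, tumorMask(scan), exclusionMask(scan))
    res <- cbind(row, region = "tumor", as.data.frame(tum),
                 stringsAsFactors = FALSE)
    if (any(muscleMask(scan))) {
      mus <- roiMedianADC(map, muscleMask(scan))
      res <- rbind(res, cbind(row, region = "muscle", as.data.frame(mus),
                              stringsAsFactors = FALSE))
    }
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort-level mean/SD table of ROI median ADC
#'
#' Mean, sample SD (n-1 denominator), min, max and n of the per-scan median
#' ADC for every region x timepoint cell; cells with no data are absent from
#' the table.
#'
#' @param summaries output of \code{\link{roiSummaries}}.
#' @return data.frame with region, timepoint, n, mean_adc, sd_adc, min_adc,
#'   max_adc.
#' @export
summarizeCohort <- function(summaries) {
  cells <- unique(summaries[c("region", "timepoint")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- summaries$median_adc[summaries$region == cells$region[i] &
                                summaries$timepoint == cells$timepoint[i]]
    data.frame(region = cells$region[i], timepoint = cells$timepoint[i],
               n = length(v), mean_adc = mean(v),
               sd_adc = if (length(v) >= 2) stats::sd(v) else NA_real_,
               min_adc = min(v), max_adc = max(v),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$region, out$timepoint), ]
  rownames(out) <- NULL
  out
}
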