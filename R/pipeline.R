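# Pipeline orchestration: config I/O, NIfTI writers/readers, the staged
# end-to-end run, and an in-process CLI argument handler.

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the cohort configuration; on read, values are merged
#' over \code{\link{defaultCohortConfig}} and unknown keys are rejected.
#'
#' @param path file path.
#' @param config configuration list (for writing).
#' @return \code{readPipelineConfig} returns the validated config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultCohortConfig()
  mergeInto <- function(base, upd, where = "") {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop("unknown config keys", where, ": ", paste(unknown, collapse = ", "))
    for (k in names(upd)) {
      if (is.list(base[[k]]) && is.list(upd[[k]]) &&
          !is.null(names(base[[k]])))
        base[[k]] <- mergeInto(base[[k]], upd[[k]], paste0(" in ", k))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  cfg <- mergeInto(cfg, user)
  if (!is.null(cfg$acquisition$schemeWeights))
    cfg$acquisition$schemeWeights <- unlist(cfg$acquisition$schemeWeights)
  validateCohortConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  # serialize the scheme weights as a YAML map so names survive the round trip
  if (!is.null(config$acquisition$schemeWeights))
    config$acquisition$schemeWeights <-
      as.list(config$acquisition$schemeWeights)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write / read a synthetic scan as NIfTI + JSON sidecar
#'
#' One .nii.gz per b-value volume, a label volume (0 background, 1 tumor,
#' 2 excluded-within-tumor, 3 muscle) and a JSON sidecar with b-values,
#' acquisition parameters, flags and ground-truth tissue states.
#'
#' @param scan a \code{SyntheticScan} with volumes.
#' @param dir output directory (created if needed).
#' @param sid scan identifier (for reading).
#' @return \code{writeScanNifti} returns the sidecar path invisibly;
#'   \code{readScanNifti} returns the reconstructed \code{SyntheticScan}.
#' @export
writeScanNifti <- function(scan, dir) {
  stopifnot(is(scan, "SyntheticScan"), length(dwiVolumes(scan)) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- scanId(scan)
  b <- bValues(scan)
  volPaths <- file.path(dir, sprintf("%s_b%04d.nii.gz", sid, as.integer(b)))
  for (i in seq_along(b))
    RNifti::writeNifti(dwiVolumes(scan)[[i]], volPaths[i])
  labels <- array(0L, dim = dim(tumorMask(scan)))
  labels[tumorMask(scan)] <- 1L
  labels[exclusionMask(scan)] <- 2L
  labels[muscleMask(scan)] <- 3L
  maskPath <- file.path(dir, sprintf("%s_masks.nii.gz", sid))
  RNifti::writeNifti(labels, maskPath)
  ts2list <- function(ts) list(f = ts@f, dTissue = ts@dTissue,
                               dPseudo = ts@dPseudo, targetADC = ts@targetADC)
  meta <- list(scan_id = sid, patient_id = scan@patientId,
               center_id = scan@centerId, timepoint = scan@timepoint,
               bvalues = b, acquisition = scan@acquisition,
               quality_score = scan@qualityScore, has_dwi = scan@hasDWI,
               in_fov = scan@inFov,
               has_measurable_tumor = scan@hasMeasurableTumor,
               ground_truth = lapply(groundTruth(scan), ts2list))
  metaPath <- file.path(dir, sprintf("%s_meta.json", sid))
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(metaPath)
}

#' @rdname writeScanNifti
#' @export
readScanNifti <- function(dir, sid) {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", sid)),
                              simplifyVector = TRUE)
  b <- as.numeric(meta$bvalues)
  vols <- lapply(b, function(bb) {
    v <- RNifti::readNifti(file.path(dir, sprintf("%s_b%04d.nii.gz", sid,
                                                  as.integer(bb))))
    array(as.numeric(v), dim = dim(v))
  })
  labels <- RNifti::readNifti(file.path(dir, sprintf("%s_masks.nii.gz", sid)))
  labels <- array(as.integer(labels), dim = dim(labels))
  gt <- lapply(meta$ground_truth, function(g)
    tissueState(g$f, g$dTissue, g$dPseudo, g$targetADC))
  new("SyntheticScan",
      scanId = meta$scan_id, patientId = meta$patient_id,
      centerId = meta$center_id, timepoint = meta$timepoint,
      bvalues = b, volumes = vols,
      tumorMask = labels == 1L | labels == 2L,
      exclusionMask = labels == 2L, muscleMask = labels == 3L,
      acquisition = as.list(meta$acquisition),
      qualityScore = as.integer(meta$quality_score),
      hasDWI = isTRUE(meta$has_dwi), inFov = isTRUE(meta$in_fov),
      hasMeasurableTumor = isTRUE(meta$has_measurable_tumor),
      groundTruth = gt)
}

#' Write an ADC map as NIfTI with a JSON provenance sidecar
#'
#' @param map an \code{ADCMap}.
#' @param path output .nii.gz path; the sidecar replaces the extension with
#'   .json and records the b-values used and the fit method.
#' @return the sidecar path, invisibly.
#' @export
writeADCMapNifti <- function(map, path) {
  stopifnot(is(map, "ADCMap"))
  adc <- adcValues(map)
  adc[invalidMask(map)] <- NA_real_
  RNifti::writeNifti(adc, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(scan_id = scanId(map),
                            fit_bvalues = bValues(map),
                            fit_method = "loglinear-ols",
                            n_invalid = sum(invalidMask(map))),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

.writeCsv <- function(x, dir, name) {
  if (is.null(x)) return(invisible(NULL))
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  invisible(file.path(dir, name))
}

#' Run the full analysis pipeline
#'
#' Simulate -> inclusion flow -> ADC fitting and ROI medians -> cohort
#' summary -> acquisition variability -> median-split / regression
#' comparisons -> b-value sensitivity -> longitudinal analysis, writing the
#' standard table set (manifest.csv, inclusion_report.json,
#' roi_summaries.csv, cohort_summary.csv, variability_table.csv,
#' comparisons.csv, regressions.csv, bsens_combinations.csv,
#' bsens_groups.csv, bsens_slopes.csv, longitudinal_deltas.csv,
#' longitudinal_tests.csv), a summary.json and the resolved config.yaml into
#' \code{outDir}. Idempotent for a fixed seed.
#'
#' @param config cohort configuration.
#' @param outDir output directory.
#' @param seed master seed (defaults to \code{config$seed}).
#' @param writeVolumes also write every scan's volumes/masks as NIfTI under
#'   \code{outDir/scans} and ADC maps under \code{outDir/adc} (slower).
#' @param bonferroniM Bonferroni family size for the median-split tests.
#' @param fitRange highest-b fit range for the sensitivity slope.
#' @return invisibly, a list with all in-memory results (cohort, report,
#'   summaries, cohortSummary, variability, comparisons, regressions, bsens,
#'   longitudinal, timepointTests).
#' @export
runPipeline <- function(config = defaultCohortConfig(), outDir,
                        seed = config$seed, writeVolumes = FALSE,
                        bonferroniM = 10, fitRange = c(200, 1000)) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(config, seed = seed, volumes = TRUE)
  writePipelineConfig(cohort$config, file.path(outDir, "config.yaml"))
  .writeCsv(cohort$manifest, outDir, "manifest.csv")

  flow <- applyInclusionFlow(cohort$manifest)
  jsonlite::write_json(flow$report, file.path(outDir, "inclusion_report.json"),
                       auto_unbox = TRUE, digits = NA)

  if (writeVolumes) {
    for (sid in flow$manifest$scan_id)
      if (length(dwiVolumes(cohort$scans[[sid]])))
        writeScanNifti(cohort$scans[[sid]], file.path(outDir, "scans"))
  }

  summaries <- roiSummaries(cohort$scans, flow$manifest)
  .writeCsv(summaries, outDir, "roi_summaries.csv")
  if (writeVolumes) {
    dir.create(file.path(outDir, "adc"), showWarnings = FALSE)
    for (sid in flow$manifest$scan_id) {
      s <- cohort$scans[[sid]]
      if (length(dwiVolumes(s)))
        writeADCMapNifti(computeADCMap(s),
                         file.path(outDir, "adc", paste0(sid, "_adc.nii.gz")))
    }
  }

  cohortSummary <- summarizeCohort(summaries)
  .writeCsv(cohortSummary, outDir, "cohort_summary.csv")

  variability <- variabilityTable(flow$manifest)
  .writeCsv(variability, outDir, "variability_table.csv")

  comparisons <- medianSplitTests(flow$manifest, summaries, m = bonferroniM)
  .writeCsv(comparisons, outDir, "comparisons.csv")
  regressions <- adcRegression(flow$manifest, summaries)
  .writeCsv(regressions, outDir, "regressions.csv")

  bsens <- bvalueSensitivity(cohort$scans, flow$manifest,
                             fitRange = fitRange)
  .writeCsv(bsens$combinations, outDir, "bsens_combinations.csv")
  .writeCsv(bsens$groups, outDir, "bsens_groups.csv")
  .writeCsv(bsens$slopes, outDir, "bsens_slopes.csv")

  longit <- longitudinalAnalysis(cohort$scans, flow$manifest)
  .writeCsv(longit$deltas, outDir, "longitudinal_deltas.csv")
  .writeCsv(longit$tests, outDir, "longitudinal_tests.csv")

  tpTests <- list(
    tumor_paired = tryCatch(compareTimepoints(summaries, "tumor", TRUE),
                            error = function(e) NULL),
    tumor_unpaired = tryCatch(compareTimepoints(summaries, "tumor", FALSE),
                              error = function(e) NULL),
    muscle_paired = tryCatch(compareTimepoints(summaries, "muscle", TRUE),
                             error = function(e) NULL))

  summary <- list(seed = cohort$config$seed,
                  inclusion = flow$report,
                  cohort_summary = cohortSummary,
                  variability = variability,
                  mean_slope_percent_per_100 = bsens$meanSlope,
                  n_longitudinal_patients =
                    if (is.null(longit$deltas)) 0L
                    else length(unique(longit$deltas$patient_id)),
                  timepoint_tests = lapply(tpTests, function(x)
                    if (is.null(x)) NULL else x[c("p", "effect", "method")]))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(cohort = cohort, report = flow$report,
                 includedManifest = flow$manifest,
                 summaries = summaries, cohortSummary = cohortSummary,
                 variability = variability, comparisons = comparisons,
                 regressions = regressions, bsens = bsens,
                 longitudinal = longit, timepointTests = tpTests))
}

#' Recompute the analysis stages from saved intermediates
#'
#' Re-runs variability, median-split/regression comparisons and the cohort
#' summary from the CSV tables a previous \code{\link{runPipeline}} left in
#' \code{outDir} (stage isolation: no simulation or fitting involved).
#'
#' @param outDir directory holding manifest.csv and roi_summaries.csv.
#' @param bonferroniM Bonferroni family size.
#' @return list with cohortSummary, variability, comparisons, regressions.
#' @export
rerunAnalysisStages <- function(outDir, bonferroniM = 10) {
  manifest <- utils::read.csv(file.path(outDir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  flow <- applyInclusionFlow(manifest)
  summaries <- utils::read.csv(file.path(outDir, "roi_summaries.csv"),
                               stringsAsFactors = FALSE)
  list(cohortSummary = summarizeCohort(summaries),
       variability = variabilityTable(flow$manifest),
       comparisons = medianSplitTests(flow$manifest, summaries,
                                      m = bonferroniM),
       regressions = adcRegression(flow$manifest, summaries))
}

#' In-process command-line entry point
#'
#' Parses CLI-style arguments and dispatches to the pipeline. Stages:
#' \code{run-all} (default) runs \code{\link{runPipeline}}; \code{simulate}
#' generates and writes the cohort only; \code{analyze} re-runs the analysis
#' stages from saved tables. Flags: \code{--config PATH}, \code{--seed INT},
#' \code{--out DIR}, \code{--noise-sigma X}, \code{--write-volumes}.
#'
#' @param args character vector, e.g. \code{commandArgs(trailingOnly=TRUE)}.
#' @return the dispatched result, invisibly.
#' @export
pipelineCLI <- function(args) {
  stage <- "run-all"
  if (length(args) && !startsWith(args[1], "--")) {
    stage <- args[1]; args <- args[-1]
  }
  opt <- list(config = NULL, seed = NULL, out = "adcvar_out",
              writeVolumes = FALSE, noiseSigma = NULL)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    adv <- function() { i <<- i + 1; args[i] }
    switch(a,
      "--config" = { opt$config <- adv() },
      "--seed" = { opt$seed <- as.integer(adv()) },
      "--out" = { opt$out <- adv() },
      "--noise-sigma" = { opt$noiseSigma <- as.numeric(adv()) },
      "--write-volumes" = { opt$writeVolumes <- TRUE },
      stop("unknown argument: ", a))
    i <- i + 1
  }
  cfg <- if (is.null(opt$config)) defaultCohortConfig()
         else readPipelineConfig(opt$config)
  if (!is.null(opt$noiseSigma)) cfg$noiseSigma <- opt$noiseSigma
  seed <- if (is.null(opt$seed)) cfg$seed else opt$seed
  res <- switch(stage,
    "run-all" = runPipeline(cfg, opt$out, seed = seed,
                            writeVolumes = opt$writeVolumes),
    "simulate" = {
      cohort <- generateCohort(cfg, seed = seed, volumes = opt$writeVolumes)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      .writeCsv(cohort$manifest, opt$out, "manifest.csv")
      writePipelineConfig(cohort$config, file.path(opt$out, "config.yaml"))
      if (opt$writeVolumes)
        for (s in cohort$scans)
          if (length(dwiVolumes(s)))
            writeScanNifti(s, file.path(opt$out, "scans"))
      cohort
    },
    "analyze" = rerunAnalysisStages(opt$out),
    stop("unknown stage: ", stage))
  invisible(res)
}
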