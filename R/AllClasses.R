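#' @import methods
NULL

#' Tissue state for the bi-exponential signal model
#'
#' A voxel compartmental description used by the synthetic signal generator:
#' a fast pseudo-diffusion (perfusion) fraction \code{f} with diffusivity
#' \code{dPseudo} and a tissue compartment with diffusivity \code{dTissue},
#' both in um^2/ms. \code{targetADC} records the two-point mono-exponential
#' ADC at the reference highest b-value that this tissue state was solved to
#' produce (see \code{\link{solveTissueD}}).
#'
#' @slot f perfusion fraction, dimensionless, in [0, 1).
#' @slot dTissue tissue diffusivity, um^2/ms.
#' @slot dPseudo pseudo-diffusion coefficient, um^2/ms; must exceed dTissue.
#' @slot targetADC calibrated two-point ADC at the reference b-value, um^2/ms.
#' @export
setClass("TissueState",
         slots = c(f = "numeric", dTissue = "numeric",
                   dPseudo = "numeric", targetADC = "numeric"))

setValidity("TissueState", function(object) {
  msg <- character()
  if (length(object@f) != 1L || is.na(object@f) || object@f < 0 || object@f >= 1)
    msg <- c(msg, "f must be a single value in [0, 1)")
  if (length(object@dTissue) != 1L || is.na(object@dTissue) || object@dTissue <= 0)
    msg <- c(msg, "dTissue must be a single positive value")
  if (length(object@dPseudo) != 1L || is.na(object@dPseudo) ||
      object@dPseudo <= object@dTissue)
    msg <- c(msg, "dPseudo must exceed dTissue")
  if (length(object@targetADC) != 1L || is.na(object@targetADC) ||
      object@targetADC <= 0)
    msg <- c(msg, "targetADC must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueState
#'
#' @param f perfusion fraction in [0, 1).
#' @param dTissue tissue diffusivity, um^2/ms.
#' @param dPseudo pseudo-diffusion coefficient, um^2/ms.
#' @param targetADC the two-point ADC (um^2/ms) at the reference b-value this
#'   state is calibrated to produce; defaults to \code{dTissue} which is exact
#'   when \code{f = 0}.
#' @return A \code{TissueState} object.
#' @examples
#' tissueState(f = 0.075, dTissue = 1.1, dPseudo = 20, targetADC = 1.178)
#' @export
tissueState <- function(f, dTissue, dPseudo = 20, targetADC = dTissue) {
  new("TissueState", f = as.numeric(f), dTissue = as.numeric(dTissue),
      dPseudo = as.numeric(dPseudo), targetADC = as.numeric(targetADC))
}

#' Synthetic multi-b DWI scan
#'
#' One scan of the synthetic cohort: a stack of 3-D signal volumes (one per
#' b-value), label masks for tumor / excluded (necrotic-like) / muscle
#' regions, the sampled acquisition parameters, inclusion-flow flags and the
#' ground-truth tissue states per region. Volumes may be absent (e.g. a scan
#' flagged as having no DWI data, or a manifest-only cohort).
#'
#' @slot scanId,patientId,centerId identifiers.
#' @slot timepoint "diagnosis" or "response".
#' @slot bvalues b-values in s/mm2, strictly increasing, first element 0.
#' @slot volumes list of 3-D arrays (signal, arbitrary units), one per b-value,
#'   or an empty list.
#' @slot tumorMask,exclusionMask,muscleMask logical arrays on the same grid;
#'   the exclusion mask is a subset of the tumor mask.
#' @slot acquisition named list: te_ms, pixel_spacing_mm, slice_thickness_mm,
#'   n_bvalues, highest_bvalue, scheme.
#' @slot qualityScore integer 1..3 (1 = poor, excluded by the inclusion flow).
#' @slot hasDWI,inFov,hasMeasurableTumor inclusion-flow flags.
#' @slot groundTruth named list of \code{TissueState} (tumor, and optionally
#'   necrotic, muscle).
#' @export
setClass("SyntheticScan",
         slots = c(scanId = "character", patientId = "character",
                   centerId = "character", timepoint = "character",
                   bvalues = "numeric", volumes = "list",
                   tumorMask = "array", exclusionMask = "array",
                   muscleMask = "array", acquisition = "list",
                   qualityScore = "integer", hasDWI = "logical",
                   inFov = "logical", hasMeasurableTumor = "logical",
                   groundTruth = "list"))

setValidity("SyntheticScan", function(object) {
  msg <- character()
  b <- object@bvalues
  if (length(b) < 2L || b[1] != 0 || any(diff(b) <= 0) || any(b < 0))
    msg <- c(msg, "bvalues must be strictly increasing with bvalues[1] = 0")
  if (!object@timepoint %in% c("diagnosis", "response"))
    msg <- c(msg, "timepoint must be 'diagnosis' or 'response'")
  nv <- length(object@volumes)
  if (nv > 0L) {
    if (nv != length(b))
      msg <- c(msg, "one volume per b-value is required")
    dims <- unique(lapply(object@volumes, dim))
    if (length(dims) > 1L)
      msg <- c(msg, "all volumes must share one grid shape")
    if (any(vapply(object@volumes, function(v) any(v < 0), logical(1))))
      msg <- c(msg, "DWI signal must be non-negative everywhere")
    if (length(dim(object@tumorMask)) == 3L) {
      if (!identical(dim(object@tumorMask), dims[[1]]))
        msg <- c(msg, "masks must live on the volume grid")
      if (any(object@exclusionMask & !object@tumorMask))
        msg <- c(msg, "exclusionMask must be a subset of tumorMask")
    }
  }
  if (!object@qualityScore %in% 1:3)
    msg <- c(msg, "qualityScore must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' Voxelwise ADC map
#'
#' The result of a mono-exponential log-linear fit applied voxelwise to a
#' subset of a scan's b-value volumes. Voxels where any input signal was
#' non-positive are flagged in \code{invalid} and carry \code{NA} in
#' \code{adc}; they are never silently zero-filled.
#'
#' @slot adc 3-D array of ADC values in um^2/ms (NA where invalid).
#' @slot bvalues the b-values used for the fit (provenance).
#' @slot invalid logical array flagging voxels where the fit was impossible.
#' @slot scanId identifier of the source scan ("" when fitted from a bare array).
#' @export
setClass("ADCMap",
         slots = c(adc = "array", bvalues = "numeric",
                   invalid = "array", scanId = "character"))

setValidity("ADCMap", function(object) {
  msg <- character()
  if (!identical(dim(object@adc), dim(object@invalid)))
    msg <- c(msg, "adc and invalid must share dimensions")
  if (any(!is.finite(object@adc[!object@invalid])))
    msg <- c(msg, "adc must be finite wherever not invalid")
  if (any(is.na(object@invalid)))
    msg <- c(msg, "invalid mask must not contain NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TissueState", function(object) {
  cat(sprintf("TissueState: f=%.4g, dTissue=%.4g, dPseudo=%.4g um2/ms (target ADC %.4g)\n",
              object@f, object@dTissue, object@dPseudo, object@targetADC))
})

setMethod("show", "SyntheticScan", function(object) {
  cat(sprintf("SyntheticScan %s (patient %s, center %s, %s)\n",
              object@scanId, object@patientId, object@centerId, object@timepoint))
  cat(sprintf("  b-values (s/mm2): %s\n", paste(object@bvalues, collapse = ", ")))
  if (length(object@volumes)) {
    d <- dim(object@volumes[[1]])
    cat(sprintf("  %d volumes on a %dx%dx%d grid; tumor %d vox (%d excluded), muscle %d vox\n",
                length(object@volumes), d[1], d[2], d[3],
                sum(object@tumorMask), sum(object@exclusionMask),
                sum(object@muscleMask)))
  } else cat("  (no volumes attached)\n")
  cat(sprintf("  quality %d, hasDWI=%s, measurable tumor=%s, in FOV=%s\n",
              object@qualityScore, object@hasDWI, object@hasMeasurableTumor,
              object@inFov))
})

setMethod("show", "ADCMap", function(object) {
  d <- dim(object@adc)
  cat(sprintf("ADCMap (%dx%dx%d) fitted on b = {%s}; %d invalid voxels\n",
              d[1], d[2], d[3], paste(object@bvalues, collapse = ", "),
              sum(object@invalid)))
})

# ---- accessors ----

#' Accessors for adcvar S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a \code{SyntheticScan} or \code{ADCMap}.
#' @return The corresponding component: numeric b-values, list of volumes,
#'   logical mask arrays, the ADC array, the invalid-voxel mask, the
#'   ground-truth list, or the scan identifier.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("dwiVolumes", function(x) standardGeneric("dwiVolumes"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setGeneric("exclusionMask", function(x) standardGeneric("exclusionMask"))
#' @rdname accessors
#' @export
setGeneric("muscleMask", function(x) standardGeneric("muscleMask"))
#' @rdname accessors
#' @export
setGeneric("adcValues", function(x) standardGeneric("adcValues"))
#' @rdname accessors
#' @export
setGeneric("invalidMask", function(x) standardGeneric("invalidMask"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))

#' @rdname accessors
setMethod("bValues", "SyntheticScan", function(x) x@bvalues)
#' @rdname accessors
setMethod("bValues", "ADCMap", function(x) x@bvalues)
#' @rdname accessors
setMethod("dwiVolumes", "SyntheticScan", function(x) x@volumes)
#' @rdname accessors
setMethod("tumorMask", "SyntheticScan", function(x) x@tumorMask)
#' @rdname accessors
setMethod("exclusionMask", "SyntheticScan", function(x) x@exclusionMask)
#' @rdname accessors
setMethod("muscleMask", "SyntheticScan", function(x) x@muscleMask)
#' @rdname accessors
setMethod("adcValues", "ADCMap", function(x) x@adc)
#' @rdname accessors
setMethod("invalidMask", "ADCMap", function(x) x@invalid)
#' @rdname accessors
setMethod("groundTruth", "SyntheticScan", function(x) x@groundTruth)
#' @rdname accessors
setMethod("scanId", "SyntheticScan", function(x) x@scanId)
#' @rdname accessors
setMethod("scanId", "ADCMap", function(x) x@scanId)
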