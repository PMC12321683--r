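# Mono-exponential log-linear ADC fitting.
#
# The estimator is ordinary least squares of ln(signal) on b: the slope of
# the 2-parameter log-linear model, obtained by solving the normal equations
# (a direct linear-system solve, i.e. Gaussian elimination). ADC is reported
# as -slope * 1e3 so that b in s/mm2 yields ADC in um^2/ms; that unit factor
# is applied exactly once, here.

.checkBValueSet <- function(bvalues) {
  if (length(bvalues) < 2L)
    stop("at least two b-values are required")
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("b-values must be finite and non-negative")
  if (anyDuplicated(bvalues))
    stop("b-values must be unique")
  if (min(bvalues) != 0)
    stop("the b-value set must contain the non-weighted image (b = 0)")
  sort(bvalues)
}

#' Fit ADC to one signal vector by log-linear least squares
#'
#' Solves the normal equations of the model ln S = a - ADC/1e3 * b by
#' Gaussian elimination and returns the ADC in um^2/ms. With exactly two
#' b-values this reduces to the log-ratio formula
#' ln(S(b0)/S(b1)) / (b1 - b0) * 1e3.
#'
#' @param bvalues b-values, s/mm2; must include 0, length >= 2.
#' @param signals positive signal values, same length as \code{bvalues}.
#' @return ADC in um^2/ms (0 for a flat signal; negative values are possible
#'   for noisy increasing signals and are reported as fitted).
#' @examples
#' fitADC(c(0, 500, 1000), exp(-c(0, 500, 1000) * 1.2e-3))  # 1.2
#' @export
fitADC <- function(bvalues, signals) {
  b <- as.numeric(bvalues)
  if (length(b) != length(signals))
    stop("bvalues and signals must have equal length")
  .checkBValueSet(b)
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop("all signals must be positive for a log-linear fit")
  o <- order(b)
  X <- cbind(1, b[o])
  beta <- solve(crossprod(X), crossprod(X, log(signals[o])))
  -beta[2L] * 1e3
}

# vectorised voxel fit: Y is an n_vox x n_b matrix of raw signals,
# b the matching b-values. Returns list(adc, invalid); invalid voxels
# (any signal <= 0 or non-finite) carry NA.
.fitADCMatrix <- function(b, Y) {
  invalid <- rowSums(!is.finite(Y) | Y <= 0) > 0
  bc <- b - mean(b)
  sxx <- sum(bc^2)
  adc <- rep(NA_real_, nrow(Y))
  if (any(!invalid)) {
    L <- log(Y[!invalid, , drop = FALSE])
    adc[!invalid] <- -as.vector(L %*% bc) / sxx * 1e3
  }
  list(adc = adc, invalid = invalid)
}

#' Compute a voxelwise ADC map from a scan's b-value subset
#'
#' Applies the log-linear fit voxelwise using only the volumes of the
#' requested b-value subset, and records the subset in the map's provenance.
#' Voxels with any non-positive signal in the subset are flagged invalid.
#'
#' @param scan a \code{SyntheticScan} with volumes attached.
#' @param bvalueSubset subset of \code{bValues(scan)}; must contain 0 and at
#'   least one nonzero b-value. Defaults to the full set. Order is irrelevant
#'   (the subset is canonically sorted).
#' @return An \code{\link{ADCMap}}.
#' @export
computeADCMap <- function(scan, bvalueSubset = bValues(scan)) {
  stopifnot(is(scan, "SyntheticScan"))
  if (!length(dwiVolumes(scan)))
    stop("scan ", scanId(scan), " has no DWI volumes")
  sub <- .checkBValueSet(as.numeric(bvalueSubset))
  if (!all(sub %in% bValues(scan)))
    stop("invalid subset: not all requested b-values are present in the scan")
  idx <- match(sub, bValues(scan))
  vols <- dwiVolumes(scan)[idx]
  d <- dim(vols[[1]])
  Y <- vapply(vols, as.vector, numeric(prod(d)))
  fit <- .fitADCMatrix(sub, Y)
  new("ADCMap", adc = array(fit$adc, dim = d), bvalues = sub,
      invalid = array(fit$invalid, dim = d), scanId = scanId(scan))
}
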