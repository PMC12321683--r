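#' Bi-exponential (IVIM-style) DWI signal
#'
#' Two-compartment diffusion signal
#' \deqn{S(b) = S_0 [ f e^{-b D_p 10^{-3}} + (1-f) e^{-b D_t 10^{-3}} ]}
#' with \eqn{b} in s/mm2 and diffusivities in um^2/ms; the 1e-3 factor makes
#' the exponent dimensionless. This is the mechanism the synthetic cohort
#' uses to make the mono-exponentially fitted ADC depend on the highest
#' b-value included in the fit: the perfusion compartment decays away at low
#' b, so fits reaching to higher b see a slower apparent decay.
#'
#' @param b b-value(s), s/mm2, non-negative. Vectorised.
#' @param tissue a \code{\link{tissueState}}.
#' @param s0 signal at b = 0 (arbitrary units), positive scalar.
#' @return Signal values, same length as \code{b}; non-increasing in b.
#' @examples
#' ts <- tissueState(f = 0.075, dTissue = 1.1, dPseudo = 20)
#' ivimSignal(c(0, 500, 1000), ts)
#' @export
ivimSignal <- function(b, tissue, s0 = 1) {
  stopifnot(is(tissue, "TissueState"))
  if (any(!is.finite(b)) || any(b < 0))
    stop("b-values must be finite and non-negative")
  if (length(s0) != 1L || !is.finite(s0) || s0 <= 0)
    stop("s0 must be a single positive value")
  s0 * (tissue@f * exp(-b * tissue@dPseudo * 1e-3) +
          (1 - tissue@f) * exp(-b * tissue@dTissue * 1e-3))
}

#' Two-point mono-exponential ADC of the model signal
#'
#' The ADC (um^2/ms) that a two-point log-ratio fit at \{0, bRef\} recovers
#' from the noise-free bi-exponential signal:
#' \eqn{\ln(S(0)/S(b_{ref})) / b_{ref} \cdot 10^3}.
#'
#' @param tissue a \code{TissueState}.
#' @param bRef reference (highest) b-value, s/mm2.
#' @return ADC in um^2/ms.
#' @export
twoPointADC <- function(tissue, bRef = 1000) {
  log(ivimSignal(0, tissue) / ivimSignal(bRef, tissue)) / bRef * 1e3
}

#' Solve the tissue diffusivity that yields a target two-point ADC
#'
#' Given a perfusion fraction and pseudo-diffusion coefficient, finds
#' \code{dTissue} such that the two-point ADC at \code{bRef}
#' (\code{\link{twoPointADC}}) equals \code{targetADC}. The two-point
#' relation inverts exactly: with k = bRef/1000,
#' (1-f) exp(-k d) = exp(-k ADC) - f exp(-k dPseudo), so
#' d = -ln[(exp(-k ADC) - f exp(-k dPseudo)) / (1-f)] / k. Targets whose
#' solution falls outside the physiologic bracket (0.01, 4) um^2/ms (or for
#' which the right-hand side is non-positive) are rejected as infeasible.
#'
#' @param targetADC desired two-point ADC at \code{bRef}, um^2/ms.
#' @param f perfusion fraction in [0, 1).
#' @param dPseudo pseudo-diffusion coefficient, um^2/ms.
#' @param bRef reference b-value, s/mm2.
#' @return A \code{TissueState} with the solved \code{dTissue} and the target
#'   recorded; exact to floating-point precision (well below 1e-6 um^2/ms).
#' @examples
#' ts <- solveTissueD(1.09, f = 0, dPseudo = 20)
#' ts@dTissue  # 1.09 exactly for f = 0
#' @export
solveTissueD <- function(targetADC, f = 0.065, dPseudo = 20, bRef = 1000) {
  if (length(targetADC) != 1L || !is.finite(targetADC) || targetADC <= 0)
    stop("targetADC must be a single positive value")
  k <- bRef * 1e-3
  rhs <- exp(-targetADC * k) - f * exp(-dPseudo * k)
  d <- if (rhs > 0) -log(rhs / (1 - f)) / k else NA_real_
  if (!is.finite(d) || d <= 0.01 || d >= 4)
    stop("infeasible target: no tissue diffusivity in (0.01, 4) um2/ms ",
         "produces a two-point ADC of ", targetADC)
  new("TissueState", f = f, dTissue = d, dPseudo = dPseudo,
      targetADC = targetADC)
}

#' Add Rician noise to a magnitude volume
#'
#' Each voxel value v is replaced by sqrt((v + e1)^2 + e2^2) with e1, e2
#' independent zero-mean Gaussians of standard deviation \code{sigma} --
#' the magnitude-image noise model of MRI. With \code{sigma = 0} the input is
#' returned unchanged. Draws come from the current RNG state; callers that
#' need reproducibility set the seed first.
#'
#' @param volume numeric array of non-negative signal values.
#' @param sigma noise standard deviation in signal units, >= 0.
#' @return Array of the same shape; note the Rician floor raises the expected
#'   value above the noise-free signal (a zero-signal voxel has mean
#'   sigma * sqrt(pi/2)).
#' @export
addRicianNoise <- function(volume, sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a single non-negative value")
  if (sigma == 0) return(volume)
  n <- length(volume)
  out <- sqrt((volume + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  array(out, dim = dim(volume))
}
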