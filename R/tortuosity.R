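#' Free-diffusion constants for the tortuosity chain
#'
#' The free (unhindered) diffusion coefficients used to convert a measured
#' tissue water ADC into a predicted tracer ADC: water at 3e-6 mm^2/ms and
#' bovine serum albumin (66 kD, the standard stand-in for a 70 kD
#' gadolinium-albumin tracer) at 8.29e-8 mm^2/ms. Both can be overridden.
#'
#' @param d_water Free water diffusivity, mm^2/ms.
#' @param d_albumin Free albumin diffusivity, mm^2/ms; must be below
#'   `d_water`.
#' @return A `free_diffusion_constants` list.
#' @export
free_diffusion_constants <- function(d_water = 3e-6, d_albumin = 8.29e-8) {
  if (d_water <= 0 || d_albumin <= 0) abort_input("constants must be > 0")
  if (d_albumin >= d_water) abort_input("d_albumin must be below d_water")
  structure(list(d_water = d_water, d_albumin = d_albumin),
            class = "free_diffusion_constants")
}

#' Squared tortuosity of a medium
#'
#' Tortuosity relates a molecule's free diffusivity to its hindered tissue
#' ADC: `lambda^2 = D_free / ADC`. Values below 1 (tissue faster than free
#' solution) are physically implausible and trigger a warning, not an error.
#'
#' @param d_free Free diffusivity, mm^2/ms; positive.
#' @param adc Measured tissue ADC, mm^2/ms; positive.
#' @return The squared tortuosity, dimensionless.
#' @export
#' @examples
#' tortuosity_squared(3e-6, 6e-7)  # 5
tortuosity_squared <- function(d_free, adc) {
  if (any(d_free <= 0)) abort_input("d_free must be positive")
  if (any(adc <= 0)) abort_input("adc must be positive")
  l2 <- d_free / adc
  if (any(l2 < 1)) {
    warning("tortuosity^2 below 1: tissue ADC exceeds the free diffusivity",
            call. = FALSE)
  }
  l2
}

#' Predict the tracer's purely diffusive ADC from the water ADC
#'
#' Applies the tortuosity chain twice: the water ADC gives the tissue
#' tortuosity (`lambda^2 = D_water / ADC_water`), and assuming the tracer
#' experiences the same tortuosity its hindered ADC is
#' `D_albumin / lambda^2`. Algebraically this is multiplication by the
#' constant ratio `D_albumin / D_water` (about 0.0276), so the standard
#' error scales by the same factor. Assuming equal tortuosity is
#' conservative for bulk-flow detection: a larger (more realistic) tracer
#' tortuosity would only lower this prediction.
#'
#' @param adc_water A [diffusivity_estimate()] of the water ADC (or a single
#'   positive number).
#' @param constants A [free_diffusion_constants()].
#' @return A [diffusivity_estimate()] with `method = "dti_scaled"` (or a
#'   number when the input was a number).
#' @export
#' @examples
#' scale_to_tracer(6e-7)  # 1.658e-8 mm^2/ms
scale_to_tracer <- function(adc_water, constants = free_diffusion_constants()) {
  stopifnot(inherits(constants, "free_diffusion_constants"))
  factor <- constants$d_albumin / constants$d_water
  if (is.numeric(adc_water)) {
    if (any(adc_water <= 0)) abort_input("adc_water must be positive")
    return(adc_water * factor)
  }
  if (!inherits(adc_water, "diffusivity_estimate")) {
    abort_input("`adc_water` must be a diffusivity_estimate or numeric")
  }
  if (adc_water$value <= 0) abort_input("adc_water must be positive")
  diffusivity_estimate(adc_water$region, adc_water$value * factor,
                       adc_water$se * factor, method = "dti_scaled",
                       n = adc_water$n)
}
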