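#' Physical constants and thermal voltage helpers
#'
#' All temperature-dependent factors used in the package funnel through these
#' helpers so that the working temperature enters each computation exactly
#' once. The default temperature is 294 K (about 21 degrees C, the midpoint of
#' typical room-temperature patch-clamp conditions).
#'
#' @name hv1-constants
#' @keywords internal
NULL

## Gas constant, J mol^-1 K^-1
.R_J <- 8.314462618
## Gas constant, kcal mol^-1 K^-1
.R_KCAL <- 1.9872e-3
## Faraday constant, C mol^-1
.F_C <- 96485.33212

#' Default working temperature in kelvin
#' @export
hv1_default_temperature <- function() 294

#' Thermal voltage RT/F in millivolts
#'
#' @param T_K absolute temperature (K).
#' @return RT/F in mV (25.33 mV at 294 K).
#' @export
thermal_voltage <- function(T_K = hv1_default_temperature()) {
  stopifnot(is.numeric(T_K), T_K > 0)
  1000 * .R_J * T_K / .F_C
}

#' Nernstian slope ln(10)*RT/F in millivolts per pH unit
#'
#' @inheritParams thermal_voltage
#' @return ln(10)*RT/F in mV (58.33 mV at 294 K).
#' @export
nernst_slope <- function(T_K = hv1_default_temperature()) {
  log(10) * thermal_voltage(T_K)
}
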