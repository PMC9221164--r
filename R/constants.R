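#' Physical constants used throughout the package
#'
#' Returns the gas constant, Boltzmann constant and Planck constant at the
#' three-significant-figure precision conventional in enzyme-thermodynamics
#' tables (`R` = 8.314 J mol^-1 K^-1, `kB` = 1.38e-23 J K^-1,
#' `h` = 6.626e-34 J s). These deliberately are not full-precision CODATA
#' values: published activation/deactivation tables in this field are
#' computed with the rounded constants, and reproducing such tables to their
#' printed precision requires using the same values.
#'
#' @return A named list with elements `R`, `kB` and `h` (SI units).
#' @examples
#' physical_constants()$R
#' @export
physical_constants <- function() {
  list(R = 8.314, kB = 1.38e-23, h = 6.626e-34)
}

#' Convert temperatures between Celsius and Kelvin
#'
#' @param temp_c,temp_k Numeric vector of temperatures.
#' @param offset Kelvin offset, either `273` (the convention of most enzyme
#'   thermostability tables, where 40 degC is listed as 313 K) or `273.15`.
#'
#' @return Numeric vector of converted temperatures.
#' @examples
#' celsius_to_kelvin(40) # 313
#' @export
celsius_to_kelvin <- function(temp_c, offset = 273) {
  stopifnot(offset %in% c(273, 273.15))
  temp_c + offset
}

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_k, offset = 273) {
  stopifnot(offset %in% c(273, 273.15))
  temp_k - offset
}
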