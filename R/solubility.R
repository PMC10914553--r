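#' Equilibrium oxygen solubility of (sea)water
#'
#' Dissolved-oxygen concentration at 100% air saturation, from the
#' Benson & Krause (1984) fit as adopted by standard DO tables, with a
#' vapour-pressure-corrected barometric scaling. This is the conversion
#' behind "% air saturation" optode readouts: a reading of \code{p} percent
#' corresponds to \code{p/100 * o2_solubility(...)} mg O2 per litre.
#'
#' @param temperature water temperature, degrees C (0-40).
#' @param salinity practical salinity, ppt (0-40). Default 35 (seawater).
#' @param pressure barometric pressure, mbar (800-1100). Default 1013.25.
#' @return equilibrium O2 concentration, mg O2 L^-1, vectorised over
#'   `temperature`.
#' @details Strictly decreasing in both temperature and salinity over the
#'   supported domain. At 29.12 degC, 0 ppt, 1013 mbar the value is 7.67
#'   mg/L; at 0 degC, 0 ppt it is 14.62 mg/L.
#' @export
#' @examples
#' o2_solubility(27, 35)          # warm seawater, ~6.6 mg/L
#' o2_solubility(29.12, 0, 1013)  # freshwater convention, 7.67 mg/L
o2_solubility <- function(temperature, salinity = 35, pressure = 1013.25) {
  stopifnot(is.numeric(temperature), is.numeric(salinity), is.numeric(pressure))
  if (any(temperature < 0 | temperature > 40)) {
    stop("o2_solubility: temperature out of supported range [0, 40] degC",
         call. = FALSE)
  }
  if (any(salinity < 0 | salinity > 40)) {
    stop("o2_solubility: salinity out of supported range [0, 40] ppt",
         call. = FALSE)
  }
  if (any(pressure < 800 | pressure > 1100)) {
    stop("o2_solubility: pressure out of supported range [800, 1100] mbar",
         call. = FALSE)
  }
  tk <- temperature + 273.15
  ln_c <- -139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
    1.2438e10 / tk^3 - 8.621949e11 / tk^4 -
    salinity * (0.017674 - 10.754 / tk + 2140.7 / tk^2)
  c0 <- exp(ln_c)
  # barometric correction (vapour pressure u in mbar, theta dimensionless)
  u <- 1013.25 * exp(11.8571 - 3840.70 / tk - 216961 / tk^2)
  theta <- 0.000975 - 1.426e-5 * temperature + 6.436e-8 * temperature^2
  p_atm <- pressure / 1013.25
  c0 * p_atm * ((1 - u / pressure) * (1 - theta * p_atm)) /
    ((1 - u / 1013.25) * (1 - theta))
}

#' Convert between percent air saturation and mg O2 per litre
#'
#' @param airsat percent air saturation.
#' @param do_mgL dissolved oxygen, mg O2 L^-1.
#' @inheritParams o2_solubility
#' @return `airsat_to_mgL`: mg O2 L^-1; `mgL_to_airsat`: percent air
#'   saturation. The two are exact inverses at fixed temperature, salinity
#'   and pressure.
#' @export
airsat_to_mgL <- function(airsat, temperature, salinity = 35,
                          pressure = 1013.25) {
  airsat / 100 * o2_solubility(temperature, salinity, pressure)
}

#' @rdname airsat_to_mgL
#' @export
mgL_to_airsat <- function(do_mgL, temperature, salinity = 35,
                          pressure = 1013.25) {
  100 * do_mgL / o2_solubility(temperature, salinity, pressure)
}
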