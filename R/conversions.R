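#' Ethanol conversion settings
#'
#' Physical constants used by the ethanol gas/liquid conversions: molar mass
#' of ethanol, ideal-gas molar volume at the reference temperature, the
#' gas/liquid partition coefficient and the density of ethanol.
#'
#' @param molar_mass Molar mass of ethanol in g/mol.
#' @param molar_volume_ref Ideal-gas molar volume in L/mol at the reference
#'   temperature (25 degrees C).
#' @param reference_temp_K Reference temperature in kelvin.
#' @param partition_coeff_alpha Dimensionless gas/liquid partition coefficient
#'   (ratio of gas-phase to liquid-phase ethanol concentration at
#'   equilibrium).  Must lie in (0, 1].
#' @param density Density of ethanol in g/mL.
#' @return A list of class `ethanol_settings`.
#' @export
#' @examples
#' ethanol_settings()
ethanol_settings <- function(molar_mass = 46.07,
                             molar_volume_ref = 24.45,
                             reference_temp_K = 298.15,
                             partition_coeff_alpha = 2.5e-4,
                             density = 0.789) {
  s <- list(molar_mass = molar_mass, molar_volume_ref = molar_volume_ref,
            reference_temp_K = reference_temp_K,
            partition_coeff_alpha = partition_coeff_alpha, density = density)
  stopifnot(all(vapply(s, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                       logical(1))))
  if (partition_coeff_alpha > 1) {
    stop("partition_coeff_alpha must be <= 1")
  }
  structure(s, class = "ethanol_settings")
}

#' CO2 conversion settings
#'
#' Constants for carbon-dioxide gas/liquid conversions: Henry's-law constant
#' for CO2 in white wine, molar mass, the gas-phase ppm-to-g/L factor, and the
#' CO2 partial pressure.
#'
#' @param henry_constant Henry's-law constant in mol/(L atm) (CO2 in white
#'   wine at 20 degrees C).
#' @param molar_mass Molar mass of CO2 in g/mol.
#' @param air_factor Gas-phase conversion factor in g/L per ppm.
#' @param partial_pressure CO2 partial pressure in atm.
#' @return A list of class `co2_settings`.
#' @export
co2_settings <- function(henry_constant = 1.65e-2,
                         molar_mass = 44.01,
                         air_factor = 1.964e-6,
                         partial_pressure = 1) {
  s <- list(henry_constant = henry_constant, molar_mass = molar_mass,
            air_factor = air_factor, partial_pressure = partial_pressure)
  stopifnot(all(vapply(s, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                       logical(1))))
  structure(s, class = "co2_settings")
}

#' Baume to specific gravity
#'
#' Converts degrees Baume of a must (liquid heavier than water) to specific
#' gravity via SG = 145 / (145 - Baume).
#'
#' @param baume Degrees Baume, in \code{[0, 145)}.  Vectorised.
#' @return Specific gravity (dimensionless, >= 1).
#' @export
#' @examples
#' baume_to_sg(10)
baume_to_sg <- function(baume) {
  stopifnot(is.numeric(baume))
  if (any(baume < 0 | baume >= 145)) {
    stop("baume must lie in [0, 145)")
  }
  145 / (145 - baume)
}

#' Baume to sugar concentration
#'
#' Converts degrees Baume to fermentable sugar in g/L using the hydrometric
#' chain Brix = 1.8 Baume and sugar (g/L) = Brix x SG x 10.
#'
#' @inheritParams baume_to_sg
#' @return Sugar concentration in g/L.
#' @export
#' @examples
#' baume_to_sugar_gL(10)  # ~193.3 g/L
baume_to_sugar_gL <- function(baume) {
  brix <- 1.8 * baume
  brix * baume_to_sg(baume) * 10
}

#' Gas-phase CO2 ppm to g/L in air
#'
#' Linear conversion of a gas-phase CO2 concentration in ppm to mass
#' concentration in the gas phase (g/L).
#'
#' @param ppm Gas-phase CO2 concentration in ppm (>= 0).  Vectorised.
#' @param settings A [co2_settings()] object.
#' @return Mass concentration in g/L (gas phase).
#' @export
co2_ppm_to_air_gL <- function(ppm, settings = co2_settings()) {
  stopifnot(is.numeric(ppm))
  if (any(ppm < 0)) stop("ppm must be non-negative")
  ppm * settings$air_factor
}

#' Gas-phase CO2 ppm to dissolved g/L
#'
#' Converts a gas-phase CO2 concentration (ppm) to the equilibrium dissolved
#' concentration in the fermenting wine via Henry's law: the per-ppm factor is
#' kH x M x 1e-6, which equals 7.262e-7 g/L per ppm for the default constants.
#'
#' @inheritParams co2_ppm_to_air_gL
#' @return Dissolved CO2 concentration in g/L.
#' @export
co2_ppm_to_dissolved_gL <- function(ppm, settings = co2_settings()) {
  stopifnot(is.numeric(ppm))
  if (any(ppm < 0)) stop("ppm must be non-negative")
  ppm * settings$henry_constant * settings$partial_pressure *
    settings$molar_mass * 1e-6
}

#' Liquid/gas CO2 partition ratio
#'
#' Ratio of dissolved to gas-phase CO2 mass concentration at equilibrium;
#' approximately 0.37 with the default constants (the dissolved concentration
#' is about 37% of the gas-phase one).
#'
#' @param settings A [co2_settings()] object.
#' @return Dimensionless ratio.
#' @export
co2_partition_ratio <- function(settings = co2_settings()) {
  if (settings$air_factor == 0) stop("air_factor must be non-zero")
  (settings$henry_constant * settings$partial_pressure *
     settings$molar_mass * 1e-6) / settings$air_factor
}

#' Gas-phase ethanol ppm to liquid-equivalent mg/L
#'
#' Converts an ethanol vapour concentration (ppm in the tank head space) to a
#' liquid-equivalent mass concentration in mg/L: ppm x M / Vm(T) x (1/alpha),
#' where the molar volume is corrected for temperature as
#' Vm(T) = Vm_ref x T_K / T_ref.
#'
#' Note that with the default partition coefficient alpha = 2.5e-4 the
#' formula's output is orders of magnitude larger than head-space trace
#' readings would suggest for a liquid-phase concentration; alpha is exposed
#' as a setting precisely because the calibration of this correction is
#' device-specific.
#'
#' @param ppm Gas-phase ethanol concentration in ppm (>= 0).  Vectorised.
#' @param temp_C Gas temperature in degrees C (> -273.15).
#' @param settings An [ethanol_settings()] object.
#' @return Liquid-equivalent ethanol concentration in mg/L.
#' @export
ethanol_ppm_to_mgL <- function(ppm, temp_C = 25, settings = ethanol_settings()) {
  stopifnot(is.numeric(ppm), is.numeric(temp_C))
  if (any(ppm < 0)) stop("ppm must be non-negative")
  if (any(temp_C <= -273.15)) stop("temp_C must exceed absolute zero")
  if (settings$partition_coeff_alpha == 0) stop("alpha must be non-zero")
  temp_K <- temp_C + 273.15
  vm <- settings$molar_volume_ref * temp_K / settings$reference_temp_K
  ppm * settings$molar_mass / vm / settings$partition_coeff_alpha
}

#' Ethanol g/L to percent alcohol by volume
#'
#' %vol = C / (rho x 1000) x 100 with rho the density of ethanol in g/mL.
#'
#' @param conc_gL Ethanol concentration in g/L (>= 0).  Vectorised.
#' @param settings An [ethanol_settings()] object.
#' @return Percent alcohol by volume.
#' @export
#' @examples
#' ethanol_gL_to_vol_percent(82.9)  # 10.5 %vol, dry wine minimum
ethanol_gL_to_vol_percent <- function(conc_gL, settings = ethanol_settings()) {
  stopifnot(is.numeric(conc_gL))
  if (any(conc_gL < 0)) stop("conc_gL must be non-negative")
  conc_gL / (settings$density * 1000) * 100
}
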