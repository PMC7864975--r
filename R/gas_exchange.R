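# Air-water CO2 exchange: solubility, chemical enhancement, and the
# conversion of pCO2 observations into daily areal C emission rates.

#' Gas-exchange parameter set
#'
#' Bundles the constants of the flux calculation: the gas transfer
#' coefficient, the CH4 share of total C emission, the atmospheric pCO2
#' used for the equilibrium concentration, and whether pH-dependent
#' chemical enhancement is applied.
#'
#' @param k Gas transfer (piston) velocity, m d-1. Default 4.464, the
#'   median floating-chamber value measured on the largest rivers of the
#'   region.
#' @param ch4_fraction Proportion of CH4 in total C emission, in `[0, 1)`.
#'   Default 0.0119 (1.19%), the median riverine share.
#' @param pco2_atm Atmospheric pCO2 in µatm used for the water-side
#'   equilibrium concentration. Default 390.
#' @param enhancement_enabled Apply the chemical enhancement factor
#'   (`TRUE`, default) or force `alpha = 1`.
#' @return List of class `"exchange_params"`.
#' @export
#' @examples
#' exchange_params()
exchange_params <- function(k = 4.464, ch4_fraction = 0.0119,
                            pco2_atm = 390, enhancement_enabled = TRUE) {
  check_number(k, "k", lower = 1e-12)
  check_number(ch4_fraction, "ch4_fraction", lower = 0)
  if (ch4_fraction >= 1) stop("'ch4_fraction' must be < 1", call. = FALSE)
  check_number(pco2_atm, "pco2_atm", lower = 0)
  structure(
    list(k = k, ch4_fraction = ch4_fraction, pco2_atm = pco2_atm,
         enhancement_enabled = isTRUE(enhancement_enabled)),
    class = "exchange_params"
  )
}

#' CO2 solubility in fresh water
#'
#' Henry's-law solubility of CO2 at zero salinity as a function of water
#' temperature, from the standard temperature polynomial for gas
#' solubility in natural waters (fitted ln K0 in mol L-1 atm-1). The
#' coefficients are cross-checked against tabulated freshwater CO2
#' solubilities in the test suite.
#'
#' @param temp_c Water temperature, degrees Celsius, in `[-1, 40]`.
#' @return Solubility in mol L-1 atm-1 (vectorized).
#' @export
#' @examples
#' co2_solubility(c(0, 10, 25))
co2_solubility <- function(temp_c) {
  if (any(!is.finite(temp_c))) {
    stop("temperature must be finite", call. = FALSE)
  }
  if (any(temp_c < -1 | temp_c > 40)) {
    stop("temperature outside the physical range [-1, 40] degC",
         call. = FALSE)
  }
  tk <- temp_c + 273.15
  exp(-58.0931 + 90.5069 * (100 / tk) + 22.2940 * log(tk / 100))
}

#' Dissolved CO2 concentration from partial pressure
#'
#' Converts a pCO2 in µatm to a molar concentration via Henry's law.
#' The 1e-6 µatm-to-atm factor and the mol L-1 to mmol m-3 conversion
#' cancel, so concentration in mmol m-3 equals solubility times pCO2
#' in µatm.
#'
#' @param pco2_uatm Partial pressure of CO2 in water, µatm (>= 0).
#' @param temp_c Water temperature, degrees Celsius.
#' @return Concentration in mmol m-3 (vectorized).
#' @export
#' @examples
#' dissolved_co2(390, 10) # ~20.9 mmol m-3
dissolved_co2 <- function(pco2_uatm, temp_c) {
  if (any(pco2_uatm < 0, na.rm = TRUE)) {
    stop("pCO2 must be non-negative", call. = FALSE)
  }
  co2_solubility(temp_c) * pco2_uatm
}

# freshwater carbonate-system constants used by the enhancement model;
# temperature in Kelvin throughout
.carbonate_constants <- function(temp_c) {
  tk <- temp_c + 273.15
  list(
    # first and second dissociation constants of carbonic acid (freshwater)
    K1 = 10^-(-126.34048 + 6320.813 / tk + 19.568224 * log(tk)),
    K2 = 10^-(-90.18333 + 5143.692 / tk + 14.613358 * log(tk)),
    # ion product of water
    Kw = 10^-(4470.99 / tk - 6.0875 + 0.01706 * tk),
    # CO2 + H2O hydration rate constant, s-1
    k_hyd = exp(1246.98 - 6.19e4 / tk - 183.0 * log(tk)),
    # CO2 + OH- rate constant, M-1 s-1
    k_oh = 8500,
    # molecular diffusivity of CO2 in water, m2 s-1
    D = 1.81e-2 * exp(-16900 / (8.314 * tk)) * 1e-4
  )
}

#' Chemical enhancement factor of CO2 exchange
#'
#' Enhancement of CO2 gas exchange over pure diffusion caused by CO2
#' hydration reactions inside the diffusive boundary layer, from the
#' classical stagnant-film solution: with film thickness `z = D/k`,
#' reaction-diffusion length ratio `Q = z * sqrt(r/D)` (r the pH-dependent
#' pseudo-first-order hydration rate) and buffering capacity
#' `tau = 1 + K1/[H+] + K1*K2/[H+]^2`,
#' `alpha = tau / (1 + (tau - 1) * tanh(Q)/Q)`.
#' The factor tends to 1 in acidic water and for large transfer
#' velocities, and is capped by `tau` for a slow (thick-film) exchange.
#'
#' @param ph Water pH; must be below 8 (callers truncate, as emission
#'   computations are restricted to pH < 8).
#' @param temp_c Water temperature, degrees Celsius.
#' @param k Gas transfer velocity, m d-1.
#' @return Dimensionless enhancement factor `alpha >= 1` (vectorized).
#' @export
#' @examples
#' enhancement_factor(7.5, 15, 4.464)
enhancement_factor <- function(ph, temp_c, k) {
  if (any(!is.finite(ph)) || any(ph <= 0) || any(ph >= 14)) {
    stop("pH must lie in (0, 14)", call. = FALSE)
  }
  if (any(ph >= 8)) {
    stop("pH >= 8 supplied; truncate pH below 8 before computing fluxes",
         call. = FALSE)
  }
  check_number(k[1], "k", lower = 1e-12)
  cc <- .carbonate_constants(temp_c)
  h <- 10^-ph
  tau <- 1 + cc$K1 / h + cc$K1 * cc$K2 / h^2
  r <- cc$k_hyd + cc$k_oh * cc$Kw / h
  k_ms <- k / 86400
  q <- sqrt(r * cc$D) / k_ms
  # tanh(q)/q -> 1 as q -> 0; guard the limit explicitly
  tq <- ifelse(q < 1e-8, 1, tanh(q) / q)
  tau / (1 + (tau - 1) * tq)
}

#' Daily CO2 emission rate from a gas sample
#'
#' Areal CO2 evasion rate from the air-water concentration gradient:
#' `alpha * k * (C_water - C_equilibrium)`, with both concentrations from
#' [dissolved_co2()] at the sample temperature, converted to
#' g C m-2 d-1 with the molar mass of carbon.
#'
#' @param pco2_water pCO2 in the water, µatm.
#' @param temp_c Water temperature, degrees Celsius.
#' @param ph Water pH (< 8); used only when enhancement is enabled.
#' @param params [exchange_params()] list.
#' @return Emission rate in g C m-2 d-1; sign follows the concentration
#'   gradient (vectorized).
#' @export
#' @examples
#' co2_emission_rate(1546, 10, 7, exchange_params(enhancement_enabled = FALSE))
co2_emission_rate <- function(pco2_water, temp_c, ph = NULL,
                              params = exchange_params()) {
  stopifnot(inherits(params, "exchange_params"))
  if (is.null(temp_c)) {
    stop("water temperature is required to evaluate solubility",
         call. = FALSE)
  }
  alpha <- if (params$enhancement_enabled) {
    if (is.null(ph)) stop("pH is required when enhancement is enabled",
                          call. = FALSE)
    enhancement_factor(ph, temp_c, params$k)
  } else {
    1
  }
  grad_mmol <- dissolved_co2(pco2_water, temp_c) -
    dissolved_co2(params$pco2_atm, temp_c)
  alpha * params$k * grad_mmol * .C_MOLAR_MASS / 1000
}

#' Add the CH4 share to a CO2 emission rate
#'
#' Returns the total C emission rate such that CH4 constitutes exactly
#' `fraction` of the total: `total = co2_rate / (1 - fraction)`. Read as
#' a share of the total, not a markup.
#'
#' @param co2_rate CO2-only emission rate, g C m-2 d-1.
#' @param fraction CH4 proportion of total C emission, in `[0, 1)`.
#' @return Total C (CO2 + CH4) emission rate, g C m-2 d-1.
#' @export
#' @examples
#' add_ch4(5.60, 0.0119) # 5.667
add_ch4 <- function(co2_rate, fraction = 0.0119) {
  check_number(fraction, "fraction", lower = 0)
  if (fraction >= 1) stop("CH4 fraction must be < 1", call. = FALSE)
  co2_rate / (1 - fraction)
}

#' Open-water-season effective pCO2 from a summer value
#'
#' Summer transect pCO2 underestimates the spring freshet peak; spring
#' pCO2 is approximated as twice the summer value and the open-water
#' effective pCO2 as the average of the two, i.e. 1.5 x summer.
#'
#' @param summer_pco2 Summer pCO2, µatm (>= 0).
#' @return Effective open-water-season pCO2, µatm.
#' @export
#' @examples
#' spring_adjust(1546) # 2319
spring_adjust <- function(summer_pco2) {
  if (any(summer_pco2 < 0, na.rm = TRUE)) {
    stop("pCO2 must be non-negative", call. = FALSE)
  }
  (summer_pco2 + 2 * summer_pco2) / 2
}
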