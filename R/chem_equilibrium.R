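# Acid-base speciation of the NH_x pool and Henry's-law gas-water
# equilibrium. Concentrations are carried internally in molar; table I/O is
# in uM (waters) and mM (droplets). Activity coefficients default to 1
# (dilute approximation); an ionic-strength hook is exposed but off.

#' Physico-chemical constants for the NH3/NH4+ system
#'
#' Bundles the reference constants used by the speciation and Henry's-law
#' functions. Temperature dependence of both the acid dissociation constant
#' and the Henry constant is by the van't Hoff relation around 25 degC.
#'
#' @param pKa_ref acid dissociation constant of NH4+ at `temp_ref_C`
#'   (dimensionless, default 9.25).
#' @param dH_kJ_mol standard enthalpy of NH4+ dissociation in kJ/mol
#'   (default 52.21); set to 0 to disable the temperature correction.
#' @param kh_ref_M_atm Henry solubility of NH3 at `temp_ref_C` in M/atm
#'   (default 59).
#' @param kh_vant_hoff_K temperature coefficient -Delta_sol H / R of the
#'   Henry constant in kelvin (default 4200); 0 disables the correction.
#' @param temp_ref_C reference temperature in degrees Celsius (default 25).
#' @param gamma_nh4,gamma_nh3 activity coefficients for NH4+ and NH3(aq).
#'   Default 1 (concentration = activity); supply values from an external
#'   ionic-strength model to override.
#'
#' @return A list of class `nhx_constants`.
#' @export
#' @examples
#' nhx_constants()
#' nhx_constants(dH_kJ_mol = 0) # temperature-independent pKa
nhx_constants <- function(pKa_ref = 9.25, dH_kJ_mol = 52.21,
                          kh_ref_M_atm = 59, kh_vant_hoff_K = 4200,
                          temp_ref_C = 25,
                          gamma_nh4 = 1, gamma_nh3 = 1) {
  stopifnot(is.numeric(pKa_ref), is.numeric(dH_kJ_mol),
            kh_ref_M_atm > 0, is.numeric(kh_vant_hoff_K),
            gamma_nh4 > 0, gamma_nh3 > 0)
  structure(list(pKa_ref = pKa_ref, dH_kJ_mol = dH_kJ_mol,
                 kh_ref_M_atm = kh_ref_M_atm,
                 kh_vant_hoff_K = kh_vant_hoff_K,
                 temp_ref_C = temp_ref_C,
                 gamma_nh4 = gamma_nh4, gamma_nh3 = gamma_nh3),
            class = "nhx_constants")
}

# gas constant, J mol-1 K-1
.R_GAS <- 8.314462618

.check_temp <- function(temp_C) {
  if (any(!is.finite(temp_C)) || any(temp_C < 0) || any(temp_C > 50)) {
    stop("temp_C must be finite and within [0, 50] degC", call. = FALSE)
  }
}

#' Temperature-corrected pKa of ammonium
#'
#' van't Hoff correction of the NH4+ acid dissociation constant around the
#' reference value (9.25 at 25 degC):
#' `pKa(T) = pKa_ref + dH / (R ln 10) * (1/T - 1/T_ref)` with T in kelvin.
#' With the positive dissociation enthalpy the pKa decreases as temperature
#' increases, i.e. cold streams hold a smaller NH3(aq) fraction.
#'
#' @param temp_C temperature in degrees Celsius, within [0, 50].
#' @param constants an [nhx_constants()] list.
#' @return pKa at `temp_C` (dimensionless), vectorized over `temp_C`.
#' @export
#' @examples
#' pka_nh4(25) # 9.25
#' pka_nh4(13) # colder water, higher pKa
pka_nh4 <- function(temp_C, constants = nhx_constants()) {
  .check_temp(temp_C)
  T_K <- temp_C + 273.15
  Tref_K <- constants$temp_ref_C + 273.15
  constants$pKa_ref +
    constants$dH_kJ_mol * 1000 / (.R_GAS * log(10)) * (1 / T_K - 1 / Tref_K)
}

#' Henry solubility of ammonia
#'
#' Henry constant KH (M/atm) for NH3(aq) <-> NH3(g), with van't Hoff
#' temperature dependence
#' `KH(T) = KH_ref * exp(theta * (1/T - 1/T_ref))`, theta = -Delta_sol H / R.
#' NH3 is more soluble in cold water, so KH increases as temperature drops.
#'
#' @inheritParams pka_nh4
#' @return Henry constant in mol L-1 atm-1, vectorized over `temp_C`.
#' @export
#' @examples
#' henry_constant_nh3(25) # the reference value, 59 M/atm
#' henry_constant_nh3(13) # ~107 M/atm
henry_constant_nh3 <- function(temp_C, constants = nhx_constants()) {
  .check_temp(temp_C)
  T_K <- temp_C + 273.15
  Tref_K <- constants$temp_ref_C + 273.15
  constants$kh_ref_M_atm *
    exp(constants$kh_vant_hoff_K * (1 / T_K - 1 / Tref_K))
}

#' Speciate the NH_x pool between NH4+ and NH3(aq)
#'
#' Partitions total dissolved `NH_x = NH3 + NH4+` between its acid and base
#' forms at the given pH: `frac_NH3 = 1 / (1 + 10^(pKa - pH))` (activity
#' coefficients 1 by default). The pKa is temperature-corrected via
#' [pka_nh4()] unless an explicit `pKa` is supplied.
#'
#' @param nhx_uM total NH3 + NH4+ in micromolar (>= 0).
#' @param pH dimensionless, within [0, 14].
#' @param temp_C temperature in degrees Celsius (default 25).
#' @param pKa optional fixed pKa overriding the temperature correction.
#' @param constants an [nhx_constants()] list.
#' @return A data.frame with columns `frac_nh3`, `frac_nh4`, `nh3_aq_M`,
#'   `nh4_aq_M`, `pKa_used`, `temp_C`; one row per input (inputs are
#'   recycled to a common length).
#' @export
#' @examples
#' speciate_nhx(100, pH = 9.25, pKa = 9.25)$frac_nh3 # 0.5 at the pKa
#' speciate_nhx(80.7, pH = 7.10, temp_C = 13)        # stream conditions
speciate_nhx <- function(nhx_uM, pH, temp_C = 25, pKa = NULL,
                         constants = nhx_constants()) {
  if (any(!is.finite(nhx_uM)) || any(nhx_uM < 0)) {
    stop("nhx_uM must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(pH)) || any(pH < 0) || any(pH > 14)) {
    stop("pH must be finite and within [0, 14]", call. = FALSE)
  }
  pKa_used <- if (is.null(pKa)) pka_nh4(temp_C, constants) else pKa
  n <- max(length(nhx_uM), length(pH), length(pKa_used), length(temp_C))
  nhx_uM <- rep_len(nhx_uM, n); pH <- rep_len(pH, n)
  pKa_used <- rep_len(pKa_used, n); temp_C <- rep_len(temp_C, n)
  # ratio [NH3]/[NH4+] = gamma_nh4/gamma_nh3 * 10^(pH - pKa)
  ratio <- (constants$gamma_nh4 / constants$gamma_nh3) * 10^(pH - pKa_used)
  frac_nh3 <- ratio / (1 + ratio)
  total_M <- nhx_uM * 1e-6
  data.frame(frac_nh3 = frac_nh3, frac_nh4 = 1 - frac_nh3,
             nh3_aq_M = frac_nh3 * total_M,
             nh4_aq_M = (1 - frac_nh3) * total_M,
             pKa_used = pKa_used, temp_C = temp_C)
}

#' Equilibrium NH3(g) mixing ratio over a water sample
#'
#' Chains NH_x speciation and Henry's law to predict the NH3(g) mixing
#' ratio in equilibrium with a stream or pool:
#' `p_NH3 = [NH3(aq)] / KH(T)`, reported as ppbv
#' (mole fraction x 1e9) at 1 atm total pressure with fugacity
#' coefficient 1. Doubling NH_x at fixed pH and temperature doubles the
#' predicted ppbv.
#'
#' @param water a data.frame (or coercible list) with numeric columns
#'   `pH`, `temp_C` and `nhx_uM`; additional columns (e.g. `site_id`,
#'   `distance_m`) are carried through. Missing values in the three
#'   required fields raise an error naming the offending field.
#' @param constants an [nhx_constants()] list.
#' @return The input columns plus `frac_nh3`, `nh3_aq_M`, `kh_M_per_atm`,
#'   `partial_pressure_atm` and `nh3_ppbv`.
#' @export
#' @examples
#' equilibrium_nh3_gas(data.frame(pH = 7.10, temp_C = 13, nhx_uM = 80.7))
equilibrium_nh3_gas <- function(water, constants = nhx_constants()) {
  water <- as.data.frame(water)
  for (f in c("pH", "temp_C", "nhx_uM")) {
    if (is.null(water[[f]])) {
      stop(sprintf("water table lacks required field '%s'", f),
           call. = FALSE)
    }
    if (any(is.na(water[[f]]))) {
      stop(sprintf("missing value in required field '%s'", f),
           call. = FALSE)
    }
  }
  sp <- speciate_nhx(water$nhx_uM, water$pH, water$temp_C,
                     constants = constants)
  kh <- henry_constant_nh3(water$temp_C, constants)
  p_atm <- constants$gamma_nh3 * sp$nh3_aq_M / kh
  out <- water
  out$frac_nh3 <- sp$frac_nh3
  out$nh3_aq_M <- sp$nh3_aq_M
  out$kh_M_per_atm <- kh
  out$partial_pressure_atm <- p_atm
  out$nh3_ppbv <- p_atm * 1e9 # mole fraction x 1e9 at 1 atm total
  out
}
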