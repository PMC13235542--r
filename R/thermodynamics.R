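# Gibbs-energy favorability of ammonia oxidation at low pH, from
# standard-state formation energies (25 degC). Reactions are written and
# normalized per mole of N oxidized so the nitrite (AOA/AOB) and nitrate
# (comammox) pathways are directly comparable.

#' Standard Gibbs energies of formation for the ammonia-oxidation system
#'
#' Reads the formation-energy table shipped with the package
#' (`inst/extdata/gibbs_formation_energies.csv`): standard-state
#' delta-G of formation at 25 degC (kJ/mol) plus elemental composition and
#' charge for machine balance checks. Values are from the CODATA key-values
#' compilation and Stumm & Morgan (1996, Aquatic Chemistry); they are
#' internally consistent with the NH4+ pKa of 9.25 used elsewhere in the
#' package (delta-G of NH4+ -> NH3(aq) + H+ is 52.81 kJ/mol, i.e. pK 9.25).
#'
#' @param path optional path to an alternative table with the same columns.
#' @return A data.frame with columns `species`, `phase`, `dG0f_kJ_mol`,
#'   `N`, `H`, `O`, `charge`, `source`.
#' @export
formation_energies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gibbs_formation_energies.csv",
                        package = "nhxiso", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Define a stoichiometric reaction for Gibbs-energy calculations
#'
#' A reaction is a named numeric vector of signed coefficients (negative
#' for reactants, positive for products). On construction the reaction is
#' checked for element (N, H, O) and charge balance against the
#' formation-energy table, and its standard-state delta-G is pre-computed
#' as `sum(coef * dG0f)`.
#'
#' @param name reaction label.
#' @param stoichiometry named numeric vector of signed coefficients; every
#'   name must appear in `energies$species`.
#' @param energies a [formation_energies()] table.
#' @return A list of class `reaction_spec` with elements `name`,
#'   `stoichiometry`, `dG0_kJ_mol` and `energies`.
#' @export
#' @examples
#' reaction_spec("AOB", c("NH4+" = -1, "O2" = -1.5,
#'                        "NO2-" = 1, "H+" = 2, "H2O" = 1))
reaction_spec <- function(name, stoichiometry,
                          energies = formation_energies()) {
  if (is.null(names(stoichiometry)) || any(names(stoichiometry) == "")) {
    stop("stoichiometry must be a fully named numeric vector",
         call. = FALSE)
  }
  missing_sp <- setdiff(names(stoichiometry), energies$species)
  if (length(missing_sp) > 0) {
    stop("no formation energy for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  idx <- match(names(stoichiometry), energies$species)
  for (elem in c("N", "H", "O", "charge")) {
    bal <- sum(stoichiometry * energies[[elem]][idx])
    if (abs(bal) > 1e-9) {
      stop(sprintf("reaction '%s' is not balanced in %s (residual %.3g)",
                   name, elem, bal), call. = FALSE)
    }
  }
  dG0 <- sum(stoichiometry * energies$dG0f_kJ_mol[idx])
  structure(list(name = name, stoichiometry = stoichiometry,
                 dG0_kJ_mol = dG0, energies = energies),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  s <- x$stoichiometry
  lhs <- -s[s < 0]; rhs <- s[s > 0]
  fmt <- function(v) paste(ifelse(v == 1, names(v),
                                  paste(v, names(v))), collapse = " + ")
  cat(sprintf("<reaction_spec> %s: %s -> %s  (dG0 = %.2f kJ/mol)\n",
              x$name, fmt(lhs), fmt(rhs), x$dG0_kJ_mol))
  invisible(x)
}

#' Built-in ammonia-oxidation reactions
#'
#' Oxidation of ammonia to nitrite (the AOA/AOB pathway), complete
#' oxidation to nitrate (the comammox pathway), and the connecting
#' nitrite-to-nitrate step, each written per mole of N oxidized. The
#' nitrogen substrate can be written as NH4+ (the dominant species at the
#' relevant pH) or as NH3; [delta_g()] speciates the total pool so the two
#' forms give thermodynamically consistent results.
#'
#' @param form reactant species for the reduced-N substrate, `"NH4+"`
#'   (default) or `"NH3"`.
#' @param energies a [formation_energies()] table.
#' @return A [reaction_spec()].
#' @export
#' @examples
#' reaction_ammonia_to_nitrite()
#' reaction_ammonia_to_nitrate(form = "NH3")
reaction_ammonia_to_nitrite <- function(form = c("NH4+", "NH3"),
                                        energies = formation_energies()) {
  form <- match.arg(form)
  st <- if (form == "NH4+") {
    c("NH4+" = -1, "O2" = -1.5, "NO2-" = 1, "H+" = 2, "H2O" = 1)
  } else {
    c("NH3" = -1, "O2" = -1.5, "NO2-" = 1, "H+" = 1, "H2O" = 1)
  }
  reaction_spec(paste0("ammonia_to_nitrite[", form, "]"), st, energies)
}

#' @rdname reaction_ammonia_to_nitrite
#' @export
reaction_ammonia_to_nitrate <- function(form = c("NH4+", "NH3"),
                                        energies = formation_energies()) {
  form <- match.arg(form)
  st <- if (form == "NH4+") {
    c("NH4+" = -1, "O2" = -2, "NO3-" = 1, "H+" = 2, "H2O" = 1)
  } else {
    c("NH3" = -1, "O2" = -2, "NO3-" = 1, "H+" = 1, "H2O" = 1)
  }
  reaction_spec(paste0("ammonia_to_nitrate[", form, "]"), st, energies)
}

#' @rdname reaction_ammonia_to_nitrite
#' @export
reaction_nitrite_to_nitrate <- function(energies = formation_energies()) {
  reaction_spec("nitrite_to_nitrate",
                c("NO2-" = -1, "O2" = -0.5, "NO3-" = 1), energies)
}

#' Environmental conditions for Gibbs-energy calculations
#'
#' Conditions follow the air-referenced convention: dissolved O2 enters
#' the reaction quotient as the gas-phase partial pressure (fugacity 1),
#' water activity is 1, and the oxidized products are held at trace
#' activities typical of an environment with no measurable nitrite or
#' nitrate.
#'
#' @param pH dimensionless, in [0, 14].
#' @param nh4_total_M total NH3 + NH4+ in molar (> 0); speciated at `pH`
#'   before entering the quotient.
#' @param temp_C temperature in degC (default 25).
#' @param pO2_atm oxygen partial pressure in atm (default 0.209), in (0, 1].
#' @param activity_no2,activity_no3 product activities (default 1e-12).
#' @return A list of class `thermo_conditions`.
#' @export
thermo_conditions <- function(pH, nh4_total_M, temp_C = 25,
                              pO2_atm = 0.209,
                              activity_no2 = 1e-12, activity_no3 = 1e-12) {
  if (any(pH < 0) || any(pH > 14)) stop("pH must lie in [0, 14]",
                                        call. = FALSE)
  if (any(nh4_total_M <= 0)) stop("nh4_total_M must be positive",
                                  call. = FALSE)
  if (pO2_atm <= 0 || pO2_atm > 1) stop("pO2_atm must lie in (0, 1]",
                                        call. = FALSE)
  if (activity_no2 <= 0 || activity_no3 <= 0) {
    stop("product activities must be positive", call. = FALSE)
  }
  structure(list(pH = pH, nh4_total_M = nh4_total_M, temp_C = temp_C,
                 pO2_atm = pO2_atm, activity_no2 = activity_no2,
                 activity_no3 = activity_no3),
            class = "thermo_conditions")
}

#' Gibbs energy of a reaction under in-situ conditions
#'
#' `dG = dG0 + RT ln Q`, with the reaction quotient Q assembled from
#' species activities: H+ from pH, O2 from its partial pressure, H2O at
#' unit activity, NO2-/NO3- at the configured trace activities, and the
#' reduced-N substrate (NH4+ or NH3, matching the reaction's
#' stoichiometry) at the concentration obtained by speciating the total
#' NH_x pool at the given pH via [speciate_nhx()].
#'
#' @param reaction a [reaction_spec()].
#' @param cond a [thermo_conditions()] list; `pH` and `nh4_total_M` must be
#'   scalar here (use [delta_g_grid()] to sweep them).
#' @param activities optional named vector of activity overrides applied
#'   after the defaults (useful for sensitivity tests).
#' @param constants an [nhx_constants()] list for the speciation step.
#' @return Gibbs energy in kJ per mole of N oxidized.
#' @export
#' @examples
#' cond <- thermo_conditions(pH = 1, nh4_total_M = 2e-3)
#' delta_g(reaction_ammonia_to_nitrite(), cond) # strongly negative
delta_g <- function(reaction, cond, activities = NULL,
                    constants = nhx_constants()) {
  stopifnot(inherits(reaction, "reaction_spec"),
            inherits(cond, "thermo_conditions"),
            length(cond$pH) == 1, length(cond$nh4_total_M) == 1)
  sp <- speciate_nhx(cond$nh4_total_M * 1e6, cond$pH, cond$temp_C,
                     constants = constants)
  act <- c("H+" = 10^(-cond$pH), "O2" = cond$pO2_atm, "H2O" = 1,
           "NO2-" = cond$activity_no2, "NO3-" = cond$activity_no3,
           "NH4+" = sp$nh4_aq_M * constants$gamma_nh4,
           "NH3" = sp$nh3_aq_M * constants$gamma_nh3)
  if (!is.null(activities)) act[names(activities)] <- activities
  need <- names(reaction$stoichiometry)
  if (any(!is.finite(act[need])) || any(act[need] <= 0)) {
    stop("all species activities must be positive and finite",
         call. = FALSE)
  }
  RT <- 8.314462618e-3 * (cond$temp_C + 273.15) # kJ/mol
  lnQ <- sum(reaction$stoichiometry * log(act[need]))
  reaction$dG0_kJ_mol + RT * lnQ
}

#' Gibbs-energy grid over pH and total ammonium
#'
#' Evaluates [delta_g()] on the outer product of a pH axis and an NH_x
#' concentration axis, the favorability map for ammonia oxidation across
#' the cave's chemical gradient (circumneutral streams to pH < 1
#' droplets).
#'
#' @param reaction a [reaction_spec()].
#' @param pH_values numeric vector of pH values (non-empty).
#' @param nh4_values numeric vector of total NH_x concentrations in molar
#'   (non-empty).
#' @param cond a [thermo_conditions()] list providing the remaining
#'   conditions (its `pH` and `nh4_total_M` are ignored).
#' @param constants an [nhx_constants()] list.
#' @return A matrix of kJ/mol with `length(pH_values)` rows and
#'   `length(nh4_values)` columns, dimnames set to the axis values.
#' @export
delta_g_grid <- function(reaction, pH_values, nh4_values,
                         cond = thermo_conditions(pH = 7,
                                                  nh4_total_M = 1e-4),
                         constants = nhx_constants()) {
  if (length(pH_values) == 0 || length(nh4_values) == 0) {
    stop("pH_values and nh4_values must be non-empty", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = length(pH_values),
                ncol = length(nh4_values),
                dimnames = list(pH = signif(pH_values, 6),
                                nh4_M = signif(nh4_values, 6)))
  for (i in seq_along(pH_values)) {
    for (j in seq_along(nh4_values)) {
      cij <- cond
      cij$pH <- pH_values[i]
      cij$nh4_total_M <- nh4_values[j]
      out[i, j] <- delta_g(reaction, cij, constants = constants)
    }
  }
  out
}
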