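# delta-15N arithmetic: equilibrium fractionation chain for volatilization
# and acid trapping, Rayleigh reservoir evolution, two-endmember mixing,
# and total-reduced-N isotope mass balance.
#
# Sign convention (used everywhere): epsilon = (alpha - 1) * 1000 with
# alpha = R_substrate / R_product, so positive epsilon means the product is
# DEPLETED in 15N relative to the substrate.

#' Enrichment factors for the volatilization-trapping chain
#'
#' The chain has four steps: (a) NH4+ <-> NH3(aq) equilibrium in the
#' stream, (b) NH3(aq) <-> NH3(g) exchange across the air-water interface,
#' (c) optional fractionation during transport in cave air, and (d)
#' trapping of NH3(g) as NH4+ in acidic droplets. The default equilibrium
#' effect for step (a) is 30 permil at 25 degC; the alternative literature
#' value of 32 permil can be selected instead (`eps_eq = 32`) -- the two
#' conventions are surfaced side by side rather than silently merged.
#' Near-quantitative acid trapping carries no fractionation (step d,
#' 0 permil); step (c) has no established magnitude and defaults to 0.
#'
#' @param eps_eq permil enrichment of NH4+ over NH3(aq) (default 30).
#' @param eps_gas permil enrichment of NH3(aq) over NH3(g) (default 8.3).
#' @param eps_transport permil, optional transport effect (default 0).
#' @param eps_trap permil, trapping effect (default 0, near-quantitative).
#' @param mode `"linear"` (delta - eps, the convention of back-of-envelope
#'   isotope arithmetic) or `"exact"` (alpha form); see
#'   [apply_fractionation()].
#' @return A list of class `fractionation_set`.
#' @export
#' @examples
#' fractionation_set()              # 30 + 8.3 + 0 = 38.3 permil total
#' fractionation_set(eps_eq = 32)   # the alternative 32 permil convention
fractionation_set <- function(eps_eq = 30, eps_gas = 8.3,
                              eps_transport = 0, eps_trap = 0,
                              mode = c("linear", "exact")) {
  mode <- match.arg(mode)
  eps <- c(eps_eq, eps_gas, eps_transport, eps_trap)
  if (any(!is.finite(eps))) stop("all epsilon values must be finite",
                                 call. = FALSE)
  structure(list(eps_eq = eps_eq, eps_gas = eps_gas,
                 eps_transport = eps_transport, eps_trap = eps_trap,
                 mode = mode),
            class = "fractionation_set")
}

#' Apply an equilibrium enrichment factor to a substrate delta value
#'
#' Computes the product delta-15N from the substrate delta-15N and an
#' enrichment factor epsilon. `"linear"` mode uses the first-order
#' approximation `delta_product = delta_substrate - eps`; `"exact"` mode
#' uses `delta_product = (delta_substrate + 1000) / alpha - 1000` with
#' `alpha = 1 + eps / 1000`. The two agree to first order (the difference
#' is O(eps^2 / 1000) permil). Positive epsilon depletes the product.
#'
#' @param delta_substrate_permil substrate delta-15N in permil vs air N2.
#' @param eps_permil enrichment factor in permil.
#' @param mode `"linear"` or `"exact"`.
#' @return Product delta-15N in permil; vectorized.
#' @export
#' @examples
#' apply_fractionation(3.3, 30)                  # -26.7
#' apply_fractionation(3.3, 30, mode = "exact")  # approx -25.9
apply_fractionation <- function(delta_substrate_permil, eps_permil,
                                mode = c("linear", "exact")) {
  mode <- match.arg(mode)
  if (any(!is.finite(delta_substrate_permil)) ||
      any(!is.finite(eps_permil))) {
    stop("delta and epsilon must be finite", call. = FALSE)
  }
  if (mode == "linear") {
    delta_substrate_permil - eps_permil
  } else {
    alpha <- 1 + eps_permil / 1000
    if (any(alpha <= 0)) {
      stop("alpha = 1 + eps/1000 must be positive", call. = FALSE)
    }
    (delta_substrate_permil + 1000) / alpha - 1000
  }
}

#' delta-15N along the volatilization and trapping chain
#'
#' Applies the enrichment factors of a [fractionation_set()] sequentially
#' in the physical order stream NH4+ -> NH3(aq) -> NH3(g) ->
#' transported NH3(g) -> acid-trapped NH4+. In linear mode the total
#' depletion is simply the sum of the epsilons (38.3 permil with the
#' defaults); in exact mode the steps do not commute, which is why the
#' physical order is fixed here.
#'
#' @param delta_stream_nh4_permil delta-15N of stream NH4+ in permil.
#' @param fs a [fractionation_set()].
#' @return A data.frame with one row per pool: `step`, `species`,
#'   `eps_applied_permil` and `d15N_permil`.
#' @export
#' @examples
#' volatilization_chain(3.3, fractionation_set())
volatilization_chain <- function(delta_stream_nh4_permil,
                                 fs = fractionation_set()) {
  stopifnot(inherits(fs, "fractionation_set"),
            length(delta_stream_nh4_permil) == 1,
            is.finite(delta_stream_nh4_permil))
  eps_steps <- c(0, fs$eps_eq, fs$eps_gas, fs$eps_transport, fs$eps_trap)
  species <- c("NH4+ (stream)", "NH3(aq)", "NH3(g)",
               "NH3(g) transported", "NH4+ (trapped)")
  d <- delta_stream_nh4_permil
  deltas <- numeric(length(species))
  for (i in seq_along(species)) {
    d <- apply_fractionation(d, eps_steps[i], mode = fs$mode)
    deltas[i] <- d
  }
  data.frame(step = c("input", "a", "b", "c", "d"), species = species,
             eps_applied_permil = eps_steps, d15N_permil = deltas)
}

#' Rayleigh evolution of the residual NH_x reservoir
#'
#' delta-15N of the dissolved pool after a fraction `1 - f_remaining` of it
#' has been removed as isotopically light gas, in the linear Rayleigh
#' convention `delta = delta0 - eps_net * ln(f)`. With the 38.3 permil net
#' effect, removing 1% of the pool shifts the reservoir by under 0.4
#' permil -- degassing does not appreciably evolve a large stream
#' reservoir over a short flow path.
#'
#' @param delta0_permil initial reservoir delta-15N in permil.
#' @param eps_net_permil net enrichment factor of removal in permil.
#' @param f_remaining fraction of the reservoir remaining, in (0, 1].
#' @return Reservoir delta-15N in permil; vectorized over `f_remaining`.
#' @export
#' @examples
#' rayleigh_remaining(3.3, 38.3, 0.99)
rayleigh_remaining <- function(delta0_permil, eps_net_permil, f_remaining) {
  if (any(!is.finite(f_remaining)) || any(f_remaining <= 0) ||
      any(f_remaining > 1)) {
    stop("f_remaining must lie in (0, 1]", call. = FALSE)
  }
  delta0_permil - eps_net_permil * log(f_remaining)
}

#' Two-endmember mixing fraction from delta-15N
#'
#' Inverts linear conservative mixing between endmembers A and B:
#' `f_A = (delta_sample - delta_B) / (delta_A - delta_B)`. Samples whose
#' delta lies outside the endmember interval yield fractions outside
#' [0, 1]; these are returned as-is and flagged (`in_hull = FALSE`) rather
#' than clamped, so observations inconsistent with a two-endmember model
#' stay visible.
#'
#' @param delta_sample_permil sample delta-15N in permil; vectorized.
#' @param delta_end_A_permil,delta_end_B_permil endmember delta-15N values;
#'   must differ by more than 1e-9 permil.
#' @return A data.frame with columns `f_A` and `in_hull`.
#' @export
#' @examples
#' mixing_fraction(-10, -27.3, 15)
mixing_fraction <- function(delta_sample_permil, delta_end_A_permil,
                            delta_end_B_permil) {
  if (abs(delta_end_A_permil - delta_end_B_permil) <= 1e-9) {
    stop("degenerate endmembers: delta_A and delta_B coincide",
         call. = FALSE)
  }
  f <- (delta_sample_permil - delta_end_B_permil) /
    (delta_end_A_permil - delta_end_B_permil)
  data.frame(f_A = f, in_hull = f >= 0 & f <= 1)
}

#' Forward two-endmember mixing
#'
#' The forward counterpart of [mixing_fraction()]:
#' `delta = f_A * delta_A + (1 - f_A) * delta_B`.
#'
#' @param f_A fraction of endmember A; vectorized.
#' @inheritParams mixing_fraction
#' @return Mixture delta-15N in permil.
#' @export
mix_deltas <- function(f_A, delta_end_A_permil, delta_end_B_permil) {
  f_A * delta_end_A_permil + (1 - f_A) * delta_end_B_permil
}

#' delta-15N of total reduced nitrogen by isotope mass balance
#'
#' Where nitrate co-occurs with reduced N, the delta-15N of the total
#' reduced pool (TRN = NH4+ + DON) is obtained by subtracting the nitrate
#' contribution from the total dissolved N pool:
#' `delta_TRN = (delta_TDN * c_TDN - delta_NO3 * c_NO3) / (c_TDN - c_NO3)`.
#'
#' @param d15N_TDN_permil delta-15N of total dissolved N in permil.
#' @param c_TDN_uM total dissolved N concentration in micromolar.
#' @param d15N_NO3_permil delta-15N of nitrate in permil.
#' @param c_NO3_uM nitrate concentration in micromolar; must satisfy
#'   `0 <= c_NO3_uM < c_TDN_uM`.
#' @return delta-15N of the reduced pool in permil; vectorized.
#' @export
#' @examples
#' trn_mass_balance(2, 100, 8, 25) # 0
trn_mass_balance <- function(d15N_TDN_permil, c_TDN_uM,
                             d15N_NO3_permil, c_NO3_uM) {
  if (any(c_TDN_uM < 0) || any(c_NO3_uM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(c_NO3_uM >= c_TDN_uM)) {
    stop("infeasible balance: c_NO3 must be smaller than c_TDN",
         call. = FALSE)
  }
  (d15N_TDN_permil * c_TDN_uM - d15N_NO3_permil * c_NO3_uM) /
    (c_TDN_uM - c_NO3_uM)
}
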