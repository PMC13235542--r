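# Independent brute-force oracles: every formula is written out from first
# principles with plain arithmetic, never by calling the package's own
# implementation. Tests compare package output against these.

.o_R <- 8.314462618 # J mol-1 K-1

oracle_pka <- function(temp_C, pKa_ref = 9.25, dH_kJ = 52.21,
                       tref_C = 25) {
  pKa_ref + (dH_kJ * 1000) / (.o_R * log(10)) *
    (1 / (temp_C + 273.15) - 1 / (tref_C + 273.15))
}

oracle_frac_nh3 <- function(pH, pKa) 1 / (1 + 10^(pKa - pH))

oracle_kh <- function(temp_C, ref = 59, theta = 4200, tref_C = 25) {
  ref * exp(theta * (1 / (temp_C + 273.15) - 1 / (tref_C + 273.15)))
}

# full chained hand evaluation: speciation -> Henry -> ppbv at 1 atm
oracle_ppbv <- function(nhx_uM, pH, temp_C) {
  frac <- oracle_frac_nh3(pH, oracle_pka(temp_C))
  nh3_M <- frac * nhx_uM * 1e-6
  (nh3_M / oracle_kh(temp_C)) * 1e9
}

oracle_frac_linear <- function(delta, eps) delta - eps
oracle_frac_exact <- function(delta, eps) {
  (delta + 1000) / (1 + eps / 1000) - 1000
}

oracle_rayleigh <- function(delta0, eps, f) delta0 - eps * log(f)

oracle_mixing_f <- function(ds, da, db) (ds - db) / (da - db)

oracle_trn <- function(d_tdn, c_tdn, d_no3, c_no3) {
  (d_tdn * c_tdn - d_no3 * c_no3) / (c_tdn - c_no3)
}

# stoichiometric hand-sum of a standard-state reaction energy
oracle_dg0 <- function(stoich, table) {
  sum(vapply(names(stoich), function(sp) {
    stoich[[sp]] * table$dG0f_kJ_mol[table$species == sp]
  }, numeric(1)))
}
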