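# Analysis configuration template. Every key is optional; omitted keys
# keep the documented package defaults. Units: delta values in permil vs
# air N2, concentrations molar unless suffixed, temperatures degC.
constants:
  pKa_ref: 9.25          # NH4+ acid dissociation constant at 25 degC
  dH_kJ_mol: 52.21       # dissociation enthalpy (van't Hoff slope)
  kh_ref_M_atm: 59       # NH3 Henry solubility at 25 degC
  kh_vant_hoff_K: 4200   # -Delta_sol H / R for the Henry constant
  temp_ref_C: 25
fractionation:
  eps_eq: 30             # NH4+ / NH3(aq) equilibrium effect, permil
  eps_gas: 8.3           # NH3(aq) / NH3(g) air-water effect, permil
  eps_transport: 0       # optional transport effect (no established value)
  eps_trap: 0            # near-quantitative acid trapping
  mode: linear           # linear (delta - eps) or exact (alpha form)
stream_air_endmember: sampler   # sampler (-27.3), droplet (-29.0), or a number
surface_endmember: 15.0
distance_bins_m: [1.5, 7.5, 12.5, 27.5]
thermo_pH_range: [0.0, 7.0]
thermo_pH_n: 15
thermo_nh4_range_M: [1.0e-6, 1.0e-2]
thermo_nh4_n: 15
thermo_conditions:
  temp_C: 25
  pO2_atm: 0.209
  activity_no2: 1.0e-12
  activity_no3: 1.0e-12
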