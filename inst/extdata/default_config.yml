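# peatthaw default run configuration.
# Provenance tags: [reported]  = value printed in the source syntheses;
#                  [derived]   = computed from reported values;
#                  [calibrated]= generator/default chosen once so the
#                                shipped defaults reproduce reported
#                                regional quantities;
#                  [placeholder] = typical value, source table unprinted.
synth:
  nrow: 500                  # [calibrated] 10-km cells, 25 Mkm2 domain
  ncol: 500
  cell_area: 100             # km2
  maat_range: [-25.0, 10.0]  # [calibrated] spans the region's climate space
  maat_noise_sd: 2.0
  depth_mean: 249            # [reported] mean peat depth, cm
  depth_sd: 97               # [reported]
  depth_floor: 40            # [reported] organic-depth threshold, cm
  peat_scale: 0.31           # [calibrated] -> peat area ~3.7 Mkm2
  peat_maat_peak: -3.0       # [calibrated] boreal peat maximum
  peat_maat_width: 7.0
  peat_noise_sdlog: 0.6
  peat_min_fraction: 0.01
  pf_noise_sd: 0.05
  bd_median: 0.09            # [calibrated] g/cm3; core storage mean ~106
  bd_sdlog: 0.35
  oc_mean: 45                # [placeholder] typical peat OC weight %
  oc_sd: 10
  n_mean: 1.5                # [placeholder] typical peat N weight %
  n_sd: 0.8
  tundra_maat: -8            # [placeholder] biome cutoffs, degrees C
  boreal_maat: 2
stocks:
  slope_c: 0.46184739        # [derived] 115/249 kg C m-2 per cm
  intercept_c: 0.0
  slope_n_free: 0.00664336   # [derived] 1.9/286
  intercept_n_free: 0.0
  slope_n_perm: 0.02048780   # [derived] 4.2/205
  intercept_n_perm: 0.0
  tropical_pg: 105           # [reported] tropical peatland C, Pg
  southern_pg: 15            # [reported] southern-hemisphere peatland C, Pg
curve:
  central: {mu: 1.95, sigma: 7.35, f_max: 0.92}  # [reported]
  upper:   {mu: 0.70, sigma: 6.10, f_max: 0.96}  # [reported]
  lower:   {mu: 3.10, sigma: 4.50, f_max: 0.86}  # [reported]
  cap_maat: 1.0              # [reported] no permafrost above ~+1 C MAAT
  amplification: 2.0         # [placeholder] uniform polar amplification
  warming_levels: [0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0]
fluxes:
  accumulation: {k: 65, r: 0.25, m: -4}  # [calibrated] regional mean ~34 g C m-2 y-1
  # stage flux table, g C (or g N) m-2 y-1; positive = emission
  # [calibrated] CH4 entries -> regional source ~0.026 Pg C y-1;
  # N2O/lateral -> ~0.022 Tg N, 0.022 Pg C, 0.7 Tg N per year
  biome_type_shares:         # [placeholder] minerotrophic share per biome
    tundra: 0.70
    boreal: 0.55
    other: 0.50
thaw:
  ald_duration: 50           # [reported] mean active-layer-deepening, y
  ald_range: [25, 75]        # [reported]
  tk_duration: 100           # [reported] mean thermokarst maturation, y
  tk_range: [50, 150]        # [reported]
  ald_rate: 1                # [reported] cm/y
  loss_a: 1.1451             # [reported] chronosequence loss coefficient
  loss_b: -0.0771            # [reported] chronosequence loss exponent
  loss_horizon: 100          # [reported] y
  eligible_fraction: 0.18    # [calibrated] reconciles the power law with
                             # landscape-mean losses of 11-18 kg C m-2
  tk_fraction: 0.5           # [placeholder] thermokarst-pathway share
  n2o_c_ratio: 0.001         # [placeholder] g N2O-N per g CO2-C in ALD
  co2_route_fraction: 0.0    # lateral routing of chronosequence losses
  horizon: 400
forcing:
  # [placeholder] AR5 impulse-response parameterization
  co2_amps: [0.2173, 0.2240, 0.2824, 0.2763]
  co2_taus: [.inf, 394.4, 36.54, 4.304]
  ch4_tau: 12.4
  n2o_tau: 121
  eff_co2: 1.37e-5           # W m-2 ppb-1
  eff_ch4: 3.63e-4
  eff_n2o: 3.00e-3
  ch4_indirect: 1.65
  pgc_per_ppm_co2: 2.124
  tg_per_ppb_ch4: 2.75
  tg_per_ppb_n2o: 4.81
  horizon: 1000
seeds:
  landscape: 1
  cores: 1
  scenario: 1
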