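# Model configuration: physical constants, default perfusate, water
# permeabilities, paracellular scale, and the kinetic constants of the
# Na+/K+-ATPase and NKCC submodels. The three scale constants k_pump,
# k_nkcc and P_pa were calibrated once against the published steady-state
# driving forces of the fitted non-CF cell (see the methods vignette) and
# are frozen here.
constants:
  F: 96485          # C/mol
  R: 8.314          # J/(mol K)
  T: 310            # K
  C_m: 1            # uF/cm^2
bath:
  lumen:  {Na: 140, K: 5.3, Cl: 120, impermeant: 25}   # mM
  serosa: {Na: 140, K: 5.3, Cl: 120, impermeant: 25}
water:
  P_w_ap: 3.0       # cm^4 mol^-1 s^-1
  P_w_bl: 3.0
paracellular:
  P_pa: 0.05399     # um/s, permeability scale (calibrated)
  selectivity: {Na: 1.0, K: 1.0, Cl: 0.026}  # calibrated: anion-poor junction
  cation_selective_Cl_ratio: 0.5   # extra Cl- multiplier in the selective variant
pump:
  k_pump: 390.235   # s^-1 per site (calibrated)
  K_mNa: 40.0       # mM, intracellular Na half-saturation (calibrated)
  K_mK: 1.4         # mM, serosal K half-saturation
nkcc:
  k_nkcc: 78.812    # s^-1 per site (calibrated)
  K_Na: 50.0        # mM
  K_K: 8.0          # mM
  K_Cl: 60.0        # mM
initial_state:
  Na: 25            # mM
  K: 120
  Cl: 45
  W: 1.0e-3         # cm^3/cm^2 (10 um cell column)
  V_a: -30          # mV
  V_b: -30
low_chloride:
  Cl_lumen: 3       # mM remaining luminal chloride
amiloride_block: 1.0
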