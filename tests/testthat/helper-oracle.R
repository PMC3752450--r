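# Independent pure-R reference implementation of the ODE right-hand side,
# assembled from the exported scalar flux laws. Used as an oracle against
# the compiled rhs.

ref_rhs <- function(state, params, bath = bath_composition(),
                    consts = default_consts(),
                    kinetics = kinetic_constants()) {
  conc <- concentrations(state)
  V_a <- state$V_a
  V_b <- state$V_b
  V_t <- transepithelial_potential(state)
  lum <- bath$lumen
  ser <- bath$serosa

  I_Na_ap <- ghk_current(params$P_Na_ap, 1, V_a, conc[["Na"]], lum[["Na"]], consts)
  I_Cl_ap <- ghk_current(params$P_Cl_ap, -1, V_a, conc[["Cl"]], lum[["Cl"]], consts)
  I_K_bl <- ghk_current(params$P_K_bl, 1, V_b, conc[["K"]], ser[["K"]], consts)
  I_Cl_bl <- ghk_current(params$P_Cl_bl, -1, V_b, conc[["Cl"]], ser[["Cl"]], consts)
  I_pa <- vapply(c("Na", "K", "Cl"), function(ion)
    paracellular_current(params, ion, V_t, ser[[ion]], lum[[ion]], consts),
    numeric(1))
  J_p <- nak_pump_flux(params$rho_NaK, conc[["Na"]], ser[["K"]], kinetics)
  J_n <- nkcc_flux(params$rho_NKCC, ser[c("Na", "K", "Cl")],
                   conc[c("Na", "K", "Cl")], kinetics)
  S_i <- sum(conc) + state$N_imp / state$W_i * 1e6
  J_w_ap <- water_flux(params$P_w_ap, sum(lum) - S_i)
  J_w_bl <- water_flux(params$P_w_bl, S_i - sum(ser))

  amp <- 1e-6  # uA -> A
  F <- consts$F
  Ia <- (I_Na_ap + I_Cl_ap) * amp
  Ib <- (I_K_bl + I_Cl_bl) * amp + F * J_p
  Ip <- sum(I_pa) * amp
  c(dW_i = J_w_bl - J_w_ap,
    dN_Na = -I_Na_ap * amp / F - 3 * J_p + J_n,
    dN_K = -I_K_bl * amp / F + 2 * J_p + J_n,
    dN_Cl = (I_Cl_ap + I_Cl_bl) * amp / F + 2 * J_n,
    dV_a = -(Ia + Ip) / (consts$C_m * 1e-6) * 1e3,
    dV_b = (Ip - Ib) / (consts$C_m * 1e-6) * 1e3)
}

# per-ion particle fluxes into each bath (mol cm^-2 s^-1), for the
# closed-system conservation harness
ref_bath_fluxes <- function(state, params, bath, consts = default_consts(),
                            kinetics = kinetic_constants()) {
  fl <- flux_state(state, params, bath, consts, kinetics)
  F <- consts$F
  amp <- 1e-6
  z <- c(Na = 1, K = 1, Cl = -1)
  into_lumen <- c(
    Na = fl$I_Na_ap * amp / (z[["Na"]] * F) + fl$I_pa_Na * amp / (z[["Na"]] * F),
    K = fl$I_pa_K * amp / (z[["K"]] * F),
    Cl = fl$I_Cl_ap * amp / (z[["Cl"]] * F) + fl$I_pa_Cl * amp / (z[["Cl"]] * F))
  into_serosa <- c(
    Na = 3 * fl$J_NaK - fl$J_NKCC - fl$I_pa_Na * amp / (z[["Na"]] * F),
    K = fl$I_K_bl * amp / (z[["K"]] * F) - 2 * fl$J_NaK - fl$J_NKCC -
      fl$I_pa_K * amp / (z[["K"]] * F),
    Cl = fl$I_Cl_bl * amp / (z[["Cl"]] * F) - 2 * fl$J_NKCC -
      fl$I_pa_Cl * amp / (z[["Cl"]] * F))
  list(into_lumen = into_lumen, into_serosa = into_serosa,
       water_into_lumen = fl$J_w_ap, water_from_serosa = fl$J_w_bl)
}
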