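test_that("symmetric passive epithelium relaxes to V_t = 0", {
  # no pumps, no cotransport, symmetric baths: the steady state carries no
  # trans-epithelial potential
  p <- transport_params(0.03, 0.05, 0.05, 0, 0, 0.05, P_pa = 0.03)
  ss <- find_steady_state(p)
  expect_true(ss$converged)
  expect_lt(abs(ss$V_t), 1e-6)
})

test_that("relaxation and root solves agree on every fixture column", {
  for (col in c("baseline", "nonCF", "CF")) {
    p <- table1_params(col)
    ss_rel <- find_steady_state(p, method = "relaxation")
    ss_root <- find_steady_state(p, method = "root", init = ss_rel$state)
    expect_true(ss_rel$converged, label = paste(col, "relaxation converged"))
    expect_true(ss_root$converged, label = paste(col, "root converged"))
    y1 <- c(ss_rel$state$W_i, ss_rel$state$N, ss_rel$state$V_a, ss_rel$state$V_b)
    y2 <- c(ss_root$state$W_i, ss_root$state$N, ss_root$state$V_a, ss_root$state$V_b)
    expect_equal(y1, y2, tolerance = 1e-6)
  }
})

test_that("steady-state residual and Kirchhoff balance hold at convergence", {
  for (col in c("nonCF", "CF")) {
    ss <- find_steady_state(table1_params(col))
    expect_true(ss$converged)
    expect_lt(ss$residual_norm, 1e-8)
    fl <- ss$fluxes
    I_ap <- fl$I_Na_ap + fl$I_Cl_ap
    I_bl <- fl$I_K_bl + fl$I_Cl_bl + fl$I_pump
    I_pa <- fl$I_pa_Na + fl$I_pa_K + fl$I_pa_Cl
    scale <- max(abs(c(fl$I_Na_ap, fl$I_K_bl, I_pa, 1)))
    # current loop: out across the apical membrane, back along the
    # paracellular path, in across the basolateral membrane
    expect_lt(abs(I_ap + I_pa) / scale, 1e-7)
    expect_lt(abs(I_ap + I_bl) / scale, 1e-7)
  }
})

test_that("steady state is unique across distinct physiological starts", {
  st0 <- initial_state()
  # a second start with the same impermeant closure and the same (zero)
  # conserved-charge offset: swap Na+ against K+ and move the potentials
  st2 <- cell_state(
    W_i = st0$W_i,
    N = c(Na = 45e-6, K = 100e-6, Cl = 45e-6) * st0$W_i,
    V_a = -10, V_b = -55, N_imp = st0$N_imp, z_imp = st0$z_imp)
  for (col in c("baseline", "nonCF", "CF")) {
    p <- table1_params(col)
    ss1 <- find_steady_state(p, init = st0)
    ss2 <- find_steady_state(p, init = st2)
    expect_true(ss1$converged && ss2$converged)
    expect_equal(ss1$V_t, ss2$V_t, tolerance = 1e-5)
    expect_equal(ss1$concentrations, ss2$concentrations, tolerance = 1e-5)
  }
})

test_that("intracellular charge matches the capacitor charge at steady state", {
  consts <- default_consts()
  ss <- find_steady_state(table1_params("nonCF"))
  st <- ss$state
  Q <- consts$F * (st$N[["Na"]] + st$N[["K"]] - st$N[["Cl"]] +
                     st$z_imp * st$N_imp)
  Q_cap <- consts$C_m * 1e-6 * (st$V_a + st$V_b) * 1e-3
  expect_equal(Q, Q_cap, tolerance = 1e-6)
})

test_that("steady-state potentials are insensitive to the water permeability", {
  p <- table1_params("nonCF")
  p10 <- p
  p10$P_w_ap <- p$P_w_ap * 10
  p10$P_w_bl <- p$P_w_bl * 10
  ss <- find_steady_state(p)
  ss10 <- find_steady_state(p10)
  expect_lt(abs(ss$V_t - ss10$V_t), 0.1)
  expect_lt(abs(ss$state$V_a - ss10$state$V_a), 0.1)
})

test_that("driving force vanishes for an ion at Nernst equilibrium", {
  # potassium-only cell: V_b relaxes to E_K, where the K+ driving force is 0
  p <- transport_params(0, 0, 0.08, 0, 0, 0, P_pa = 0)
  ss <- find_steady_state(p)
  expect_true(ss$converged)
  expect_lt(abs(driving_force(ss, "K", "basolateral")), 1e-6)
})

test_that("non-convergence is reported, not silently accepted", {
  # an absurd parameter set that cannot settle inside the physical region
  p <- transport_params(50, 0, 0, 500, 0, 0, P_pa = 1e-5)
  ss <- suppressWarnings(find_steady_state(p))
  expect_false(is.na(ss$converged))
  if (!ss$converged) expect_true(ss$status != 0)
})
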