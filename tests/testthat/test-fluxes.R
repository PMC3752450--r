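consts <- default_consts()

test_that("Nernst potential: identity, closed-form values, domain errors", {
  expect_equal(nernst_potential(1, 100, 100), 0)
  # (RT/F) ln 10 at 310 K = 61.54 mV for a tenfold cation gradient
  expect_equal(nernst_potential(1, 140, 14), 61.54, tolerance = 1e-3)
  # anion sign flip
  expect_equal(nernst_potential(-1, 120, 45), -26.21, tolerance = 1e-2)
  expect_error(nernst_potential(1, 0, 10), "positive")
  expect_error(nernst_potential(1, 10, -1), "positive")
})

test_that("GHK current: no gradient, small-V limit, domain errors", {
  expect_equal(ghk_current(0.05, 1, 0, 80, 80), 0)
  # hand-computed small-V_m limit P z F (c_in - c_out)
  expect_equal(ghk_current(0.024, 1, 0, 25, 140), -26.63, tolerance = 1e-3)
  expect_error(ghk_current(-0.01, 1, 0, 10, 10), "non-negative")
  expect_error(ghk_current(0.01, 1, Inf, 10, 10), "finite")
})

test_that("GHK current reverses exactly at the Nernst potential", {
  cases <- expand.grid(z = c(1, -1), ci = c(5, 45, 120), co = c(3, 120, 140))
  for (i in seq_len(nrow(cases))) {
    z <- cases$z[i]; ci <- cases$ci[i]; co <- cases$co[i]
    E <- nernst_potential(z, co, ci, consts)
    I <- ghk_current(0.05, z, E, ci, co, consts)
    scale <- abs(ghk_current(0.05, z, E + 25, ci, co, consts))
    expect_lt(abs(I) / scale, 1e-10)
  }
})

test_that("GHK V_m -> 0 branch matches the analytic limit to 12 digits", {
  lim <- ghk_current(0.05, 1, 0, 25, 140)
  for (V in c(1e-8, 1e-7, 2e-5)) {
    above <- ghk_current(0.05, 1, V, 25, 140)
    below <- ghk_current(0.05, 1, -V, 25, 140)
    expect_equal(above, lim, tolerance = 1e-12 + abs(V) * 1e2)
    expect_equal(below, lim, tolerance = 1e-12 + abs(V) * 1e2)
  }
  # the expansion branch agrees with the exact formula evaluated at the
  # same potential just below the branch threshold
  V <- 0.9999e-6 * consts$R * consts$T / consts$F * 1e3  # mV
  branch <- ghk_current(0.05, 1, V, 25, 140, consts)
  u <- V * 1e-3 / (consts$R * consts$T / consts$F)
  exact <- 0.05e-4 * consts$F * u * (25e-6 - 140e-6 * exp(-u)) /
    (1 - exp(-u)) * 1e6
  expect_equal(branch, exact, tolerance = 1e-10)
})

test_that("paracellular current: symmetry, selectivity, z -> -z equality", {
  p <- table1_params("baseline")
  for (ion in c("Na", "K", "Cl"))
    expect_equal(paracellular_current(p, ion, 0, 100, 100), 0)
  # cation-selective variant: zero Cl permeability kills the Cl current
  p0 <- p; p0$pa_selectivity[["Cl"]] <- 0
  expect_equal(paracellular_current(p0, "Cl", -25, 120, 120), 0)
  expect_equal(paracellular_current(p0, "Cl", 40, 120, 3), 0)
  # symmetric baths: GHK gives equal currents for z and -z (ions move in
  # opposite directions, transporting charge in the same direction)
  I_Na <- paracellular_current(p, "Na", -10, 140, 140)
  I_Cl_eq <- ghk_current(p$P_pa, -1, 10, 140, 140)
  expect_equal(I_Na, I_Cl_eq, tolerance = 1e-12)
  expect_gt(I_Na, 0)  # lumen-negative V_t drives cations serosa -> lumen
})

test_that("NKCC flux: zero density, equilibrium product, direction, errors", {
  ser <- c(Na = 140, K = 5.3, Cl = 120)
  cell <- c(Na = 25, K = 120, Cl = 45)
  expect_equal(nkcc_flux(0, ser, cell), 0)
  # equal chemical-potential products -> zero net flux
  cell_eq <- c(Na = 140, K = 5.3, Cl = 120)
  expect_equal(nkcc_flux(0.4, ser, cell_eq), 0)
  # scaled equilibrium: [Na][K][Cl]^2 equal on both sides
  cell_eq2 <- c(Na = 140 * 4, K = 5.3, Cl = 60)
  expect_equal(nkcc_flux(0.4, ser, cell_eq2), 0, tolerance = 1e-22)
  # serosal product exceeds intracellular product -> inward (positive)
  expect_gt(nkcc_flux(0.4, ser, cell), 0)
  # proportional to density
  expect_equal(nkcc_flux(0.8, ser, cell), 2 * nkcc_flux(0.4, ser, cell))
  expect_error(nkcc_flux(0.4, c(Na = 0, K = 5.3, Cl = 120), cell), "positive")
})

test_that("pump flux: zero density, monotonicity, saturation, proportionality", {
  expect_equal(nak_pump_flux(0, 25, 5.3), 0)
  expect_gt(nak_pump_flux(0.4, 50, 5.3), nak_pump_flux(0.4, 10, 5.3))
  expect_gt(nak_pump_flux(0.4, 25, 5.3), nak_pump_flux(0.4, 25, 1))
  # bounded by the maximal turnover
  kin <- kinetic_constants()
  expect_lt(nak_pump_flux(0.4, 5000, 5000), 0.4e-10 * kin$k_pump)
  expect_equal(nak_pump_flux(0.8, 25, 5.3), 2 * nak_pump_flux(0.4, 25, 5.3))
  expect_error(nak_pump_flux(0.4, 0, 5.3), "positive")
})

test_that("water flux is linear in the osmotic gradient", {
  expect_equal(water_flux(3, 0), 0)
  expect_equal(water_flux(3, 10), -water_flux(3, -10))
  expect_equal(water_flux(6, 10), 2 * water_flux(3, 10))
  expect_error(water_flux(-1, 10), "not TRUE")
})

test_that("compiled flux kernel agrees with the R flux laws", {
  st <- initial_state()
  p <- table1_params("nonCF")
  bath <- bath_composition()
  kin <- kinetic_constants()
  fl <- flux_state(st, p, bath, consts, kin)
  conc <- concentrations(st)
  expect_equal(fl$I_Na_ap,
               ghk_current(p$P_Na_ap, 1, st$V_a, conc[["Na"]],
                           bath$lumen[["Na"]], consts), tolerance = 1e-12)
  expect_equal(fl$I_Cl_bl,
               ghk_current(p$P_Cl_bl, -1, st$V_b, conc[["Cl"]],
                           bath$serosa[["Cl"]], consts), tolerance = 1e-12)
  expect_equal(fl$I_pa_Na,
               paracellular_current(p, "Na", transepithelial_potential(st),
                                    bath$serosa[["Na"]], bath$lumen[["Na"]],
                                    consts), tolerance = 1e-12)
  expect_equal(fl$J_NaK,
               nak_pump_flux(p$rho_NaK, conc[["Na"]], bath$serosa[["K"]], kin),
               tolerance = 1e-12)
  expect_equal(fl$J_NKCC,
               nkcc_flux(p$rho_NKCC, bath$serosa[c("Na", "K", "Cl")],
                         conc[c("Na", "K", "Cl")], kin), tolerance = 1e-12)
})
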