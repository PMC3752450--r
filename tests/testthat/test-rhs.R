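consts <- default_consts()

test_that("all transport shut off gives a quiescent cell", {
  p <- transport_params(0, 0, 0, 0, 0, 0, P_pa = 0)
  st <- initial_state()
  dy <- hne_rhs(st, p)
  # water flux is unaffected by channel block; the closure makes the
  # reference state iso-osmotic, so every derivative vanishes
  expect_true(all(abs(dy) < 1e-14 * c(1, 1e-7, 1e-7, 1e-7, 1e3, 1e3)))
})

test_that("compiled rhs agrees with the independent R oracle", {
  p <- table1_params("nonCF")
  bath <- bath_composition()
  states <- list(
    initial_state(),
    initial_state(conc = c(Na = 40, K = 90, Cl = 60), V_a = -18, V_b = -40),
    initial_state(conc = c(Na = 15, K = 140, Cl = 30), V_a = -55, V_b = -12))
  for (st in states) {
    expect_equal(hne_rhs(st, p, bath), ref_rhs(st, p, bath),
                 tolerance = 1e-10)
  }
  # and for the CF column with a selective junction
  pcf <- table1_params("CF")
  pcf$pa_selectivity[["Cl"]] <- 0.5
  expect_equal(hne_rhs(states[[2]], pcf, bath), ref_rhs(states[[2]], pcf, bath),
               tolerance = 1e-10)
})

test_that("rhs agrees with an explicit-Euler finite-difference microstep", {
  p <- table1_params("nonCF")
  st <- initial_state()
  dy <- hne_rhs(st, p)
  h <- 1e-6  # s
  st2 <- cell_state(W_i = st$W_i + h * dy[["dW_i"]],
                    N = c(Na = st$N[["Na"]] + h * dy[["dN_Na"]],
                          K = st$N[["K"]] + h * dy[["dN_K"]],
                          Cl = st$N[["Cl"]] + h * dy[["dN_Cl"]]),
                    V_a = st$V_a + h * dy[["dV_a"]],
                    V_b = st$V_b + h * dy[["dV_b"]],
                    N_imp = st$N_imp, z_imp = st$z_imp)
  dy2 <- hne_rhs(st2, p)
  # O(h) consistency of the derivative field along the Euler step (the
  # potential equations have rates of order g/C_m ~ 1e3 /s, so a 1 us step
  # moves them by a fraction of a percent)
  expect_equal(dy2, dy, tolerance = 2e-2)
})

test_that("state invariant violations are reported with diagnostics", {
  p <- table1_params("nonCF")
  st <- initial_state()
  st$N[["Na"]] <- 400e-6 * st$W_i  # 400 mM is legal, 600 is not
  expect_silent(hne_rhs(st, p))
  st$N[["Na"]] <- 600e-6 * st$W_i
  expect_error(hne_rhs(st, p), "500")
  expect_error(cell_state(W_i = -1, N = c(Na = 1e-8, K = 1e-8, Cl = 1e-8),
                          V_a = 0, V_b = 0, N_imp = 1e-7, z_imp = -1),
               "W_i")
})

test_that("closed two-bath system conserves every species, water and charge", {
  p <- table1_params("nonCF")
  kin <- kinetic_constants()
  bath0 <- bath_composition()
  st0 <- initial_state(bath0)
  V_l0 <- 5e-3   # finite bath volumes, cm^3 per cm^2 of epithelium
  V_s0 <- 5e-3
  M_l0 <- bath0$lumen * 1e-6 * V_l0       # mol/cm^2 (incl. impermeant)
  M_s0 <- bath0$serosa * 1e-6 * V_s0

  # y = (cell state, luminal Na K Cl moles, V_l, serosal Na K Cl moles, V_s)
  dfun <- function(t, y, parms) {
    st <- cell_state(W_i = y[1], N = c(Na = y[2], K = y[3], Cl = y[4]),
                     V_a = y[5] * 1e3, V_b = y[6] * 1e3,
                     N_imp = st0$N_imp, z_imp = st0$z_imp)
    V_l <- y[11]; V_s <- y[15]
    bath <- bath_composition(
      lumen = c(Na = y[7] / V_l, K = y[8] / V_l, Cl = y[9] / V_l,
                impermeant = y[10] / V_l) * 1e6,
      serosa = c(Na = y[12] / V_s, K = y[13] / V_s, Cl = y[14] / V_s,
                 impermeant = M_s0[["impermeant"]] / V_s) * 1e6)
    dy <- hne_rhs(st, p, bath, consts, kin)
    bf <- ref_bath_fluxes(st, p, bath, consts, kin)
    c(dy[["dW_i"]], dy[["dN_Na"]], dy[["dN_K"]], dy[["dN_Cl"]],
      dy[["dV_a"]] * 1e-3, dy[["dV_b"]] * 1e-3,
      bf$into_lumen[["Na"]], bf$into_lumen[["K"]], bf$into_lumen[["Cl"]],
      0,  # luminal impermeant moles are fixed
      bf$water_into_lumen,
      bf$into_serosa[["Na"]], bf$into_serosa[["K"]], bf$into_serosa[["Cl"]],
      -bf$water_from_serosa)
  }
  y0 <- c(st0$W_i, st0$N[["Na"]], st0$N[["K"]], st0$N[["Cl"]],
          st0$V_a * 1e-3, st0$V_b * 1e-3,
          M_l0[["Na"]], M_l0[["K"]], M_l0[["Cl"]], M_l0[["impermeant"]], V_l0,
          M_s0[["Na"]], M_s0[["K"]], M_s0[["Cl"]], V_s0)
  times <- seq(0, 120, by = 30)
  sol <- deSolve::lsoda(y = y0, times = times,
                        func = function(t, y, parms) list(dfun(t, y, parms)),
                        parms = NULL, rtol = 1e-10, atol = 1e-16)
  expect_gte(attr(sol, "istate")[1], 0)
  fin <- as.numeric(sol[nrow(sol), -1])
  tot0 <- function(k_cell, k_l, k_s) y0[k_cell] + y0[k_l] + y0[k_s]
  totF <- function(k_cell, k_l, k_s) fin[k_cell] + fin[k_l] + fin[k_s]
  for (ix in list(c(2, 7, 12), c(3, 8, 13), c(4, 9, 14)))  # Na, K, Cl
    expect_equal(totF(ix[1], ix[2], ix[3]), tot0(ix[1], ix[2], ix[3]),
                 tolerance = 1e-9)
  expect_equal(fin[1] + fin[11] + fin[15], y0[1] + y0[11] + y0[15],
               tolerance = 1e-9)

  # charge-capacitance consistency: intracellular net charge tracks the
  # charge stored on the membrane capacitances along the whole trajectory
  defect <- apply(sol[, -1], 1, function(y) {
    consts$F * (y[2] + y[3] - y[4] + st0$z_imp * st0$N_imp) -
      consts$C_m * 1e-6 * (y[5] + y[6])
  })
  expect_lt(max(abs(defect - defect[1])), 1e-6 * consts$F * y0[2])
})
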