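#' Nernst equilibrium potential
#'
#' `(RT / zF) ln(c_out / c_in)`, the reversal potential of a single-ion
#' conductance.
#'
#' @param z ion valence (+1 or -1 here).
#' @param c_out,c_in concentrations on the two sides (mM); must be positive.
#' @param consts a `phys_consts`.
#' @return Potential in mV.
#' @examples
#' nernst_potential(1, 140, 14)   # about +61.5 mV at 310 K
#' nernst_potential(-1, 120, 45)  # about -26.2 mV
#' @export
nernst_potential <- function(z, c_out, c_in, consts = default_consts()) {
  if (any(c_out <= 0) || any(c_in <= 0))
    stop("Nernst potential requires strictly positive concentrations")
  stopifnot(z != 0)
  .rtf(consts) / z * log(c_out / c_in) * 1e3
}

#' Goldman-Hodgkin-Katz channel current
#'
#' Constant-field current through a membrane of permeability `P` for an ion
#' of valence `z`:
#' `I = P z^2 F^2 V / (RT) * (c_in - c_out exp(-zFV/RT)) / (1 - exp(-zFV/RT))`,
#' with the removable singularity at `V = 0` evaluated by its analytic limit
#' `P z F (c_in - c_out)`. Positive current means positive charge leaving the
#' `c_in` side (cation efflux positive).
#'
#' @param P permeability (um s^-1); must be non-negative.
#' @param z ion valence.
#' @param V_m membrane potential, inside minus outside (mV).
#' @param c_in,c_out concentrations (mM).
#' @param consts a `phys_consts`.
#' @return Current in uA cm^-2.
#' @examples
#' ghk_current(0.024, 1, 0, 25, 140)    # small-V limit: -26.6 uA/cm^2
#' ghk_current(0.05, 1, nernst_potential(1, 140, 25), 25, 140)  # ~0
#' @export
ghk_current <- function(P, z, V_m, c_in, c_out, consts = default_consts()) {
  if (any(P < 0)) stop("permeability P must be non-negative")
  if (any(c_in < 0) || any(c_out < 0))
    stop("concentrations must be non-negative")
  if (any(!is.finite(V_m))) stop("V_m must be finite")
  n <- max(length(P), length(V_m), length(c_in), length(c_out))
  Pc <- rep_len(P * 1e-4, n)     # cm/s
  ci <- rep_len(c_in * 1e-6, n)  # mol/cm^3
  co <- rep_len(c_out * 1e-6, n)
  u <- rep_len(z * V_m * 1e-3 / .rtf(consts), n)
  small <- abs(u) < 1e-6
  I <- numeric(n)
  I[small] <- (Pc * z * consts$F * ((ci - co) + 0.5 * u * (ci + co)))[small]
  if (any(!small)) {
    e <- exp(-u)
    I[!small] <- (Pc * z * consts$F * u * (ci - co * e) / (1 - e))[!small]
  }
  I * 1e6                        # uA/cm^2
}

#' Paracellular ion current
#'
#' GHK current across the tight junction, with the trans-epithelial potential
#' as the electrical driving force and the serosal compartment taken as the
#' "inside". Positive current means positive charge moving serosa to lumen.
#' The effective permeability is `P_pa * pa_selectivity[ion]`.
#'
#' @param params a `transport_params`.
#' @param ion `"Na"`, `"K"` or `"Cl"` (or an [ion_species()] object).
#' @param V_t trans-epithelial potential, lumen minus serosa (mV).
#' @param c_serosa,c_lumen bath concentrations of the ion (mM).
#' @param consts a `phys_consts`.
#' @return Current in uA cm^-2.
#' @examples
#' p <- table1_params("baseline")
#' paracellular_current(p, "Na", -10, 140, 140)
#' @export
paracellular_current <- function(params, ion, V_t, c_serosa, c_lumen,
                                 consts = default_consts()) {
  stopifnot(inherits(params, "transport_params"))
  if (is.list(ion)) ion <- ion$name
  ion <- match.arg(ion, c("Na", "K", "Cl"))
  P_eff <- params$P_pa * params$pa_selectivity[[ion]]
  # serosa as inside: V_inside_minus_outside = psi_s - psi_l = -V_t
  ghk_current(P_eff, .VALENCE[[ion]], -V_t, c_serosa, c_lumen, consts)
}

#' Na+-K+-2Cl- cotransporter flux
#'
#' Electroneutral carrier turnover per unit area, proportional to the NKCC
#' membrane density. The carrier moves 1 Na+, 1 K+ and 2 Cl- per cycle; the
#' net flux follows the combined chemical potential of the transported
#' species and therefore vanishes when
#' `[Na]s [K]s [Cl]s^2 = [Na]i [K]i [Cl]i^2`. The saturating form is
#' `J = rho k (u_s - u_i) / (1 + u_s + u_i)` with
#' `u = ([Na]/K_Na)([K]/K_K)([Cl]/K_Cl)^2`.
#'
#' @param rho_NKCC cotransporter density (1e-10 mol cm^-2).
#' @param serosa,cell named concentration vectors with `Na`, `K`, `Cl` (mM);
#'   all strictly positive.
#' @param kinetics kinetic constants, see [kinetic_constants()].
#' @return Net influx in mol cm^-2 s^-1 (positive into the cell).
#' @examples
#' nkcc_flux(0.4, c(Na = 140, K = 5.3, Cl = 120), c(Na = 25, K = 120, Cl = 45))
#' @export
nkcc_flux <- function(rho_NKCC, serosa, cell, kinetics = kinetic_constants()) {
  stopifnot(rho_NKCC >= 0)
  need <- c("Na", "K", "Cl")
  stopifnot(all(need %in% names(serosa)), all(need %in% names(cell)))
  if (any(serosa[need] <= 0) || any(cell[need] <= 0))
    stop("NKCC flux requires strictly positive concentrations")
  u <- function(x) (x[["Na"]] / kinetics$K_Na) * (x[["K"]] / kinetics$K_K) *
    (x[["Cl"]] / kinetics$K_Cl)^2
  us <- u(serosa)
  ui <- u(cell)
  rho_NKCC * 1e-10 * kinetics$k_nkcc * (us - ui) / (1 + us + ui)
}

#' Na+/K+-ATPase pump flux
#'
#' Pump cycle rate per unit area, proportional to the pump density and
#' saturating in intracellular Na+ (third order) and serosal K+ (second
#' order). Each cycle exports 3 Na+, imports 2 K+ and exports one net
#' elementary charge.
#'
#' @param rho_NaK pump density (1e-10 mol cm^-2).
#' @param na_i intracellular Na+ concentration (mM), strictly positive.
#' @param k_s serosal K+ concentration (mM), strictly positive.
#' @param kinetics kinetic constants, see [kinetic_constants()].
#' @return Cycle flux in mol cm^-2 s^-1.
#' @examples
#' nak_pump_flux(0.4, 25, 5.3)
#' @export
nak_pump_flux <- function(rho_NaK, na_i, k_s, kinetics = kinetic_constants()) {
  stopifnot(rho_NaK >= 0)
  if (any(na_i <= 0) || any(k_s <= 0))
    stop("pump flux requires strictly positive concentrations")
  sNa <- na_i / (na_i + kinetics$K_mNa)
  sK <- k_s / (k_s + kinetics$K_mK)
  rho_NaK * 1e-10 * kinetics$k_pump * sNa^3 * sK^2
}

#' Osmotic water flux
#'
#' Volume flux proportional to the trans-membrane osmolarity difference,
#' `J_w = P_w * dS`. Orientation is fixed by the caller; in the model the
#' serosal-to-mucosal direction is positive.
#'
#' @param P_w water permeability coefficient (cm^4 mol^-1 s^-1).
#' @param delta_S osmolarity difference (mM).
#' @return Volume flux in cm^3 cm^-2 s^-1.
#' @export
water_flux <- function(P_w, delta_S) {
  stopifnot(P_w >= 0)
  P_w * delta_S * 1e-6
}
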