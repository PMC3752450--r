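#' Cell state
#'
#' The six dynamical variables of the model (cell volume per unit area,
#' intracellular Na+, K+ and Cl- moles per unit area, apical and basolateral
#' membrane potentials) plus the fixed impermeant intracellular species.
#' Potential conventions: `V_a = psi_cell - psi_lumen`,
#' `V_b = psi_cell - psi_serosa`, so `V_t = V_b - V_a = psi_lumen - psi_serosa`.
#'
#' @param W_i cell volume per unit epithelial area (cm^3 cm^-2).
#' @param N named vector of intracellular moles per unit area for
#'   `Na`, `K`, `Cl` (mol cm^-2).
#' @param V_a,V_b membrane potentials (mV).
#' @param N_imp impermeant intracellular moles per unit area (mol cm^-2).
#' @param z_imp mean valence of the impermeant species.
#' @return An object of class `cell_state`.
#' @seealso [initial_state()] which constructs a state with the
#'   electroneutrality/osmolarity closure.
#' @export
cell_state <- function(W_i, N, V_a, V_b, N_imp, z_imp) {
  stopifnot(W_i > 0, all(c("Na", "K", "Cl") %in% names(N)), all(N >= 0),
            N_imp >= 0)
  conc <- N[c("Na", "K", "Cl")] / W_i * 1e6
  if (any(conc > 500))
    stop("derived intracellular concentration exceeds 500 mM: ",
         paste(sprintf("%s=%.1f", names(conc), conc), collapse = ", "))
  structure(list(W_i = W_i, N = N[c("Na", "K", "Cl")], V_a = V_a, V_b = V_b,
                 N_imp = N_imp, z_imp = z_imp), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  conc <- concentrations(x)
  cat(sprintf("Cell state: W_i = %.3g cm^3/cm^2, V_a = %.2f mV, V_b = %.2f mV, V_t = %.2f mV\n",
              x$W_i, x$V_a, x$V_b, transepithelial_potential(x)))
  cat(sprintf("  [Na]_i = %.1f, [K]_i = %.1f, [Cl]_i = %.1f mM (impermeant %.1f mM, z = %.3f)\n",
              conc[["Na"]], conc[["K"]], conc[["Cl"]],
              x$N_imp / x$W_i * 1e6, x$z_imp))
  invisible(x)
}

#' Intracellular concentrations (mM)
#' @param state a `cell_state`.
#' @export
concentrations <- function(state) {
  stopifnot(inherits(state, "cell_state"))
  state$N / state$W_i * 1e6
}

#' Trans-epithelial potential difference
#'
#' `V_t = psi_lumen - psi_serosa`, with the serosal compartment as earth.
#' Under the membrane conventions used here this is `V_b - V_a`.
#'
#' @param state a `cell_state`.
#' @return V_t in mV.
#' @examples
#' st <- initial_state()
#' transepithelial_potential(st)
#' @export
transepithelial_potential <- function(state) {
  stopifnot(inherits(state, "cell_state"))
  state$V_b - state$V_a
}

#' Reference initial cell state
#'
#' Builds the canonical initial state used to start every steady-state
#' computation. The impermeant intracellular species is closed once, at this
#' reference state, by requiring (i) osmotic balance against the serosal bath
#' and (ii) that the net intracellular charge equals the charge stored on the
#' two membrane capacitances; `N_imp` and `z_imp` are then held constant.
#'
#' @param bath a `bath_composition`; sets the osmolarity target.
#' @param consts a `phys_consts`.
#' @param conc reference intracellular concentrations (mM).
#' @param W_i reference cell volume per unit area (cm^3 cm^-2; the default
#'   corresponds to a 10 um tall cell column).
#' @param V_a,V_b reference membrane potentials (mV).
#' @return A `cell_state`.
#' @examples
#' initial_state()
#' @export
initial_state <- function(bath = bath_composition(), consts = default_consts(),
                          conc = NULL, W_i = NULL, V_a = NULL, V_b = NULL) {
  s <- model_settings()$initial_state
  if (is.null(conc)) conc <- c(Na = s$Na, K = s$K, Cl = s$Cl)
  if (is.null(W_i)) W_i <- s$W
  if (is.null(V_a)) V_a <- s$V_a
  if (is.null(V_b)) V_b <- s$V_b
  stopifnot(all(c("Na", "K", "Cl") %in% names(conc)))
  conc <- conc[c("Na", "K", "Cl")]
  S_ref <- bath_osmolarity(bath, "serosa")
  c_imp <- S_ref - sum(conc)
  if (c_imp <= 0)
    stop("reference ionic osmolarity exceeds the bath osmolarity; ",
         "no impermeant closure exists")
  N <- conc * 1e-6 * W_i
  N_imp <- c_imp * 1e-6 * W_i
  # charge on the capacitors (cell side), C cm^-2
  Q_cap <- consts$C_m * 1e-6 * (V_a + V_b) * 1e-3
  z_imp <- (Q_cap / consts$F - (N[["Na"]] + N[["K"]] - N[["Cl"]])) / N_imp
  cell_state(W_i = W_i, N = N, V_a = V_a, V_b = V_b,
             N_imp = N_imp, z_imp = z_imp)
}

# internal: state <-> solver vector (V in volts)
.pack_y <- function(state) {
  c(state$W_i, state$N[["Na"]], state$N[["K"]], state$N[["Cl"]],
    state$V_a * 1e-3, state$V_b * 1e-3)
}

.unpack_y <- function(y, template) {
  cell_state(W_i = y[1], N = c(Na = y[2], K = y[3], Cl = y[4]),
             V_a = y[5] * 1e3, V_b = y[6] * 1e3,
             N_imp = template$N_imp, z_imp = template$z_imp)
}
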