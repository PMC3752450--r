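# Model assembly: packing R-level objects into the solver's numeric vectors
# and exposing the ODE right-hand side and the full flux breakdown.

.model_ctx <- function(params, bath, consts, kinetics, state) {
  list(q = .pack_q(params), b = .pack_b(bath),
       m = .pack_m(params, consts, kinetics, state))
}

.check_state_invariants <- function(state) {
  conc <- concentrations(state)
  bad <- character(0)
  if (!(state$W_i > 0)) bad <- c(bad, sprintf("W_i = %g <= 0", state$W_i))
  if (any(state$N < 0))
    bad <- c(bad, sprintf("negative moles: %s",
                          paste(names(state$N)[state$N < 0], collapse = ",")))
  over <- conc > 500 | conc < 0
  if (any(over))
    bad <- c(bad, sprintf("concentration out of [0, 500] mM: %s",
                          paste(sprintf("[%s]=%.1f", names(conc)[over],
                                        conc[over]), collapse = ", ")))
  if (length(bad))
    stop("cell state violates invariants: ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

#' Time derivatives of the six state variables
#'
#' Right-hand side of the coupled ODE system: water balance for the cell
#' volume, net trans-membrane ion fluxes for the intracellular moles (channel
#' currents converted by `1/(zF)`, pump contributions `-3 J_NaK` for Na+ and
#' `+2 J_NaK` for K+, cotransporter contributions `+J_NKCC` for Na+ and K+
#' and `+2 J_NKCC` for Cl-), and capacitive charging of the two membranes
#' under Kirchhoff's law at the lumen and serosa nodes:
#' `C_m dV_a/dt = -(I_ap + I_pa)` and `C_m dV_b/dt = I_pa - I_bl`.
#'
#' @param state a `cell_state`.
#' @param params a `transport_params`.
#' @param bath a `bath_composition`.
#' @param consts a `phys_consts`.
#' @param kinetics kinetic constants, see [kinetic_constants()].
#' @return Named vector of derivatives: `dW_i` (cm^3 cm^-2 s^-1), `dN_Na`,
#'   `dN_K`, `dN_Cl` (mol cm^-2 s^-1), `dV_a`, `dV_b` (mV s^-1).
#' @examples
#' hne_rhs(initial_state(), table1_params("nonCF"), bath_composition())
#' @export
hne_rhs <- function(state, params, bath = bath_composition(),
                    consts = default_consts(),
                    kinetics = kinetic_constants()) {
  stopifnot(inherits(state, "cell_state"))
  .check_state_invariants(state)
  ctx <- .model_ctx(params, bath, consts, kinetics, state)
  dy <- .rhs_cpp(.pack_y(state), ctx$q, ctx$b, ctx$m)
  c(dW_i = dy[1], dN_Na = dy[2], dN_K = dy[3], dN_Cl = dy[4],
    dV_a = dy[5] * 1e3, dV_b = dy[6] * 1e3)
}

#' Full flux breakdown at a given state
#'
#' All individual channel currents, paracellular currents, carrier fluxes and
#' water fluxes evaluated at one cell state, under the model's sign
#' conventions (positive channel current = positive charge out of the cell;
#' positive paracellular current = positive charge serosa to lumen; positive
#' `J_NKCC` = influx; positive water flux = serosal to mucosal).
#'
#' @inheritParams hne_rhs
#' @return An object of class `flux_state`: currents in uA cm^-2, carrier
#'   fluxes in mol cm^-2 s^-1, water fluxes in cm^3 cm^-2 s^-1.
#' @examples
#' flux_state(initial_state(), table1_params("nonCF"))
#' @export
flux_state <- function(state, params, bath = bath_composition(),
                       consts = default_consts(),
                       kinetics = kinetic_constants()) {
  stopifnot(inherits(state, "cell_state"))
  ctx <- .model_ctx(params, bath, consts, kinetics, state)
  fl <- .flux_cpp(.pack_y(state), ctx$q, ctx$b, ctx$m)
  out <- as.list(fl)
  for (nm in c("I_Na_ap", "I_Cl_ap", "I_K_bl", "I_Cl_bl",
               "I_pa_Na", "I_pa_K", "I_pa_Cl"))
    out[[nm]] <- out[[nm]] * 1e6
  out$I_pump <- fl[["J_NaK"]] * consts$F * 1e6  # net pump current, uA/cm^2
  structure(out, class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("Fluxes:\n")
  cat(sprintf("  apical:       I_Na %8.3f  I_Cl %8.3f uA/cm^2\n",
              x$I_Na_ap, x$I_Cl_ap))
  cat(sprintf("  basolateral:  I_K  %8.3f  I_Cl %8.3f  I_pump %8.3f uA/cm^2\n",
              x$I_K_bl, x$I_Cl_bl, x$I_pump))
  cat(sprintf("  paracellular: I_Na %8.3f  I_K  %8.3f  I_Cl %8.3f uA/cm^2\n",
              x$I_pa_Na, x$I_pa_K, x$I_pa_Cl))
  cat(sprintf("  carriers:     J_NaK %.3g  J_NKCC %.3g mol/cm^2/s\n",
              x$J_NaK, x$J_NKCC))
  cat(sprintf("  water:        J_ap %.3g  J_bl %.3g cm^3/cm^2/s\n",
              x$J_w_ap, x$J_w_bl))
  invisible(x)
}
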