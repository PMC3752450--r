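#' Solve the model to its open-circuit steady state
#'
#' Two routes are available and cross-checked: `"relaxation"` integrates the
#' stiff ODE system by pseudo-transient continuation (backward-Euler steps
#' with adaptive pseudo-time step) until the nondimensionalised derivative
#' norm falls below `rtol_relax`; `"root"` solves the algebraic system
#' rhs = 0 by a damped Newton iteration, with the model's exact
#' charge-conservation law substituted for the redundant potential equation.
#' The default `"hybrid"` relaxes to a loose tolerance and then polishes the
#' root. Non-convergence is always reported, never silently accepted.
#'
#' @param params a `transport_params`.
#' @param bath a `bath_composition`.
#' @param init initial `cell_state`; defaults to [initial_state()].
#' @param method `"hybrid"`, `"relaxation"` or `"root"`.
#' @param consts a `phys_consts`.
#' @param kinetics kinetic constants, see [kinetic_constants()].
#' @param rtol_relax relaxation stopping tolerance on the nondimensional
#'   derivative norm.
#' @param rtol_root Newton stopping tolerance on the nondimensional root
#'   residual.
#' @param check_stability also require all eigenvalues of the (scaled)
#'   Jacobian to have non-positive real part (up to the structural zero mode
#'   of the conservation law); unstable fixed points are reported as
#'   non-converged with `stable = FALSE`.
#' @return An object of class `steady_state`: the final `cell_state`, `V_t`
#'   (mV), intracellular `concentrations` (mM), the `fluxes` breakdown, and
#'   diagnostics `converged`, `residual_norm`, `stable`, `max_re_eig`.
#' @examples
#' ss <- find_steady_state(table1_params("nonCF"))
#' ss$V_t
#' @export
find_steady_state <- function(params, bath = bath_composition(),
                              init = NULL,
                              method = c("hybrid", "relaxation", "root"),
                              consts = default_consts(),
                              kinetics = kinetic_constants(),
                              rtol_relax = 1e-9, rtol_root = 1e-12,
                              check_stability = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(params, "transport_params"))
  if (is.null(init)) init <- initial_state(bath, consts)
  .check_state_invariants(init)
  ctx <- .model_ctx(params, bath, consts, kinetics, init)
  mcode <- c(hybrid = 0L, relaxation = 1L, root = 2L)[[method]]
  sol <- .steady_cpp(.pack_y(init), ctx$q, ctx$b, ctx$m, mcode,
                     rtol_relax, rtol_root, check_stability)
  state <- tryCatch(.unpack_y(sol$y, init), error = function(e) NULL)
  converged <- isTRUE(sol$converged) && !is.null(state)
  out <- list(
    state = state,
    V_t = if (!is.null(state)) transepithelial_potential(state) else NA_real_,
    concentrations = if (!is.null(state)) concentrations(state) else NULL,
    fluxes = if (!is.null(state))
      flux_state(state, params, bath, consts, kinetics) else NULL,
    converged = converged,
    status = sol$status,
    residual_norm = sol$residual,
    stable = is.na(sol$max_re_eig) || sol$max_re_eig <= 1e-6,
    max_re_eig = sol$max_re_eig,
    method = method,
    params = params, bath = bath, consts = consts, kinetics = kinetics)
  class(out) <- "steady_state"
  out
}

#' @export
print.steady_state <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Steady state: NOT converged (status %d, residual %.3g)\n",
                x$status, x$residual_norm))
    return(invisible(x))
  }
  cat(sprintf("Steady state (%s): V_t = %.2f mV, V_a = %.2f mV, V_b = %.2f mV\n",
              x$method, x$V_t, x$state$V_a, x$state$V_b))
  cat(sprintf("  [Na]_i = %.1f mM, [K]_i = %.1f mM, [Cl]_i = %.1f mM\n",
              x$concentrations[["Na"]], x$concentrations[["K"]],
              x$concentrations[["Cl"]]))
  cat(sprintf("  residual %.2g, max Re(eig) %.2g /s\n",
              x$residual_norm, x$max_re_eig))
  invisible(x)
}

#' Electrochemical driving force at a steady state
#'
#' `V_m - E_ion` for the named membrane, where `E_ion` is the Nernst
#' potential of the ion across that membrane. Driving forces set the
#' direction and permeability-sensitivity of channel fluxes: for the fitted
#' non-CF cell the apical Na+ driving force is large and negative
#' (absorptive) while the apical Cl- driving force is close to zero.
#'
#' @param result a converged `steady_state`.
#' @param ion `"Na"`, `"K"` or `"Cl"` (or an [ion_species()] object).
#' @param membrane `"apical"` or `"basolateral"`.
#' @return Driving force in mV.
#' @examples
#' ss <- find_steady_state(table1_params("nonCF"))
#' driving_force(ss, "Na", "apical")
#' @export
driving_force <- function(result, ion, membrane = c("apical", "basolateral")) {
  stopifnot(inherits(result, "steady_state"))
  if (!result$converged) stop("driving_force requires a converged steady state")
  membrane <- match.arg(membrane)
  if (is.list(ion)) ion <- ion$name
  ion <- match.arg(ion, c("Na", "K", "Cl"))
  conc_i <- result$concentrations[[ion]]
  if (membrane == "apical") {
    V_m <- result$state$V_a
    c_out <- result$bath$lumen[[ion]]
  } else {
    V_m <- result$state$V_b
    c_out <- result$bath$serosa[[ion]]
  }
  E <- nernst_potential(.VALENCE[[ion]], c_out, conc_i, result$consts)
  V_m - E
}

#' The nine filtered observables of a parameter set
#'
#' Computes the basal steady state, then independently the post-amiloride
#' and post-low-chloride steady states (each perturbation applied to the
#' basal condition separately, not sequentially), and assembles the nine
#' observables used for filtering and fitting: basal `[Na+]_i`, `[Cl-]_i`,
#' `V_a`, `V_b`, `V_t`, and the amiloride- and low-Cl--induced changes in
#' `V_a` and `V_t` (post-perturbation steady value minus basal value).
#'
#' @inheritParams find_steady_state
#' @return A named numeric vector of length 9 with attributes
#'   `physiological` (logical: all three solves converged to stable,
#'   physical states) and `status` (the three per-solve status codes).
#'   Degenerate parameter sets with no apical or no basolateral charge
#'   pathway (indeterminate membrane potentials) are flagged
#'   non-physiological without solving.
#' @examples
#' evaluate_observables(table1_params("nonCF"))
#' @export
evaluate_observables <- function(params, bath = bath_composition(),
                                 init = NULL, consts = default_consts(),
                                 kinetics = kinetic_constants(),
                                 rtol_relax = 1e-9, rtol_root = 1e-12) {
  stopifnot(inherits(params, "transport_params"))
  if (is.null(init)) init <- initial_state(bath, consts)
  # a cell with no apical or no basolateral charge pathway has indeterminate
  # membrane potentials: flag rather than solve
  degenerate <-
    params$P_Na_ap + params$P_Cl_ap + params$P_pa == 0 ||
    params$P_K_bl + params$P_Cl_bl + params$P_pa == 0
  if (degenerate) {
    obs <- setNames(rep(NA_real_, 9), .obs_names())
    attr(obs, "physiological") <- FALSE
    attr(obs, "status") <- rep(2L, 3)
    return(obs)
  }
  ctx <- .model_ctx(params, bath, consts, kinetics, init)
  blow <- .pack_b(apply_low_chloride(bath))
  parmat <- matrix(ctx$q[1:6], nrow = 1)
  dummy <- matrix(c(-Inf, Inf), nrow = 5, ncol = 2, byrow = TRUE)
  res <- .observables_batch_cpp(parmat, ctx$q[7], ctx$b, blow, ctx$m,
                                .pack_y(init), dummy, FALSE,
                                rtol_relax, rtol_root)
  obs <- setNames(as.numeric(res[1, 1:9]), .obs_names())
  status <- as.integer(res[1, 10:12])
  attr(obs, "physiological") <- all(status == 0L)
  attr(obs, "status") <- status
  obs
}

#' Change in basal V_t on complete loss of CFTR permeability
#'
#' Sets the apical Cl- permeability to zero, re-solves the steady state from
#' the basal one, and returns the V_t change
#' `dVt0 = V_t(P_Cl_ap = 0) - V_t(basal)`. Depending on the other transport
#' parameters this can be negative (hyperpolarising) or positive
#' (depolarising).
#'
#' @inheritParams find_steady_state
#' @return dVt0 in mV (NA with a warning if either solve fails).
#' @examples
#' cftr_knockout_delta_vt(table1_params("nonCF"))
#' @export
cftr_knockout_delta_vt <- function(params, bath = bath_composition(),
                                   init = NULL, consts = default_consts(),
                                   kinetics = kinetic_constants()) {
  stopifnot(inherits(params, "transport_params"))
  if (is.null(init)) init <- initial_state(bath, consts)
  ctx <- .model_ctx(params, bath, consts, kinetics, init)
  res <- .knockout_batch_cpp(matrix(ctx$q[1:6], nrow = 1), ctx$q[7],
                             ctx$b, ctx$m, .pack_y(init))
  if (any(res[1, 2:3] != 0)) {
    warning("steady-state solve failed during CFTR knockout (status ",
            paste(res[1, 2:3], collapse = "/"), ")")
    return(NA_real_)
  }
  res[1, 1]
}
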