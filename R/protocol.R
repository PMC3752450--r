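#' Simulate the clinical nasal potential-difference protocol
#'
#' Three-phase open-circuit simulation of the first stages of a nasal PD
#' recording: basal V_t from 0 to 5 min, complete amiloride block of ENaC at
#' t = 5 min, and a switch of the luminal perfusate to a low-Cl- solution
#' (amiloride maintained) at t = 10 min. The simulation starts at the basal
#' steady state, so the pre-perturbation trace is flat.
#'
#' Variants modify the parameters before simulation: `nonCF_lowCFTR` reduces
#' the apical Cl- permeability of the non-CF fit to 5 % of its value;
#' `CF_restoredCFTR` raises the CF fit's apical Cl- permeability to the
#' non-CF fitted value. `custom` uses `params` as supplied.
#'
#' @param params a `transport_params`; defaults to the fitted column implied
#'   by `variant` (ignored unless `variant = "custom"`).
#' @param bath a `bath_composition`.
#' @param variant one of `"nonCF"`, `"nonCF_lowCFTR"`, `"CF"`,
#'   `"CF_restoredCFTR"`, `"custom"`.
#' @param t_end end of the simulation (min), at least 15.
#' @param dt output grid spacing (min).
#' @param consts,kinetics model constants.
#' @return A `protocol_trace`: a data frame with columns `time` (min), `V_t`,
#'   `V_a`, `V_b` (mV), `Na_i`, `Cl_i` (mM), plus an `events` attribute
#'   marking the perturbations.
#' @examples
#' \donttest{
#' tr <- run_nasal_pd_protocol(variant = "nonCF")
#' head(tr)
#' }
#' @export
run_nasal_pd_protocol <- function(params = NULL, bath = bath_composition(),
                                  variant = c("nonCF", "nonCF_lowCFTR", "CF",
                                              "CF_restoredCFTR", "custom"),
                                  t_end = 15, dt = 0.05,
                                  consts = default_consts(),
                                  kinetics = kinetic_constants()) {
  variant <- match.arg(variant)
  stopifnot(t_end >= 15, dt > 0)
  if (variant != "custom") {
    params <- switch(variant,
      nonCF = table1_params("nonCF"),
      nonCF_lowCFTR = {
        p <- table1_params("nonCF")
        p$P_Cl_ap <- 0.05 * p$P_Cl_ap
        p
      },
      CF = table1_params("CF"),
      CF_restoredCFTR = {
        p <- table1_params("CF")
        p$P_Cl_ap <- table1_params("nonCF")$P_Cl_ap
        p
      })
  }
  if (is.null(params)) stop("variant = 'custom' requires params")
  stopifnot(inherits(params, "transport_params"))

  basal <- find_steady_state(params, bath, consts = consts,
                             kinetics = kinetics)
  if (!basal$converged)
    stop("basal steady state did not converge; cannot run protocol")
  init <- basal$state

  p_amil <- apply_amiloride(params)
  bath_low <- apply_low_chloride(bath)

  phases <- list(
    list(from = 0, to = 5, params = params, bath = bath),
    list(from = 5, to = 10, params = p_amil, bath = bath),
    list(from = 10, to = t_end, params = p_amil, bath = bath_low))

  y <- .pack_y(init)
  rows <- list()
  for (ph in phases) {
    ctx <- .model_ctx(ph$params, ph$bath, consts, kinetics, init)
    times <- seq(ph$from, ph$to, by = dt) * 60  # seconds
    dfun <- function(t, yy, parms) {
      list(as.numeric(.rhs_cpp(yy, ctx$q, ctx$b, ctx$m)))
    }
    sol <- deSolve::lsoda(y = y, times = times, func = dfun, parms = NULL,
                          rtol = 1e-8,
                          atol = c(1e-10, 1e-14, 1e-14, 1e-14, 1e-10, 1e-10))
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed in protocol phase starting at t = ",
           ph$from, " min")
    y <- as.numeric(sol[nrow(sol), -1])
    rows[[length(rows) + 1]] <- sol
  }
  mat <- do.call(rbind, lapply(seq_along(rows), function(i) {
    m <- rows[[i]]
    if (i > 1) m <- m[-1, , drop = FALSE]  # drop duplicated phase boundary
    m
  }))
  trace <- data.frame(
    time = mat[, 1] / 60,
    V_t = (mat[, 7] - mat[, 6]) * 1e3,
    V_a = mat[, 6] * 1e3,
    V_b = mat[, 7] * 1e3,
    Na_i = mat[, 3] / mat[, 2] * 1e6,
    Cl_i = mat[, 5] / mat[, 2] * 1e6)
  attr(trace, "events") <- data.frame(
    time = c(5, 10),
    event = c("amiloride", "low_Cl"))
  attr(trace, "variant") <- variant
  class(trace) <- c("protocol_trace", "data.frame")
  trace
}

#' @export
print.protocol_trace <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("Nasal PD protocol trace (%s): %d points, %.1f-%.1f min\n",
              attr(x, "variant"), nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  events: %s\n",
              paste(sprintf("%s at %g min", ev$event, ev$time),
                    collapse = ", ")))
  cat(sprintf("  V_t: basal %.2f, final %.2f mV\n", x$V_t[1],
              x$V_t[nrow(x)]))
  invisible(x)
}
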