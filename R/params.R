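#' Transport parameter set
#'
#' The free transport parameters of the epithelial model (apical ENaC and
#' CFTR permeabilities, basolateral K+ and Cl- permeabilities, Na+/K+-ATPase
#' and NKCC densities) together with the fixed paracellular permeability
#' scale, per-ion paracellular selectivity multipliers and osmotic water
#' permeabilities.
#'
#' @param P_Na_ap apical Na+ permeability, ENaC (um s^-1).
#' @param P_Cl_ap apical Cl- permeability, CFTR (um s^-1).
#' @param P_K_bl basolateral K+ permeability (um s^-1).
#' @param rho_NaK Na+/K+-ATPase pump density (1e-10 mol cm^-2).
#' @param rho_NKCC NKCC cotransporter density (1e-10 mol cm^-2).
#' @param P_Cl_bl basolateral Cl- permeability (um s^-1).
#' @param P_pa paracellular permeability scale (um s^-1); default from the
#'   packaged settings.
#' @param pa_selectivity named per-ion multipliers on `P_pa`
#'   (`c(Na = 1, K = 1, Cl = 1)` is a non-selective tight junction). The
#'   packaged default junction is cation-selective (a small Cl- multiplier,
#'   see [model_settings()]): the printed perturbation responses of both the
#'   non-CF and CF cell are only mutually consistent with a junction of low
#'   anion permeability.
#' @param P_w_ap,P_w_bl osmotic water permeability coefficients
#'   (cm^4 mol^-1 s^-1: volume flux per unit area per unit osmolarity
#'   difference); defaults from the packaged settings.
#'
#' @return An object of class `transport_params`.
#' @examples
#' transport_params(0.028, 0.072, 0.080, 0.400, 0.400, 0.100)
#' table1_params("nonCF")
#' @export
transport_params <- function(P_Na_ap, P_Cl_ap, P_K_bl, rho_NaK, rho_NKCC,
                             P_Cl_bl, P_pa = NULL, pa_selectivity = NULL,
                             P_w_ap = NULL, P_w_bl = NULL) {
  s <- model_settings()
  if (is.null(P_pa)) P_pa <- s$paracellular$P_pa
  if (is.null(pa_selectivity))
    pa_selectivity <- unlist(s$paracellular$selectivity)
  if (is.null(P_w_ap)) P_w_ap <- s$water$P_w_ap
  if (is.null(P_w_bl)) P_w_bl <- s$water$P_w_bl
  vals <- c(P_Na_ap, P_Cl_ap, P_K_bl, rho_NaK, rho_NKCC, P_Cl_bl, P_pa,
            P_w_ap, P_w_bl)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all transport parameters must be finite and non-negative")
  need <- c("Na", "K", "Cl")
  if (!all(need %in% names(pa_selectivity)))
    stop("pa_selectivity must be named with Na, K, Cl")
  pa_selectivity <- pa_selectivity[need]
  if (any(pa_selectivity < 0)) stop("pa_selectivity must be non-negative")
  structure(list(
    P_Na_ap = P_Na_ap, P_Cl_ap = P_Cl_ap, P_K_bl = P_K_bl,
    rho_NaK = rho_NaK, rho_NKCC = rho_NKCC, P_Cl_bl = P_Cl_bl,
    P_pa = P_pa, pa_selectivity = pa_selectivity,
    P_w_ap = P_w_ap, P_w_bl = P_w_bl), class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Transport parameters:\n")
  cat(sprintf("  P_Na_ap  %7.4f um/s (ENaC)\n", x$P_Na_ap))
  cat(sprintf("  P_Cl_ap  %7.4f um/s (CFTR)\n", x$P_Cl_ap))
  cat(sprintf("  P_K_bl   %7.4f um/s\n", x$P_K_bl))
  cat(sprintf("  rho_NaK  %7.4f x1e-10 mol/cm^2\n", x$rho_NaK))
  cat(sprintf("  rho_NKCC %7.4f x1e-10 mol/cm^2\n", x$rho_NKCC))
  cat(sprintf("  P_Cl_bl  %7.4f um/s\n", x$P_Cl_bl))
  cat(sprintf("  P_pa     %7.4f um/s, selectivity Na %.2f K %.2f Cl %.2f\n",
              x$P_pa, x$pa_selectivity[["Na"]], x$pa_selectivity[["K"]],
              x$pa_selectivity[["Cl"]]))
  invisible(x)
}

#' Published transport-parameter fixtures
#'
#' Literature baseline and fitted non-CF / CF transport-parameter columns,
#' shipped as a YAML fixture with exactly the published values.
#'
#' @param column `"baseline"`, `"nonCF"` or `"CF"`.
#' @param ... passed on to [transport_params()] (e.g. a different `P_pa`).
#' @return A `transport_params` object.
#' @examples
#' table1_params("CF")$P_Cl_ap
#' @export
table1_params <- function(column = c("baseline", "nonCF", "CF"), ...) {
  column <- match.arg(column)
  tab <- yaml::read_yaml(.extdata("table1_params.yaml"))
  v <- tab[[column]]
  transport_params(P_Na_ap = v$P_Na_ap, P_Cl_ap = v$P_Cl_ap,
                   P_K_bl = v$P_K_bl, rho_NaK = v$rho_NaK,
                   rho_NKCC = v$rho_NKCC, P_Cl_bl = v$P_Cl_bl, ...)
}

#' Complete ENaC block by amiloride
#'
#' Amiloride is modelled as a complete block of the epithelial Na+ channel:
#' the apical Na+ permeability is scaled by `1 - block` (default `block = 1`,
#' i.e. set to zero). Idempotent for a complete block.
#'
#' @param params a `transport_params` object.
#' @param block fraction of ENaC permeability removed, in \[0, 1\].
#' @return A `transport_params` object with reduced `P_Na_ap`.
#' @examples
#' apply_amiloride(table1_params("nonCF"))$P_Na_ap
#' @export
apply_amiloride <- function(params, block = NULL) {
  stopifnot(inherits(params, "transport_params"))
  if (is.null(block)) block <- model_settings()$amiloride_block
  stopifnot(block >= 0, block <= 1)
  params$P_Na_ap <- params$P_Na_ap * (1 - block)
  params
}

#' Extract the six free parameters as a named vector
#'
#' @param params a `transport_params` object.
#' @return Named numeric vector in published row order (um/s and
#'   1e-10 mol/cm^2).
#' @export
free_params <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  setNames(as.numeric(params[.param_names()]), .param_names())
}

# internal packers: convert to solver units -------------------------------

# q: cm/s for permeabilities, mol/cm^2 for densities
.pack_q <- function(params) {
  c(params$P_Na_ap * 1e-4, params$P_Cl_ap * 1e-4, params$P_K_bl * 1e-4,
    params$rho_NaK * 1e-10, params$rho_NKCC * 1e-10, params$P_Cl_bl * 1e-4,
    params$P_pa * 1e-4)
}

# free-parameter matrix (rows in published units) -> internal units
.pack_parmat <- function(mat) {
  scale <- c(1e-4, 1e-4, 1e-4, 1e-10, 1e-10, 1e-4)
  sweep(as.matrix(mat), 2, scale, `*`)
}

# m: model-constant vector for the C++ core; state supplies N_imp and z_imp
.pack_m <- function(params, consts, kinetics, state) {
  c(consts$F, consts$R, consts$T, consts$C_m * 1e-6,
    params$P_w_ap, params$P_w_bl,
    state$N_imp, state$z_imp,
    kinetics$k_pump, kinetics$K_mNa * 1e-6, kinetics$K_mK * 1e-6,
    kinetics$k_nkcc, kinetics$K_Na * 1e-6, kinetics$K_K * 1e-6,
    kinetics$K_Cl * 1e-6,
    params$pa_selectivity[["Na"]], params$pa_selectivity[["K"]],
    params$pa_selectivity[["Cl"]])
}
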