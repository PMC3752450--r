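# Packaged model settings: physical constants, default bath, water
# permeabilities, pump/cotransporter kinetic constants, paracellular scale,
# reference initial state. Values live in inst/extdata/model_settings.yaml so
# that every numerical convention is config, not code.

.settings_env <- new.env(parent = emptyenv())

#' Default model settings
#'
#' Reads the packaged model configuration: physical constants, the default
#' Krebs-Ringer-like bath composition, water permeabilities, the saturation
#' and rate constants of the Na+/K+-ATPase and NKCC submodels, the
#' paracellular permeability scale, and the reference initial cell state.
#'
#' @param reload force re-reading the packaged YAML file.
#' @return A nested list mirroring `inst/extdata/model_settings.yaml`.
#' @examples
#' s <- model_settings()
#' s$pump$k_pump
#' @export
model_settings <- function(reload = FALSE) {
  if (reload || is.null(.settings_env$settings))
    .settings_env$settings <- yaml::read_yaml(.extdata("model_settings.yaml"))
  .settings_env$settings
}

#' Kinetic constants of the active-transport submodels
#'
#' Saturation constants (mM) and maximal per-site turnover rates (s^-1) for
#' the Na+/K+-ATPase pump and the Na+-K+-2Cl- cotransporter. The flux of each
#' carrier is proportional to its membrane density, so the turnover constants
#' set the meaning of one density unit.
#'
#' @param ... named overrides, e.g. `k_pump = 50`.
#' @return A list with elements `k_pump`, `K_mNa`, `K_mK` (pump) and
#'   `k_nkcc`, `K_Na`, `K_K`, `K_Cl` (cotransporter).
#' @export
kinetic_constants <- function(...) {
  s <- model_settings()
  kin <- list(
    k_pump = s$pump$k_pump, K_mNa = s$pump$K_mNa, K_mK = s$pump$K_mK,
    k_nkcc = s$nkcc$k_nkcc, K_Na = s$nkcc$K_Na, K_K = s$nkcc$K_K,
    K_Cl = s$nkcc$K_Cl)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(kin))
    if (length(bad)) stop("unknown kinetic constant: ", paste(bad, collapse = ", "))
    kin[names(over)] <- over
  }
  stopifnot(all(unlist(kin) > 0))
  kin
}

#' @rdname phys_consts
#' @details `default_consts()` returns the packaged constants
#'   (F = 96485 C/mol, R = 8.314 J/(mol K), T = 310 K, C_m = 1 uF/cm^2).
#' @export
default_consts <- function() {
  s <- model_settings()$constants
  phys_consts(F = s$F, R = s$R, T = s$T, C_m = s$C_m)
}
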