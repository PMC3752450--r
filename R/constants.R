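#' Physical constants
#'
#' Bundle of physical constants used by the transport model. Units follow the
#' conventions of epithelial electrophysiology: temperature in kelvin,
#' membrane capacitance in uF cm^-2.
#'
#' @param F Faraday constant (C mol^-1).
#' @param R gas constant (J mol^-1 K^-1).
#' @param T absolute temperature (K); must lie in \[273, 320\].
#' @param C_m membrane capacitance per unit area (uF cm^-2).
#'
#' @return An object of class `phys_consts`.
#' @examples
#' phys_consts()
#' phys_consts(T = 298)
#' @export
phys_consts <- function(F = 96485, R = 8.314, T = 310, C_m = 1) {
  stopifnot(F > 0, R > 0, C_m > 0)
  if (T < 273 || T > 320)
    stop("temperature T must lie in [273, 320] K, got ", T)
  structure(list(F = F, R = R, T = T, C_m = C_m), class = "phys_consts")
}

#' @export
print.phys_consts <- function(x, ...) {
  cat(sprintf(
    "Physical constants: F = %g C/mol, R = %g J/(mol K), T = %g K, C_m = %g uF/cm^2\n",
    x$F, x$R, x$T, x$C_m))
  invisible(x)
}

#' Ion species descriptor
#'
#' @param name one of `"Na"`, `"K"`, `"Cl"`.
#' @return A list with the ion name and its valence `z`.
#' @examples
#' ion_species("Cl")$z
#' @export
ion_species <- function(name = c("Na", "K", "Cl")) {
  name <- match.arg(name)
  list(name = name, z = unname(.VALENCE[name]))
}

# RT/F in volts
.rtf <- function(consts) consts$R * consts$T / consts$F
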