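#' Bath (perfusate) composition
#'
#' Ion and impermeant-osmolyte concentrations of the luminal and serosal
#' compartments bathing the epithelium. The default preset is a
#' Krebs-Ringer-like physiological saline applied symmetrically, matching
#' standard Ussing-chamber perfusates.
#'
#' @param lumen,serosa named numeric vectors with elements `Na`, `K`, `Cl`
#'   and `impermeant`, all in mM.
#' @return An object of class `bath_composition`.
#' @examples
#' bath_composition()
#' @export
bath_composition <- function(lumen = NULL, serosa = NULL) {
  s <- model_settings()$bath
  default <- function(side) c(Na = side$Na, K = side$K, Cl = side$Cl,
                              impermeant = side$impermeant)
  if (is.null(lumen)) lumen <- default(s$lumen)
  if (is.null(serosa)) serosa <- default(s$serosa)
  .check_side <- function(x, nm) {
    need <- c("Na", "K", "Cl", "impermeant")
    if (!all(need %in% names(x)))
      stop(nm, " must have components ", paste(need, collapse = ", "))
    x <- x[need]
    if (any(x < 0)) stop(nm, " concentrations must be non-negative")
    x
  }
  lumen <- .check_side(lumen, "lumen")
  serosa <- .check_side(serosa, "serosa")
  structure(list(lumen = lumen, serosa = serosa),
            class = "bath_composition")
}

#' @export
print.bath_composition <- function(x, ...) {
  cat("Bath composition (mM):\n")
  m <- rbind(lumen = x$lumen, serosa = x$serosa)
  print(round(m, 2))
  cat(sprintf("osmolarity: lumen %.1f, serosa %.1f mM\n",
              sum(x$lumen), sum(x$serosa)))
  invisible(x)
}

#' Total osmolarity of one bath side (mM)
#' @param bath a `bath_composition`.
#' @param side `"lumen"` or `"serosa"`.
#' @export
bath_osmolarity <- function(bath, side = c("lumen", "serosa")) {
  side <- match.arg(side)
  sum(bath[[side]])
}

#' Low luminal chloride perturbation
#'
#' Replaces luminal Cl- mole-for-mole with impermeant anion (gluconate-like
#' substitution), keeping luminal osmolarity and cation concentrations
#' unchanged. The serosal side is untouched. This reproduces the low-Cl-
#' stage of the nasal potential-difference protocol, which introduces a
#' diffusion potential for Cl- efflux.
#'
#' @param bath a `bath_composition`.
#' @param cl_lumen remaining luminal Cl- concentration (mM); default from the
#'   packaged settings (3 mM).
#' @return A new `bath_composition`.
#' @examples
#' b <- apply_low_chloride(bath_composition())
#' b$lumen
#' @export
apply_low_chloride <- function(bath, cl_lumen = NULL) {
  stopifnot(inherits(bath, "bath_composition"))
  if (is.null(cl_lumen)) cl_lumen <- model_settings()$low_chloride$Cl_lumen
  stopifnot(cl_lumen >= 0)
  removed <- bath$lumen[["Cl"]] - cl_lumen
  if (removed < 0) stop("cl_lumen exceeds current luminal [Cl-]")
  lum <- bath$lumen
  lum[["Cl"]] <- cl_lumen
  lum[["impermeant"]] <- lum[["impermeant"]] + removed
  bath_composition(lumen = lum, serosa = bath$serosa)
}

# internal: pack to mol/cm^3 vector in solver order
.pack_b <- function(bath) {
  as.numeric(c(bath$lumen, bath$serosa)) * 1e-6
}
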