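#' Measurement-noise model for synthetic observations
#'
#' Independent additive Gaussian noise with one standard deviation for
#' potential-type observables (mV) and one for concentration-type
#' observables (mM), standing in for inter-culture variability.
#'
#' @param sigma_potential noise SD on V_a, V_b, V_t and the delta-V
#'   observables (mV).
#' @param sigma_concentration noise SD on `[Na+]_i` and `[Cl-]_i` (mM).
#' @return A `noise_model`.
#' @examples
#' noise_model(1, 2)
#' @export
noise_model <- function(sigma_potential = 1, sigma_concentration = 2) {
  stopifnot(sigma_potential >= 0, sigma_concentration >= 0)
  structure(list(sigma_potential = sigma_potential,
                 sigma_concentration = sigma_concentration),
            class = "noise_model")
}

.obs_sigmas <- function(noise) {
  s <- c(Na_i = noise$sigma_concentration, Cl_i = noise$sigma_concentration)
  c(s, setNames(rep(noise$sigma_potential, 7), .obs_names()[3:9]))
}

#' Generate synthetic replicate observation sets
#'
#' Evaluates the nine observables from a known ground-truth parameter set
#' and adds independent Gaussian noise per replicate, producing observation
#' sets for testing the estimation pipeline without external data.
#'
#' @param truth a `transport_params` yielding a converged physiological
#'   steady state.
#' @param bath a `bath_composition`.
#' @param noise a `noise_model`.
#' @param n_replicates number of replicate observation sets.
#' @param seed integer seed.
#' @param condition weighting condition passed to [observation_set()].
#' @param consts,kinetics model configuration.
#' @return List of `observation_set`s, with the noise-free observables as
#'   attribute `truth_observables`.
#' @examples
#' obs <- generate_observations(table1_params("nonCF"),
#'                              noise = noise_model(0, 0), n_replicates = 2)
#' obs[[1]]$targets
#' @export
generate_observations <- function(truth, bath = bath_composition(),
                                  noise = noise_model(), n_replicates = 1,
                                  seed = 1L, condition = "nonCF",
                                  consts = default_consts(),
                                  kinetics = kinetic_constants()) {
  stopifnot(inherits(truth, "transport_params"), n_replicates >= 1)
  base <- evaluate_observables(truth, bath, consts = consts,
                               kinetics = kinetics)
  if (!isTRUE(attr(base, "physiological")))
    stop("ground-truth parameters do not yield a physiological steady state")
  sig <- .obs_sigmas(noise)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  reps <- lapply(seq_len(n_replicates), function(i) {
    noisy <- base + rnorm(9, 0, sig[.obs_names()])
    observation_set(setNames(as.numeric(noisy), .obs_names()),
                    condition = condition)
  })
  attr(reps, "truth_observables") <- base
  reps
}

#' Generate filter bounds centred on a ground truth
#'
#' Builds a `filter_bounds` box centred on the observables of a known
#' parameter set, with stated half-widths for potential-type and
#' concentration-type observables — an in-silico analogue of constructing
#' admissible ranges from observed variability. The truth itself is always
#' accepted against these bounds.
#'
#' @param truth a `transport_params`.
#' @param bath a `bath_composition`.
#' @param half_width_potentials half-width on potential observables (mV).
#' @param half_width_concentrations half-width on concentration observables
#'   (mM).
#' @param consts,kinetics model configuration.
#' @return A `filter_bounds`.
#' @examples
#' b <- generate_bounds(table1_params("nonCF"), half_width_potentials = 3,
#'                      half_width_concentrations = 6)
#' classify_observables(evaluate_observables(table1_params("nonCF")), b)
#' @export
generate_bounds <- function(truth, bath = bath_composition(),
                            half_width_potentials = 3,
                            half_width_concentrations = 6,
                            consts = default_consts(),
                            kinetics = kinetic_constants()) {
  stopifnot(half_width_potentials >= 0, half_width_concentrations >= 0)
  base <- evaluate_observables(truth, bath, consts = consts,
                               kinetics = kinetics)
  if (!isTRUE(attr(base, "physiological")))
    stop("ground-truth parameters do not yield a physiological steady state")
  hw <- .obs_sigmas(noise_model(half_width_potentials,
                                half_width_concentrations))
  m <- cbind(lower = as.numeric(base) - hw[.obs_names()],
             upper = as.numeric(base) + hw[.obs_names()])
  filter_bounds(m, condition_label = "synthetic")
}
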