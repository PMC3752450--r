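#' Physiological filter bounds
#'
#' Published lower/upper admissible values for the nine observables, per
#' condition (non-CF, CF), shipped as a YAML fixture with exactly the
#' published values. Observables 6-9 are the perturbation-induced *changes*
#' in V_a and V_t.
#'
#' @param condition `"nonCF"` or `"CF"`.
#' @return An object of class `filter_bounds`: a 9 x 2 matrix with rows
#'   named as in [evaluate_observables()] and columns `lower`, `upper`.
#' @examples
#' table2_bounds("nonCF")
#' @export
table2_bounds <- function(condition = c("nonCF", "CF")) {
  condition <- match.arg(condition)
  tab <- yaml::read_yaml(.extdata("table2_bounds.yaml"))[[condition]]
  m <- t(vapply(.obs_names(), function(nm) {
    v <- tab[[nm]]
    c(lower = v$lower, upper = v$upper)
  }, numeric(2)))
  filter_bounds(m, condition)
}

#' @rdname table2_bounds
#' @param bounds a 9 x 2 numeric matrix (rows in observable order, columns
#'   lower/upper).
#' @param condition_label free-text label stored with the bounds.
#' @export
filter_bounds <- function(bounds, condition_label = "custom") {
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 9, ncol(bounds) == 2)
  rownames(bounds) <- .obs_names()
  colnames(bounds) <- c("lower", "upper")
  if (any(bounds[, 1] > bounds[, 2]))
    stop("filter bounds must satisfy lower <= upper in every row")
  structure(bounds, class = c("filter_bounds", "matrix"),
            condition = condition_label)
}

#' Classify an observable vector against filter bounds
#'
#' A parameter set is accepted iff all three steady-state solves converged
#' to stable, physical states and every one of the nine observables lies
#' inside its closed interval (bound comparisons are inclusive).
#'
#' @param obs an observable vector from [evaluate_observables()], or any
#'   named numeric of length 9 (then assumed physiological unless it has a
#'   `physiological` attribute).
#' @param bounds a `filter_bounds`.
#' @return `"accepted"` or `"rejected"`.
#' @examples
#' classify_observables(evaluate_observables(table1_params("nonCF")),
#'                      table2_bounds("nonCF"))
#' @export
classify_observables <- function(obs, bounds) {
  stopifnot(inherits(bounds, "filter_bounds"))
  phys <- attr(obs, "physiological")
  if (!is.null(phys) && !isTRUE(phys)) return("rejected")
  v <- as.numeric(obs[.obs_names()])
  if (any(!is.finite(v))) return("rejected")
  ok <- all(v >= bounds[, 1] & v <= bounds[, 2])
  if (ok) "accepted" else "rejected"
}

#' Uniform Monte Carlo sampling of transport-parameter space
#'
#' Each of the six free transport parameters is drawn independently from
#' `U(0, factor x baseline)`; the paracellular and water permeabilities stay
#' at their configured values. The full sample matrix is generated in one
#' call from the seed, so downstream chunked evaluation cannot change it.
#'
#' @param N number of parameter sets.
#' @param baseline a `transport_params` supplying the baseline values.
#' @param factor upper bound as a multiple of baseline (default 5).
#' @param seed integer RNG seed.
#' @return An N x 6 matrix in published units, columns named as
#'   [free_params()].
#' @examples
#' head(sample_parameters(5, seed = 1))
#' @export
sample_parameters <- function(N, baseline = table1_params("baseline"),
                              factor = 5, seed = 1L) {
  stopifnot(N >= 1, factor > 0)
  base <- free_params(baseline)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  u <- matrix(runif(N * 6L), nrow = N, ncol = 6L)
  m <- sweep(u, 2L, factor * base, `*`)
  colnames(m) <- names(base)
  m
}

.union_bounds <- function(b1, b2) {
  cbind(pmin(b1[1:5, 1], b2[1:5, 1]), pmax(b1[1:5, 2], b2[1:5, 2]))
}

.classify_rows <- function(obsmat, status, bounds) {
  ok <- status[, 1] == 0 & status[, 2] == 0 & status[, 3] == 0
  v <- obsmat
  inb <- ok
  for (k in 1:9)
    inb <- inb & !is.na(v[, k]) & v[, k] >= bounds[k, 1] & v[, k] <= bounds[k, 2]
  inb & ok
}

#' Monte Carlo filtering into non-CF and CF parameter populations
#'
#' Draws `N` parameter sets from `U(0, factor x baseline)`, computes the nine
#' observables for each, and classifies every sample against the non-CF and
#' the CF bound sets independently. Samples whose simulations fail
#' (divergence, loss of physicality, unstable kinetics) are labelled
#' `discarded`; samples that simulate cleanly but fall outside both bound
#' sets are labelled `rejected`.
#'
#' Paracellular variants re-run the fixed paracellular configuration:
#' `low_Ppa_CF` halves `P_pa` for the CF classification (higher shunt
#' resistance in CF), `cation_selective` multiplies the paracellular Cl-
#' permeability by the configured selectivity ratio (default 0.5) for both
#' classifications, and `both` combines the two.
#'
#' @param N number of raw draws.
#' @param baseline a `transport_params` with the baseline column and the
#'   fixed paracellular/water configuration.
#' @param bounds_nonCF,bounds_CF `filter_bounds` objects.
#' @param seed integer seed for the parameter draw.
#' @param variant `"default"`, `"low_Ppa_CF"`, `"cation_selective"`, `"both"`.
#' @param factor sampling upper bound as a multiple of baseline.
#' @param bath,consts,kinetics model configuration.
#' @param early_reject skip the perturbation solves for samples whose basal
#'   observables already fall outside the union of the two bound boxes
#'   (their label is decidable from the basal solve alone; their
#'   perturbation observables are reported as NA).
#' @return An `hne_population`: list with the draw matrix `params`
#'   (published units), `observables` (N x 9), per-condition logical
#'   `accepted_nonCF` / `accepted_CF`, factor `label`
#'   (nonCF/CF/rejected/discarded; a sample passing both filters would be
#'   labelled with the rarer CF class, but the published bound sets are
#'   disjoint in `dVt_amil`), `counts`, `percentiles` (1, 25, 50, 75, 99 per
#'   parameter per condition), plus the seed, variant and configuration.
#' @examples
#' \donttest{
#' pop <- run_filter(2000, seed = 7)
#' pop$counts
#' }
#' @export
run_filter <- function(N, baseline = table1_params("baseline"),
                       bounds_nonCF = table2_bounds("nonCF"),
                       bounds_CF = table2_bounds("CF"),
                       seed = 1L,
                       variant = c("default", "low_Ppa_CF",
                                   "cation_selective", "both"),
                       factor = 5, bath = bath_composition(),
                       consts = default_consts(),
                       kinetics = kinetic_constants(),
                       early_reject = TRUE) {
  variant <- match.arg(variant)
  parmat <- sample_parameters(N, baseline, factor, seed)

  # variants are applied relative to the configured default junction:
  # cation_selective multiplies the junction Cl- permeability by the
  # configured ratio, low_Ppa_CF halves P_pa for the CF classification
  sel_ratio <- model_settings()$paracellular$cation_selective_Cl_ratio
  p_nonCF <- baseline
  if (variant %in% c("cation_selective", "both"))
    p_nonCF$pa_selectivity[["Cl"]] <- p_nonCF$pa_selectivity[["Cl"]] * sel_ratio
  p_CF <- p_nonCF
  if (variant %in% c("low_Ppa_CF", "both"))
    p_CF$P_pa <- p_CF$P_pa / 2

  ub <- .union_bounds(bounds_nonCF, bounds_CF)
  obs_nonCF <- .evaluate_batch(parmat, p_nonCF, bath, consts, kinetics, ub,
                               early_reject)
  same_config <- identical(p_CF, p_nonCF)
  obs_CF <- if (same_config) obs_nonCF
            else .evaluate_batch(parmat, p_CF, bath, consts, kinetics, ub,
                                 early_reject)

  acc_non <- .classify_rows(obs_nonCF$obs, obs_nonCF$status, bounds_nonCF)
  acc_cf <- .classify_rows(obs_CF$obs, obs_CF$status, bounds_CF)

  # status > 0 = solver failure / lost physicality / unstable kinetics;
  # status -1 = perturbation skipped for a sample already outside both boxes
  discarded <- obs_nonCF$status[, 1] > 0 | obs_nonCF$status[, 2] > 0 |
    obs_nonCF$status[, 3] > 0
  label <- rep("rejected", N)
  label[discarded] <- "discarded"
  label[acc_non] <- "nonCF"
  label[acc_cf] <- "CF"
  label <- factor(label, levels = c("nonCF", "CF", "rejected", "discarded"))

  counts <- c(table(label))
  pct <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  percentiles <- list(
    nonCF = apply(parmat[acc_non, , drop = FALSE], 2, quantile, probs = pct),
    CF = apply(parmat[acc_cf, , drop = FALSE], 2, quantile, probs = pct))

  structure(list(
    N = N, seed = seed, variant = variant, factor = factor,
    params = parmat,
    observables = obs_nonCF$obs,
    observables_CF = if (same_config) NULL else obs_CF$obs,
    status = obs_nonCF$status,
    accepted_nonCF = acc_non, accepted_CF = acc_cf,
    label = label, counts = counts, percentiles = percentiles,
    baseline = baseline, bounds_nonCF = bounds_nonCF, bounds_CF = bounds_CF,
    bath = bath, consts = consts, kinetics = kinetics),
    class = "hne_population")
}

# shared batched evaluation used by run_filter and helpers
.evaluate_batch <- function(parmat, params_template, bath, consts, kinetics,
                            union_bounds5 = NULL, early_reject = TRUE) {
  init <- initial_state(bath, consts)
  ctx <- .model_ctx(params_template, bath, consts, kinetics, init)
  blow <- .pack_b(apply_low_chloride(bath))
  if (is.null(union_bounds5)) {
    union_bounds5 <- matrix(c(-Inf, Inf), nrow = 5, ncol = 2, byrow = TRUE)
    early_reject <- FALSE
  }
  res <- .observables_batch_cpp(.pack_parmat(parmat), ctx$q[7], ctx$b, blow,
                                ctx$m, .pack_y(init), union_bounds5,
                                early_reject)
  obs <- res[, 1:9, drop = FALSE]
  colnames(obs) <- .obs_names()
  list(obs = obs, status = res[, 10:12, drop = FALSE],
       max_re_eig = res[, 13])
}

#' @export
print.hne_population <- function(x, ...) {
  cat(sprintf("Monte Carlo filter: N = %d, seed = %d, variant = %s\n",
              x$N, x$seed, x$variant))
  cat(sprintf("  accepted non-CF: %d (%.4f%%), CF: %d (%.4f%%)\n",
              sum(x$accepted_nonCF), 100 * mean(x$accepted_nonCF),
              sum(x$accepted_CF), 100 * mean(x$accepted_CF)))
  cat(sprintf("  rejected: %d, discarded (non-physiological/unstable): %d\n",
              sum(x$label == "rejected"), sum(x$label == "discarded")))
  invisible(x)
}

#' CFTR-knockout V_t change across a filtered population
#'
#' Applies [cftr_knockout_delta_vt()] to every accepted non-CF parameter set
#' of a population, in one batched sweep.
#'
#' @param population an `hne_population`.
#' @param which which accepted subset to use (`"nonCF"` or `"CF"`).
#' @return Numeric vector of dVt0 values (mV), NA where a solve failed.
#' @examples
#' \donttest{
#' pop <- run_filter(20000, seed = 7)
#' dvt0 <- knockout_population(pop)
#' range(dvt0, na.rm = TRUE)
#' }
#' @export
knockout_population <- function(population, which = c("nonCF", "CF")) {
  stopifnot(inherits(population, "hne_population"))
  which <- match.arg(which)
  idx <- if (which == "nonCF") population$accepted_nonCF else
    population$accepted_CF
  parmat <- population$params[idx, , drop = FALSE]
  if (nrow(parmat) == 0) return(numeric(0))
  init <- initial_state(population$bath, population$consts)
  ctx <- .model_ctx(population$baseline, population$bath, population$consts,
                    population$kinetics, init)
  res <- .knockout_batch_cpp(.pack_parmat(parmat), ctx$q[7], ctx$b, ctx$m,
                             .pack_y(init))
  res[, 1]
}
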