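#' Observation set for parameter estimation
#'
#' Target values (and weights) for any subset of the nine observables. The
#' default weights are the reciprocals of the published bound half-widths,
#' which makes the residuals dimensionless and commensurate across
#' potentials and concentrations.
#'
#' @param targets named numeric vector; names must be a subset of the nine
#'   observable names, at least 6 present for a 6-parameter fit.
#' @param weights optional named numeric vector of positive weights
#'   (same names as `targets`).
#' @param condition which bound set supplies the default half-width weights.
#' @return An object of class `observation_set`.
#' @examples
#' obs <- evaluate_observables(table1_params("nonCF"))
#' observation_set(obs)
#' @export
observation_set <- function(targets, weights = NULL,
                            condition = c("nonCF", "CF")) {
  condition <- match.arg(condition)
  targets <- unlist(targets)
  bad <- setdiff(names(targets), .obs_names())
  if (length(bad))
    stop("unknown observable(s): ", paste(bad, collapse = ", "))
  if (length(targets) < 6)
    stop("at least 6 observables are required for a 6-parameter fit, got ",
         length(targets))
  if (is.null(weights)) {
    b <- table2_bounds(condition)
    hw <- (b[, 2] - b[, 1]) / 2
    weights <- 1 / hw[names(targets)]
  }
  weights <- weights[names(targets)]
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  structure(list(targets = targets, weights = weights,
                 condition = condition),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set (%d observables, %s weighting):\n",
              length(x$targets), x$condition))
  print(round(rbind(target = x$targets, weight = x$weights), 4))
  invisible(x)
}

# residual magnitude assigned to every slot when a candidate parameter set
# fails to produce a physiological steady state; large enough to dominate
# any in-bounds residual, finite so optimisers can step back out
.PENALTY_RESIDUAL <- 1e3

#' Weighted residuals of a parameter set against an observation set
#'
#' `w_k * (model observable_k - target_k)` for each present observable,
#' using [evaluate_observables()]. A non-physiological parameter set yields
#' a vector of large finite penalty residuals (1e3 per slot) so that
#' least-squares optimisers can escape such regions.
#'
#' @param params a `transport_params`.
#' @param obs an `observation_set`.
#' @param bath,consts,kinetics model configuration.
#' @return Numeric residual vector, one entry per present observable, with
#'   the model observables as attribute `model`.
#' @examples
#' p <- table1_params("nonCF")
#' obs <- observation_set(evaluate_observables(p))
#' hne_residuals(p, obs)  # all zero
#' @export
hne_residuals <- function(params, obs, bath = bath_composition(),
                          consts = default_consts(),
                          kinetics = kinetic_constants()) {
  stopifnot(inherits(obs, "observation_set"))
  model <- evaluate_observables(params, bath, consts = consts,
                                kinetics = kinetics)
  nm <- names(obs$targets)
  if (!isTRUE(attr(model, "physiological"))) {
    r <- rep(.PENALTY_RESIDUAL, length(nm))
    names(r) <- nm
    attr(r, "model") <- model
    return(r)
  }
  r <- obs$weights * (model[nm] - obs$targets)
  names(r) <- nm
  attr(r, "model") <- model
  r
}

#' Bound-constrained least-squares fit of the six transport parameters
#'
#' Levenberg-Marquardt least squares (trust-region style, via
#' \pkg{minpack.lm}) of the six free transport parameters to an observation
#' set, within box bounds, optionally multi-started from seeded uniform
#' samples inside the bounds. The paracellular and water permeabilities are
#' held fixed. The best start by final objective is returned.
#'
#' @param obs an `observation_set`.
#' @param init a `transport_params` giving the first start (and the fixed
#'   paracellular/water configuration).
#' @param lower,upper named numeric bounds on the six free parameters;
#'   default `0` and `5 x` the baseline column.
#' @param seed integer seed for the multi-start draws.
#' @param n_starts number of starts (1 = local fit from `init` only).
#' @param bath,consts,kinetics model configuration.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return A `fit_result`: fitted `transport_params`, `objective` (weighted
#'   SSE), per-observable `residuals`, `converged` flag and diagnostics,
#'   `bounds`, and all multi-start objectives.
#' @examples
#' \donttest{
#' truth <- table1_params("nonCF")
#' obs <- observation_set(evaluate_observables(truth))
#' start <- truth; start$P_Na_ap <- truth$P_Na_ap * 1.5
#' fit <- hne_fit(obs, start, n_starts = 1)
#' free_params(fit$params)
#' }
#' @export
hne_fit <- function(obs, init = table1_params("baseline"),
                    lower = NULL, upper = NULL, seed = 1L, n_starts = 10,
                    bath = bath_composition(), consts = default_consts(),
                    kinetics = kinetic_constants(),
                    control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(obs, "observation_set"), inherits(init, "transport_params"))
  base <- free_params(table1_params("baseline"))
  if (is.null(lower)) lower <- setNames(rep(0, 6), .param_names())
  if (is.null(upper)) upper <- 5 * base
  lower <- lower[.param_names()]
  upper <- upper[.param_names()]
  p0 <- free_params(init)
  if (any(p0 < lower) || any(p0 > upper))
    stop("init must lie within the bounds")

  as_params <- function(v) {
    p <- init
    p[.param_names()] <- as.list(pmin(pmax(v, lower), upper))
    p
  }
  fn <- function(v) {
    as.numeric(hne_residuals(as_params(v), obs, bath, consts, kinetics))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  starts <- list(p0)
  if (n_starts > 1) {
    extra <- replicate(n_starts - 1,
                       lower + runif(6) * (upper - lower), simplify = FALSE)
    starts <- c(starts, lapply(extra, setNames, .param_names()))
  }

  runs <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = fn,
                         control = control),
      error = function(e) NULL)
  })
  objectives <- vapply(runs, function(r)
    if (is.null(r)) Inf else sum(r$fvec^2), numeric(1))
  if (all(!is.finite(objectives)))
    stop("all optimisation starts failed to converge")
  best <- runs[[which.min(objectives)]]
  pars <- as_params(best$par)
  res <- hne_residuals(pars, obs, bath, consts, kinetics)
  structure(list(
    params = pars,
    objective = sum(res^2),
    residuals = res,
    model = attr(res, "model"),
    converged = best$info %in% 1:4,
    info = best$info, message = best$message,
    niter = best$niter,
    start_objectives = objectives,
    bounds = cbind(lower = lower, upper = upper),
    obs = obs, seed = seed),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Least-squares fit: objective %.4g (%s, %d iterations)\n",
              x$objective, if (x$converged) "converged" else "NOT converged",
              x$niter))
  print(round(free_params(x$params), 4))
  invisible(x)
}

#' Profile identifiability of a fit
#'
#' Perturbs each fitted parameter by a factor and re-optimises the remaining
#' five; a well-identified parameter raises the re-optimised objective.
#' Directions that stay flat (objective increase below `flat_tol`) are
#' reported, not hidden.
#'
#' @param fit a `fit_result`.
#' @param delta relative perturbation (default 0.2, i.e. +/-20 %).
#' @param flat_tol objective increase below which a direction is flagged
#'   flat.
#' @param ... passed to [hne_fit()] (e.g. `bath`).
#' @return Data frame with columns parameter, direction, objective and flat
#'   flag.
#' @export
profile_identifiability <- function(fit, delta = 0.2, flat_tol = 1e-4, ...) {
  stopifnot(inherits(fit, "fit_result"))
  p_hat <- free_params(fit$params)
  rows <- list()
  for (k in .param_names()) {
    for (dir in c(-1, 1)) {
      p_k <- p_hat
      p_k[k] <- p_hat[k] * (1 + dir * delta)
      lo <- fit$bounds[, "lower"]; hi <- fit$bounds[, "upper"]
      p_k[k] <- min(max(p_k[k], lo[k]), hi[k])
      lo[k] <- hi[k] <- p_k[k]  # pin the profiled parameter
      start <- fit$params
      start[.param_names()] <- as.list(p_k)
      ref <- tryCatch(
        hne_fit(fit$obs, start, lower = lo, upper = hi, n_starts = 1, ...),
        error = function(e) NULL)
      objective <- if (is.null(ref)) NA_real_ else ref$objective
      rows[[length(rows) + 1]] <- data.frame(
        parameter = k, direction = dir, objective = objective,
        flat = is.finite(objective) &&
          (objective - fit$objective) < flat_tol)
    }
  }
  do.call(rbind, rows)
}
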