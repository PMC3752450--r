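#' Normalise a parameter sample by its baseline values
#'
#' Divides each of the six free transport parameters by its baseline value,
#' giving dimensionless regressors ("baseline multiples") for the sensitivity
#' regression. A regression coefficient then reads "mV per baseline-multiple
#' of the parameter".
#'
#' @param samples N x 6 matrix of parameter sets (published units).
#' @param baseline a `transport_params` with strictly positive free
#'   parameters.
#' @return N x 6 matrix of normalised values.
#' @examples
#' b <- table1_params("baseline")
#' normalise_parameters(sample_parameters(3, b, seed = 1), b)
#' @export
normalise_parameters <- function(samples, baseline = table1_params("baseline")) {
  base <- free_params(baseline)
  if (any(base <= 0))
    stop("normalisation requires strictly positive baseline values")
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 6)
  out <- sweep(samples, 2, base, `/`)
  colnames(out) <- names(base)
  out
}

#' Ordinary least-squares sensitivity regression
#'
#' Fits `y = b0 + sum_i b_i x_i` by OLS with intercept, where the `x_i` are
#' normalised parameter values and `y` is one model output over a filtered
#' population. Coefficient magnitudes rank the linear influence of each
#' transport parameter on the output.
#'
#' @param X design matrix (rows = parameter sets, columns = normalised
#'   parameters); at least 50 rows and full column rank.
#' @param y output vector (mV).
#' @return A `sensitivity_result`: output name, intercept, named
#'   coefficients, their standard errors, and R^2.
#' @examples
#' X <- matrix(runif(600), ncol = 6,
#'             dimnames = list(NULL, c("P_Na_ap", "P_Cl_ap", "P_K_bl",
#'                                     "rho_NaK", "rho_NKCC", "P_Cl_bl")))
#' y <- 2 * X[, 1] - X[, 2] + rnorm(100, sd = 0.01)
#' linear_sensitivity(X, y)
#' @export
linear_sensitivity <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 50)
    stop("sensitivity regression requires at least 50 rows, got ", nrow(X))
  stopifnot(nrow(X) == length(y))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop("design matrix is rank deficient; collinear columns: ",
         paste(colnames(X)[dropped[dropped > 0]], collapse = ", "))
  }
  df <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = df)
  # summary.lm warns on an exactly constant response; R^2 is set below
  sm <- suppressWarnings(summary(fit))
  cf <- coef(sm)
  b <- cf[-1, "Estimate"]
  names(b) <- colnames(X)
  se <- cf[-1, "Std. Error"]
  names(se) <- colnames(X)
  r2 <- if (all(abs(y - mean(y)) < 1e-12)) 0 else sm$r.squared
  structure(list(output = attr(y, "output") %||% "y",
                 intercept = cf[1, "Estimate"],
                 coefficients = b, se = se, r_squared = r2,
                 n = nrow(X), fit = fit),
            class = "sensitivity_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity regression for %s (n = %d, R^2 = %.3f):\n",
              x$output, x$n, x$r_squared))
  ord <- order(-abs(x$coefficients))
  for (i in ord)
    cat(sprintf("  b(%-8s) = %8.3f mV  (se %.3f)\n",
                names(x$coefficients)[i], x$coefficients[i], x$se[i]))
  invisible(x)
}

#' Sensitivity analysis of a filtered population
#'
#' Runs the linear sensitivity regression of basal `V_t`, `dVt_amil` and
#' `dVt_lowCl` on the baseline-normalised parameters over the accepted
#' non-CF (or CF) subset of a Monte Carlo filter run.
#'
#' @param population an `hne_population`.
#' @param which accepted subset to regress over.
#' @param outputs which observables to use as responses.
#' @return Named list of `sensitivity_result` objects.
#' @examples
#' \donttest{
#' pop <- run_filter(50000, seed = 7)
#' rep <- sensitivity_report(pop)
#' rep$V_t$coefficients
#' }
#' @export
sensitivity_report <- function(population, which = c("nonCF", "CF"),
                               outputs = c("V_t", "dVt_amil", "dVt_lowCl")) {
  stopifnot(inherits(population, "hne_population"))
  which <- match.arg(which)
  idx <- if (which == "nonCF") population$accepted_nonCF else
    population$accepted_CF
  n_acc <- sum(idx)
  if (n_acc < 50)
    stop("sensitivity analysis requires at least 50 accepted ", which,
         " parameter sets, got ", n_acc,
         "; increase the Monte Carlo sample size")
  X <- normalise_parameters(population$params[idx, , drop = FALSE],
                            population$baseline)
  obs <- population$observables
  if (which == "CF" && !is.null(population$observables_CF))
    obs <- population$observables_CF
  out <- lapply(outputs, function(nm) {
    y <- obs[idx, nm]
    attr(y, "output") <- nm
    linear_sensitivity(X, y)
  })
  names(out) <- outputs
  out
}
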