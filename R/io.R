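# Configuration and result serialization: YAML/JSON configs in, tidy CSV /
# JSON summaries out. Every run can write its fully resolved configuration
# next to its outputs for provenance.

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration with any of the keys `constants`,
#' `bath`, `params`, `kinetics`, `seed`, `filter` and validates them against
#' the packaged defaults; unknown top-level keys raise an error naming the
#' offending key.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A `run_config` list with fully resolved components: `consts`
#'   (`phys_consts`), `bath` (`bath_composition`), `params`
#'   (`transport_params`), `kinetics`, `seed`, and the raw `filter` block.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("seed: 7\nparams:\n  column: nonCF", cfg)
#' load_run_config(cfg)$seed
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("constants", "bath", "params", "kinetics", "seed", "filter")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")

  consts <- if (is.null(raw$constants)) default_consts()
  else do.call(phys_consts, modifyList(unclass(default_consts()),
                                       raw$constants))
  bath <- if (is.null(raw$bath)) bath_composition()
  else bath_composition(lumen = unlist(raw$bath$lumen),
                        serosa = unlist(raw$bath$serosa))
  params <- if (is.null(raw$params)) table1_params("baseline")
  else if (!is.null(raw$params$column)) {
    extra <- raw$params[setdiff(names(raw$params), "column")]
    do.call(table1_params, c(list(column = raw$params$column), extra))
  } else do.call(transport_params, raw$params)
  kinetics <- if (is.null(raw$kinetics)) kinetic_constants()
  else do.call(kinetic_constants, raw$kinetics)

  structure(list(consts = consts, bath = bath, params = params,
                 kinetics = kinetics,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 filter = raw$filter, path = path),
            class = "run_config")
}

#' Write a resolved run configuration
#'
#' Serialises the resolved configuration (constants, bath, parameters,
#' kinetic constants, seed) to YAML so a run's provenance can sit next to
#' its outputs. `load_run_config(write_run_config(cfg, f))` reproduces the
#' same resolved configuration.
#'
#' @param config a `run_config`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  out <- list(
    constants = unclass(config$consts),
    bath = list(lumen = as.list(config$bath$lumen),
                serosa = as.list(config$bath$serosa)),
    params = c(as.list(setNames(as.numeric(free_params(p)), .param_names())),
               list(P_pa = p$P_pa,
                    pa_selectivity = as.list(p$pa_selectivity),
                    P_w_ap = p$P_w_ap, P_w_bl = p$P_w_bl)),
    kinetics = config$kinetics,
    seed = config$seed)
  if (!is.null(config$filter)) out$filter <- config$filter
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write analysis results to disk
#'
#' Dispatches on the result type: protocol traces become tidy long-format
#' CSV (`time`, `variable`, `value`); populations become a per-sample CSV
#' (parameters, observables, label) plus a JSON summary with counts and
#' percentiles; steady states, fits and sensitivity results become JSON
#' summaries. Paths get the appropriate extension appended if missing.
#'
#' @param result a `protocol_trace`, `hne_population`, `steady_state`,
#'   `fit_result`, or a plain named list/vector of scalar summaries.
#' @param path output path.
#' @return The path written, invisibly.
#' @export
write_results <- function(result, path) {
  ensure_ext <- function(p, ext) {
    if (!grepl(paste0("\\.", ext, "$"), p, ignore.case = TRUE))
      p <- paste0(p, ".", ext)
    p
  }
  if (inherits(result, "protocol_trace")) {
    path <- ensure_ext(path, "csv")
    long <- do.call(rbind, lapply(
      setdiff(names(result), "time"),
      function(v) data.frame(time = result$time, variable = v,
                             value = result[[v]])))
    write.csv(long, path, row.names = FALSE)
  } else if (inherits(result, "hne_population")) {
    path <- ensure_ext(path, "csv")
    df <- data.frame(result$params, result$observables,
                     label = result$label, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
    summary_path <- sub("\\.csv$", "_summary.json", path)
    jsonlite::write_json(
      list(N = result$N, seed = result$seed, variant = result$variant,
           counts = as.list(result$counts),
           percentiles = lapply(result$percentiles, function(m)
             as.data.frame(m))),
      summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (inherits(result, "steady_state")) {
    path <- ensure_ext(path, "json")
    jsonlite::write_json(
      list(V_t = result$V_t, V_a = result$state$V_a, V_b = result$state$V_b,
           concentrations = as.list(result$concentrations),
           converged = result$converged,
           residual_norm = result$residual_norm),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (inherits(result, "fit_result")) {
    path <- ensure_ext(path, "json")
    jsonlite::write_json(
      list(params = as.list(free_params(result$params)),
           objective = result$objective,
           residuals = as.list(unclass(result$residuals)),
           converged = result$converged, seed = result$seed),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    path <- ensure_ext(path, "json")
    jsonlite::write_json(as.list(result), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
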