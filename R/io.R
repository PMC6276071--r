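# Configuration-driven runs and result serialisation. Model/protocol
# configurations are YAML; curves and time series are written as CSV, fits
# and audits as JSON.

.known_models <- c("symmetric", "asymmetric", "multisite", "branched")

# Schema: top-level keys and the builder/protocol parameters they admit.
.config_schema <- list(
  model = c("type", "params", "n_species", "block_right_branch"),
  protocol = c("type", "direction", "grid", "labelled_fraction",
               "inside_load", "tracer_outside", "t_max", "inside_volume"),
  grid = c("n_points", "from", "to"),
  fit = c("enabled"),
  audit = c("enabled", "bath_conc", "tolerance"),
  output = c("dir", "prefix"),
  seed = NULL)

.carrier_param_keys <- c("KD_out", "KD_in", "b_out_in", "b_in_out",
                         "f_out_in", "f_in_out", "k_on", "auto_close", "total")
.multisite_param_keys <- c("site_KD", "diffusion_rate", "k_on",
                           "central_slowdown", "branch_rates", "branch_KD",
                           "exchange_site", "exchange_rate",
                           "void_volume", "total")

#' Validate a run configuration
#'
#' Checks the nested key structure of a configuration list against the
#' published schema; unknown keys anywhere are rejected with a field-level
#' message before any computation starts.
#'
#' @param config A list, typically from [yaml::read_yaml()].
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (sec in intersect(names(config), c("model", "protocol", "fit", "audit", "output"))) {
    bad <- setdiff(names(config[[sec]]), .config_schema[[sec]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", ")))
    }
  }
  bad_grid <- setdiff(names(config$protocol$grid), .config_schema$grid)
  if (length(bad_grid)) {
    abort(sprintf("unknown key(s) in 'protocol.grid': %s",
                  paste(bad_grid, collapse = ", ")))
  }
  if (is.null(config$model$type) || !config$model$type %in% .known_models) {
    abort(sprintf("model.type must be one of: %s",
                  paste(.known_models, collapse = ", ")))
  }
  pk <- if (config$model$type %in% c("symmetric", "asymmetric")) {
    .carrier_param_keys
  } else .multisite_param_keys
  bad <- setdiff(names(config$model$params), pk)
  if (length(bad)) {
    abort(sprintf("unknown key(s) in 'model.params': %s", paste(bad, collapse = ", ")))
  }
  invisible(config)
}

#' Build a model from a configuration list
#'
#' @param config Validated configuration (see [validate_config()]).
#' @return A `transport_network`.
#' @export
model_from_config <- function(config) {
  validate_config(config)
  p <- config$model$params %||% list()
  n_sp <- config$model$n_species %||% 1
  switch(config$model$type,
    symmetric = build_symmetric_carrier(do.call(carrier_params, p)),
    asymmetric = {
      if (!length(p)) p <- list(KD_out = 3, KD_in = 30)
      build_asymmetric_carrier(do.call(carrier_params, p))
    },
    multisite = build_multisite_chain(do.call(multisite_params, p), n_species = n_sp),
    branched = build_branched_multisite(
      block_right_branch = isTRUE(config$model$block_right_branch),
      params = do.call(multisite_params, p), n_species = n_sp))
}

#' Serialise a model to a configuration list
#'
#' Builder-produced models round-trip through their recorded parameters;
#' the returned list rebuilds a structurally identical network via
#' [model_from_config()].
#'
#' @param model A builder-produced `transport_network`.
#' @return A configuration list (suitable for [yaml::write_yaml()]).
#' @export
model_to_config <- function(model) {
  p <- attr(model, "params")
  b <- attr(model, "builder")
  if (is.null(p) || is.null(b)) {
    abort("only builder-produced models carry a serialisable parameter set")
  }
  list(model = c(b, list(params = unclass(p))))
}

#' Write a flux curve (or any tabular result) as CSV
#'
#' Flux curves are written with the documented two-column layout
#' `concentration_mmol_per_L`, `flux_per_carrier_per_s`.
#'
#' @param x A `flux_curve`, `time_course`, or data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "flux_curve")) {
    names(df)[match(c("concentration", "flux"), names(df))] <-
      c("concentration_mmol_per_L", "flux_per_carrier_per_s")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' `cycle_report`s are written with one record per basis cycle;
#' `saturation_fit`, `kinetic_summary`, `equilibrium_audit` and
#' `carrier_calibration` objects are written as their tidy/summary tables.
#' Numeric formatting is pinned (15 significant digits) so identical runs
#' produce byte-identical files.
#'
#' @param x Report object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  payload <- if (inherits(x, "cycle_report")) {
    list(tolerance = x$tolerance, passed = x$passed, cycles = tidy(x))
  } else if (inherits(x, "saturation_fit")) {
    list(estimates = tidy(x), diagnostics = glance(x))
  } else if (inherits(x, "kinetic_summary")) {
    list(summary = tidy(x))
  } else if (inherits(x, "equilibrium_audit")) {
    list(uniform = x$uniform, bath_conc = x$bath_conc,
         max_conc_deviation = x$max_conc_deviation,
         max_flux_imbalance = x$max_flux_imbalance)
  } else if (inherits(x, "carrier_calibration")) {
    list(params = unclass(x$params), observables = tidy(x),
         objective = x$objective, seed = x$seed)
  } else x
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 15,
                       pretty = TRUE)
  invisible(path)
}

#' Execute a configuration-driven pipeline
#'
#' Reads and validates a YAML configuration, builds the requested model,
#' runs the requested protocol, optionally fits the saturation curve and
#' audits equilibrium uniformity, and writes CSV/JSON artifacts together
#' with a log recording the configuration hash, package version and seed.
#' Nothing is written if validation fails.
#'
#' @param path Path to a YAML configuration file.
#' @param out_dir Output directory override (defaults to the config's
#'   `output.dir`, or the config file's directory).
#' @return Named character vector of the files written, invisibly.
#' @export
run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  config <- yaml::read_yaml(path)
  validate_config(config)
  out_dir <- out_dir %||% config$output$dir %||% dirname(path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prefix <- config$output$prefix %||%
    tools::file_path_sans_ext(basename(path))
  if (!is.null(config$seed)) set.seed(config$seed)

  model <- model_from_config(config)
  files <- character()
  emit <- function(obj, name, writer) {
    f <- file.path(out_dir, paste0(prefix, "_", name))
    writer(obj, f)
    files[[name]] <<- f
  }

  proto <- config$protocol
  if (!is.null(proto)) {
    g <- proto$grid
    grid <- default_conc_grid(n = g$n_points %||% 24,
                              from = g$from %||% 0.03, to = g$to %||% 300)
    direction <- proto$direction %||% "influx"
    if (proto$type == "zero_trans") {
      curve <- run_zero_trans(model, direction, grid)
      emit(curve, "curve.csv", write_result_csv)
    } else if (proto$type == "equilibrium_exchange") {
      curve <- run_equilibrium_exchange(model, direction, grid,
                                        proto$labelled_fraction %||% 1e-6)
      emit(curve, "curve.csv", write_result_csv)
    } else if (proto$type == "counterflow") {
      m <- with_finite_inside(model, proto$inside_volume %||% 1)
      cf <- run_counterflow(m, proto$inside_load %||% 100,
                            proto$tracer_outside %||% 1,
                            seq(0.5, proto$t_max %||% 200, by = 0.5))
      emit(cf, "counterflow.csv", write_result_csv)
      curve <- NULL
    } else if (proto$type == "kinetic_summary") {
      ks <- kinetic_summary(model, grid, proto$labelled_fraction %||% 1e-6)
      emit(ks, "kinetic_summary.json", write_result_json)
      curve <- NULL
    } else {
      abort(sprintf("unknown protocol type '%s'", proto$type))
    }
    if (isTRUE(config$fit$enabled) && !is.null(curve)) {
      emit(fit_michaelis_menten(curve), "fit.json", write_result_json)
    }
  }

  if (isTRUE(config$audit$enabled)) {
    emit(check_detailed_balance(model), "cycles.json", write_result_json)
    emit(equilibrium_audit(model, config$audit$bath_conc %||% 10,
                           config$audit$tolerance %||% 1e-6),
         "equilibrium_audit.json", write_result_json)
  }

  log <- list(config = path,
              config_sha = unname(tools::md5sum(path)),
              package_version = as.character(utils::packageVersion("portersim")),
              seed = config$seed %||% NA,
              files = as.list(files))
  lf <- file.path(out_dir, paste0(prefix, "_run_log.json"))
  jsonlite::write_json(log, lf, auto_unbox = TRUE, pretty = TRUE)
  files[["run_log.json"]] <- lf
  invisible(files)
}
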