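#' Write sensorgrams to a delimited-text table
#'
#' Serializes a [sensorgram_series()] or a full `sensorgram_set` (active +
#' interspot + blank channels) to CSV with columns `curve_id`, `conc_M`,
#' `time_s`, `response_RU`, `channel`. Concentrations are always stored in
#' molar; the dialect is comma-separated, UTF-8, `.` decimal, header
#' mandatory.
#'
#' @param x a [sensorgram_series()] or `sensorgram_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_table <- function(x, path) {
  rows <- function(series, channel) {
    do.call(rbind, lapply(seq_along(series$curves), function(i) {
      cv <- series$curves[[i]]
      data.frame(curve_id = if (nzchar(cv$label)) cv$label else paste0("curve", i),
                 conc_M = cv$conc, time_s = cv$time, response_RU = cv$response,
                 channel = channel, stringsAsFactors = FALSE)
    }))
  }
  d <- if (inherits(x, "sensorgram_set")) {
    rbind(rows(x$active, "active"), rows(x$interspot, "interspot"),
          rows(x$blank, "blank"))
  } else if (inherits(x, "sensorgram_series")) {
    rows(x, "active")
  } else stop("'x' must be a sensorgram_series or sensorgram_set")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sensorgrams from a delimited-text table
#'
#' Parses the CSV format written by [write_sensorgram_table()] (columns
#' `curve_id`, `conc_M`, `time_s`, `response_RU`, `channel`). Grids are
#' validated: strictly increasing within each curve and identical across
#' all curves of a channel. Parse failures report the offending line
#' number.
#'
#' @param path input file path.
#' @param schedule optional [phase_schedule()] attached to every curve
#'   (required downstream by [global_fit()]).
#' @return A named list of [sensorgram_series()], one per channel present
#'   (`active`, and `interspot`/`blank` when present).
#' @export
read_sensorgram_table <- function(path, schedule = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("cannot parse '", path, "': ",
                                         conditionMessage(e)))
  if (!nrow(d)) stop("parse error in '", path, "': file has no data rows")
  need <- c("curve_id", "conc_M", "time_s", "response_RU", "channel")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("parse error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  for (nm in c("conc_M", "time_s", "response_RU")) {
    v <- d[[nm]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("parse error in '", path, "' line ", bad + 1L,
           ": non-numeric value in column '", nm, "'")
    }
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      stop("parse error in '", path, "' line ", bad + 1L,
           ": non-finite value in column '", nm, "'")
    }
  }
  out <- list()
  for (ch in unique(d$channel)) {
    dc <- d[d$channel == ch, ]
    curves <- lapply(split(dc, dc$curve_id), function(g) {
      if (any(diff(g$time_s) <= 0)) {
        bad <- which(diff(g$time_s) <= 0)[1L]
        stop("parse error in '", path, "': time grid of curve '",
             g$curve_id[1L], "' (channel ", ch, ") not strictly increasing ",
             "near line ", as.integer(rownames(g)[bad + 1L]) + 1L)
      }
      uc <- unique(g$conc_M)
      if (length(uc) != 1L)
        stop("parse error in '", path, "': curve '", g$curve_id[1L],
             "' has inconsistent conc_M values")
      sensorgram(g$time_s, g$response_RU, uc, schedule, g$curve_id[1L])
    })
    # keep injection order: descending concentration
    ord <- order(vapply(curves, `[[`, numeric(1), "conc"), decreasing = TRUE)
    out[[ch]] <- sensorgram_series(curves[ord], ch)
  }
  grids <- lapply(out, function(s) s$curves[[1L]]$time)
  if (length(grids) > 1L &&
      !all(vapply(grids[-1L], function(g)
        length(g) == length(grids[[1L]]) && all(g == grids[[1L]]), logical(1))))
    stop("parse error in '", path, "': channels do not share one time grid")
  out
}

fit_report_list <- function(fit) {
  list(schema = "sprkin-fit-report", schema_version = "1.0",
       package_version = as.character(utils::packageVersion("sprkin")),
       kind = fit$kind,
       estimates = as.list(fit$estimates),
       standard_errors = as.list(fit$se),
       offsets = fit$offsets,
       KD = fit$KD, se_KD = fit$se_KD,
       KD2 = fit$KD2, se_KD2 = fit$se_KD2,
       rss = fit$rss, dof = fit$dof, n_obs = fit$n_obs, n_par = fit$n_par,
       converged = fit$converged, seed = fit$seed, starts = fit$starts,
       concentrations_M = fit$concs)
}

#' Serialize a fit result to JSON
#'
#' Writes an `spr_fit` (schema `sprkin-fit-report` v1.0) or a
#' `model_selection` report (schema `sprkin-model-selection` v1.0) to a
#' structured JSON document carrying all estimates, standard errors,
#' derived KD values and residual statistics.
#'
#' @param x an `spr_fit` from [global_fit()] or a `model_selection` from
#'   [compare_models()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(x, path) {
  obj <- if (inherits(x, "spr_fit")) {
    fit_report_list(x)
  } else if (inherits(x, "model_selection")) {
    list(schema = "sprkin-model-selection", schema_version = "1.0",
         package_version = as.character(utils::packageVersion("sprkin")),
         selected = x$selected, rationale = x$rationale,
         table = x$table,
         fits = lapply(x$fits, fit_report_list))
  } else stop("'x' must be an spr_fit or model_selection object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

config_fields <- list(
  kind = c("langmuir_1to1", "heterogeneous_ligand", "bivalent_analyte",
           "heterogeneous_analyte"),
  params = c("ka1", "kd1", "Rmax1", "ka2", "kd2", "Rmax2"),
  schedule = c("t_assoc", "t_dissoc", "dt"),
  concentrations = c("top", "factor", "n", "values"),
  noise = c("sd", "drift", "bulk", "seed"),
  fit = c("starts", "seed", "offsets"))

#' Run configuration
#'
#' Builds and validates the configuration object driving the simulate/fit
#' pipeline: model kind and true parameters (for simulation), phase
#' schedule, concentration ladder (either explicit `values` in M or a
#' `top`/`factor`/`n` serial dilution), noise specification, and fit
#' options. Unknown keys at any level are rejected with a named error, so
#' a config round-trips losslessly through its on-disk YAML/JSON form.
#'
#' @param x a named list (e.g. parsed from YAML/JSON).
#' @return The validated list, class `run_config`.
#' @export
run_config <- function(x) {
  if (!is.list(x)) stop("config must be a named list")
  unknown <- setdiff(names(x), names(config_fields))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(x), c("params", "schedule", "concentrations",
                                    "noise", "fit"))) {
    bad <- setdiff(names(x[[sec]]), config_fields[[sec]])
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(x$kind) && !x$kind %in% config_fields$kind)
    stop("unknown model kind '", x$kind, "' in config; expected one of: ",
         paste(config_fields$kind, collapse = ", "))
  structure(x, class = c("run_config", "list"))
}

#' Read a run configuration from YAML or JSON
#'
#' File format is chosen by extension (`.yaml`/`.yml` or `.json`); both
#' carry the same schema (see [run_config()]).
#'
#' @param path config file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use .yaml, .yml or .json)"))
  run_config(x)
}

#' Write a run configuration
#'
#' @param cfg a `run_config` (or plain named list, validated first).
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- run_config(unclass(cfg))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(unclass(cfg), path),
    json = jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("unsupported config format '.", ext, "'"))
  invisible(path)
}

# Materialize pieces of a run_config into package objects.
config_schedule <- function(cfg) {
  s <- cfg$schedule
  if (is.null(s)) phase_schedule()
  else do.call(phase_schedule, s)
}

config_concs <- function(cfg) {
  cl <- cfg$concentrations
  if (is.null(cl)) serial_dilution(250e-12, 2, 5)
  else if (!is.null(cl$values)) as.numeric(cl$values)
  else serial_dilution(cl$top, cl$factor, cl$n)
}

config_noise <- function(cfg, seed_override = NULL) {
  n <- cfg$noise
  args <- list(sd = n$sd %||% 0.5, drift = n$drift %||% 0,
               bulk = n$bulk %||% 0, seed = n$seed %||% 1L)
  if (!is.null(seed_override)) args$seed <- seed_override
  do.call(noise_spec, args)
}

config_params <- function(cfg) {
  if (is.null(cfg$kind) || is.null(cfg$params))
    stop("config needs 'kind' and 'params' to simulate")
  do.call(kinetic_params, c(list(kind = cfg$kind), cfg$params))
}

config_fit_options <- function(cfg, seed_override = NULL) {
  f <- cfg$fit
  args <- list(starts = f$starts %||% 8L, seed = f$seed %||% 1L,
               offsets = f$offsets %||% FALSE)
  if (!is.null(seed_override)) args$seed <- seed_override
  do.call(fit_options, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
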