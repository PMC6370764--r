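# Run-configuration loading and deterministic trajectory / summary output.
#
# Config dialect: one flat JSON object. JSON (not YAML) so values like
# 0.00046 survive round-trip without implicit coercion. Keys are either
# model-parameter names (see parameters.R) or the reserved run keys below;
# anything else is an error naming the offending key.

.config_keys <- c("model", "initial_state", "t_end", "rtol", "atol",
                  "output_step", "scenario", "out_csv", "out_json")

.config_defaults <- list(model = "healthy", initial_state = NULL,
                         t_end = 160, rtol = 1e-8, atol = 1e-10,
                         output_step = 0.5, scenario = NULL,
                         out_csv = NULL, out_json = NULL)

#' Load a run configuration from a flat JSON file
#'
#' Reads a flat JSON object whose keys are either model-parameter names
#' (overriding the published defaults) or run settings: `model`
#' (`"healthy"`/`"tumor"`), `initial_state` (array of 3 or 4 numbers),
#' `t_end`, `rtol`, `atol`, `output_step`, `scenario`, `out_csv`,
#' `out_json`. Missing parameter keys fall back to the defaults; unknown
#' keys are an error naming the key.
#'
#' @param path path to the JSON file.
#' @return An object of class `flc_config`: list with `params`
#'   (`flc_params`) and the run settings.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"gamma_L": 0.01, "model": "healthy", "t_end": 100}', f)
#' cfg <- load_config(f)
#' cfg$params$gamma_L
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  unknown <- setdiff(names(raw), c(.param_names, .config_keys))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  overrides <- raw[intersect(names(raw), .param_names)]
  for (nm in names(overrides)) {
    if (!is.numeric(overrides[[nm]]) || length(overrides[[nm]]) != 1) {
      stop("config key '", nm, "' must be a single number (model ",
           "parameter)", call. = FALSE)
    }
  }
  cfg <- .config_defaults
  for (nm in intersect(names(raw), .config_keys)) cfg[[nm]] <- raw[[nm]]
  if (!cfg$model %in% c("healthy", "tumor")) {
    stop("config key 'model' must be \"healthy\" or \"tumor\"",
         call. = FALSE)
  }
  for (nm in c("t_end", "rtol", "atol", "output_step")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("config key '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$initial_state)) {
    want <- if (cfg$model == "healthy") 3L else 4L
    if (!is.numeric(cfg$initial_state) ||
        length(cfg$initial_state) != want) {
      stop("config key 'initial_state' must have ", want,
           " numeric components for the ", cfg$model, " model",
           call. = FALSE)
    }
  }
  cfg$params <- do.call(flc_params, overrides)
  cfg$overridden <- names(overrides)
  structure(cfg, class = "flc_config")
}

#' Write a run configuration back to JSON
#'
#' Inverse of [load_config()]: writes only the explicitly overridden
#' parameters plus the run settings, producing a file that loads back to an
#' identical configuration.
#'
#' @param config an `flc_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "flc_config"))
  out <- list()
  for (nm in config$overridden) out[[nm]] <- config$params[[nm]]
  for (nm in .config_keys) {
    if (!is.null(config[[nm]])) out[[nm]] <- config[[nm]]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# fixed 12-significant-digit formatting: below solver tolerance, above
# noise, and byte-deterministic across runs
.fmt_num <- function(x) {
  formatC(x, format = "g", digits = 12)
}

#' Write a trajectory to an annotated CSV file
#'
#' Writes the output grid as CSV with a `#`-prefixed comment header carrying
#' the model id, units, solver settings and full parameter set, then a
#' `t,P,L,F[,T]` header row and one row per grid time. Any threshold
#' crossings attached to the trajectory are appended as `#EVENT` comment
#' lines. Floats are fixed at 12 significant digits, so identical runs give
#' byte-identical files.
#'
#' @param traj an `flc_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "flc_trajectory"))
  vars <- colnames(traj$states)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# model: ", traj$model_id),
    "# units: t days; P percent; L mg/L; F percent; T percent",
    paste0("# solver: lsoda rtol=", .fmt_num(traj$rtol),
           " atol=", .fmt_num(traj$atol),
           " output_step=", .fmt_num(traj$output_step)),
    paste0("# params: ",
           paste(sprintf("%s=%s", names(traj$params),
                         vapply(traj$params, format, character(1),
                                digits = 15)),
                 collapse = " "))
  ), con)
  writeLines(paste(c("t", vars), collapse = ","), con)
  rows <- cbind(traj$times, traj$states)
  writeLines(apply(rows, 1, function(r) {
    paste(.fmt_num(r), collapse = ",")
  }), con)
  for (ev in traj$events) {
    writeLines(paste("#EVENT", ev$variable, .fmt_num(ev$level),
                     .fmt_num(ev$time),
                     paste(.fmt_num(ev$state), collapse = ",")), con)
  }
  invisible(path)
}

#' Read back a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path path to the CSV file.
#' @return A list with `times` and `states` (matrix with named columns);
#'   comment and event lines are skipped.
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  data_lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(data_lines, collapse = "\n"))
  states <- as.matrix(df[, -1, drop = FALSE])
  list(times = df$t, states = states)
}

#' Write a scenario summary as JSON
#'
#' Serialises an `flc_scenario`'s name, summary scalars, convergence or
#' qualitative flags, and solver settings to JSON.
#'
#' @param scenario an `flc_scenario` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "flc_scenario"))
  if (scenario$name == "homeostasis_perturbation") {
    tr <- scenario$trajectories[[1]]
    out <- list(
      scenario = scenario$name,
      target = as.list(scenario$target),
      runs = scenario$summary,
      solver = list(method = "lsoda", rtol = tr$rtol, atol = tr$atol,
                    output_step = tr$output_step)
    )
  } else {
    s <- scenario$summary
    tr <- scenario$trajectory
    out <- list(
      scenario = scenario$name,
      max_L = s$max_L,
      terminal = as.list(s$terminal),
      crossing_L500 = if (is.null(s$crossing_L500)) NULL else list(
        time = s$crossing_L500$time,
        state = as.list(s$crossing_L500$state)),
      crossing_L1000_time = if (is.na(s$crossing_L1000_time)) NULL
        else s$crossing_L1000_time,
      flags = as.list(s$flags),
      solver = list(method = "lsoda", rtol = tr$rtol, atol = tr$atol,
                    output_step = tr$output_step)
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
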