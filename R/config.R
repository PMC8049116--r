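# Declarative run configuration: one nested YAML file whose sections map
# onto the package's constructor arguments. Unknown sections or keys are
# rejected at load time and all physical invariants are enforced by the
# constructors themselves.

.config_builders <- function() {
  list(geometry = reactor_geometry,
       fluid = fluid_properties,
       cell = cell_properties,
       optics = optical_properties,
       flow = flow_field,
       kinetics = kinetic_params,
       oxygen = oxygen_params)
}

.simulation_keys <- c("setpoints_uE", "calibration_case", "hold_hours",
                      "dt_h", "od_center", "od_half_width", "gdcw_per_od",
                      "light_mode", "dom_spacing", "n_particles",
                      "mu_window", "absorption_a", "absorption_b")
.trace_keys <- c("n_particles", "dt", "duration", "record_every", "mode",
                 "setpoint_uE", "calibration_case", "spacing")
.top_keys <- c("run_id", "output_dir", "seed", "verbosity",
               "simulation", "trace", "campaign")

#' Load and validate a run configuration
#'
#' Reads the nested YAML configuration, checks every section and key
#' against the package's parameter surface (unknown keys are an error
#' listing all offenders), and instantiates the validated component
#' records.
#'
#' @param path Path to a YAML configuration file.
#' @return A `pbr_config` list with instantiated components (`geometry`,
#'   `fluid`, `cell`, `optics`, `flow`, `kinetics`, `oxygen`), the raw
#'   `simulation`/`trace`/`campaign` sections, and the top-level scalars.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  builders <- .config_builders()
  offenders <- character(0)

  add_offenders <- function(section, bad) {
    # paste0 maps zero-length inputs to "", so guard explicitly
    if (length(bad)) c(offenders, paste0(section, ".", bad)) else offenders
  }
  offenders <- c(offenders,
                 setdiff(names(raw), c(names(builders), .top_keys)))
  for (sec in intersect(names(raw), names(builders))) {
    offenders <- add_offenders(
      sec, setdiff(names(raw[[sec]]), names(formals(builders[[sec]]))))
  }
  offenders <- add_offenders(
    "simulation", setdiff(names(raw$simulation), .simulation_keys))
  offenders <- add_offenders(
    "trace", setdiff(names(raw$trace), .trace_keys))
  offenders <- add_offenders(
    "campaign", setdiff(names(raw$campaign), names(formals(campaign))))
  if (length(offenders)) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(offenders, collapse = ", ")))
  }

  comps <- purrr::imap(builders, function(fn, sec) {
    args <- raw[[sec]] %||% list()
    do.call(fn, args)
  })
  structure(c(comps,
              list(simulation = raw$simulation %||% list(),
                   trace = raw$trace %||% list(),
                   campaign_section = raw$campaign %||% list(),
                   run_id = raw$run_id %||% "run",
                   output_dir = raw$output_dir %||% ".",
                   seed = raw$seed %||% 1L,
                   verbosity = raw$verbosity %||% 0L,
                   path = path)),
            class = "pbr_config")
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
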