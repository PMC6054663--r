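#' Load a run configuration
#'
#' Reads a YAML configuration and fills defaults for everything that is not
#' specified; an empty file yields the all-defaults configuration.  Every
#' default is a documented model value: knee angle 8.4 degrees, heel lift
#' 16.5% of leg length, constant efficiency 0.25, CoP excursion 0.8 of foot
#' length.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Object of class `"walk_config"`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) list() else raw
  }
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  structure(cfg, class = "walk_config")
}

default_config <- function() {
  list(
    body = list(mass = 70, height = 1.75),
    muscle = list(knee_angle = 8.4, omega_max = 22,
                  efficiency_mode = "constant", eta = 0.25),
    model = list(heel_lift = 0.165, cop_excursion = 0.8,
                 n_segments = 3L, n_samples = 201L),
    grid = list(speed_min = 0.4, speed_max = 2.0, speed_step = 0.05,
                freq_min = 1.0, freq_max = 3.0, freq_step = 0.05),
    efficiency_table = default_efficiency_table()
  )
}

#' Validate a configuration's parameter ranges
#'
#' Checks every parameter against its documented physical range and lists
#' all offending keys in one error.
#' @param cfg A configuration list (classed or not).
#' @return The configuration, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, key) if (!ok) bad <<- c(bad, key)
  chk(cfg$body$mass > 0, "body.mass")
  chk(cfg$body$height > 0, "body.height")
  chk(cfg$muscle$knee_angle >= 0 && cfg$muscle$knee_angle <= 30,
      "muscle.knee_angle")
  chk(cfg$muscle$omega_max > 0, "muscle.omega_max")
  chk(cfg$muscle$eta > 0 && cfg$muscle$eta < 1, "muscle.eta")
  chk(cfg$muscle$efficiency_mode %in% c("constant", "variable"),
      "muscle.efficiency_mode")
  chk(cfg$model$heel_lift >= 0 && cfg$model$heel_lift <= 0.5,
      "model.heel_lift")
  chk(cfg$model$cop_excursion >= 0 && cfg$model$cop_excursion <= 1.2,
      "model.cop_excursion")
  chk(cfg$grid$speed_min > 0 && cfg$grid$speed_max > cfg$grid$speed_min,
      "grid.speed")
  chk(cfg$grid$freq_min > 0 && cfg$grid$freq_max > cfg$grid$freq_min,
      "grid.freq")
  if (length(bad) > 0L)
    stop("invalid configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(cfg)
}

#' Write a configuration back to YAML
#'
#' `load_config(dump_config(cfg, f))` reproduces `cfg` exactly.
#' @param cfg A `"walk_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "walk_config"))
  out <- unclass(cfg)
  out$efficiency_table <- as.list(as.data.frame(out$efficiency_table))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param cfg A `"walk_config"`.
#' @return List with `body`, `muscle`, `speeds`, `frequencies`, and the
#'   solver settings (`heel_lift`, `cop_excursion`, `n_segments`,
#'   `n_samples`).
#' @export
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "walk_config"))
  et <- as.data.frame(cfg$efficiency_table)
  list(
    body = scale_body(cfg$body$mass, cfg$body$height),
    muscle = walk_muscle(knee_angle = cfg$muscle$knee_angle,
                         omega_max = cfg$muscle$omega_max,
                         efficiency_mode = cfg$muscle$efficiency_mode,
                         eta = cfg$muscle$eta,
                         efficiency_table = et),
    speeds = seq(cfg$grid$speed_min, cfg$grid$speed_max,
                 by = cfg$grid$speed_step),
    frequencies = seq(cfg$grid$freq_min, cfg$grid$freq_max,
                      by = cfg$grid$freq_step),
    heel_lift = cfg$model$heel_lift,
    cop_excursion = cfg$model$cop_excursion,
    n_segments = as.integer(cfg$model$n_segments),
    n_samples = as.integer(cfg$model$n_samples)
  )
}
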