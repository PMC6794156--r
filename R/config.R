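# Run configuration: defaults, YAML load/dump and structural validation.

#' Default run configuration
#'
#' Nested list covering fluid properties, the physiological model, aortic and
#' venous pressures, solver settings, the cohort specification and the stent
#' policy. All values can be overridden via a YAML file ([load_config()]).
#'
#' @param seed Integer seed for the cohort and experiment.
#' @return A list of class `ffr_config`.
#' @export
default_config <- function(seed = 20260101) {
  structure(list(
    seed = as.integer(seed),
    fluid = list(mu = 0.0035, rho = 1050),
    physiology = list(myocardial_mass_g = 100, q_scale = 0.013, k = 0.75,
                      hyperemia_factor = 0.24, radius_ref_mm = 1.8,
                      radius_exp = 2.6),
    pa_mmHg = 90, pv_mmHg = 0,
    solver = list(ds_oracle_mm = 0.05, flow_tol_ml_s = 0.05, margin_mm = 2),
    cohort = list(n_vessels = 100, length_range = c(80, 140),
                  inlet_radius_range = c(1.4, 2.2),
                  taper_pct_range = c(10, 30), n_lesions = 2,
                  ds_range = c(40, 85), lesion_len_range = c(8, 25),
                  min_gap = 10, edge_margin_mm = 5, ds = 0.25),
    stent_policy = "both",
    tost_margin = 0.02
  ), class = "ffr_config")
}

config_schema <- function() {
  list(seed = "numeric", fluid = "list", physiology = "list",
       pa_mmHg = "numeric", pv_mmHg = "numeric", solver = "list",
       cohort = "list", stent_policy = "character", tost_margin = "numeric")
}

#' Validate a run configuration
#'
#' Structural check: required keys present, types as expected, stent policy
#' one of `both`, `most_severe`, `proximal`, `distal`.
#'
#' @param config A configuration list.
#' @return The config, invisibly; errors on violation.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  for (key in names(schema)) {
    if (is.null(config[[key]])) {
      stop(sprintf("config is missing key `%s`", key), call. = FALSE)
    }
    ok <- switch(schema[[key]],
                 numeric = is.numeric(config[[key]]),
                 character = is.character(config[[key]]),
                 list = is.list(config[[key]]))
    if (!ok) {
      stop(sprintf("config key `%s` must be %s", key, schema[[key]]),
           call. = FALSE)
    }
  }
  if (!config$stent_policy %in% c("both", "most_severe", "proximal", "distal")) {
    stop("stent_policy must be one of both, most_severe, proximal, distal",
         call. = FALSE)
  }
  if (config$pa_mmHg <= config$pv_mmHg) {
    stop("pa_mmHg must exceed pv_mmHg", call. = FALSE)
  }
  invisible(config)
}

#' Load a configuration from YAML
#'
#' Keys present in the file override the defaults; everything else keeps its
#' default value.
#'
#' @param path YAML file path.
#' @param base Base configuration to override (default [default_config()]).
#' @return A validated `ffr_config`.
#' @export
load_config <- function(path, base = default_config()) {
  user <- yaml::read_yaml(path)
  merged <- utils::modifyList(base, user)
  class(merged) <- "ffr_config"
  validate_config(merged)
  merged
}

#' Dump a configuration as YAML text
#'
#' @param config An `ffr_config`.
#' @return A single YAML string.
#' @export
dump_config <- function(config = default_config()) {
  yaml::as.yaml(unclass(config))
}

config_cohort_spec <- function(config) {
  co <- config$cohort
  cohort_spec(n_vessels = co$n_vessels, seed = config$seed,
              length_range = co$length_range,
              inlet_radius_range = co$inlet_radius_range,
              taper_pct_range = co$taper_pct_range,
              n_lesions = co$n_lesions, ds_range = co$ds_range,
              lesion_len_range = co$lesion_len_range,
              min_gap = co$min_gap, edge_margin_mm = co$edge_margin_mm,
              ds = co$ds)
}

config_fluid <- function(config) {
  fluid_properties(mu = config$fluid$mu, rho = config$fluid$rho)
}

config_physiology <- function(config) {
  p <- config$physiology
  physiology_model(myocardial_mass_g = p$myocardial_mass_g,
                   q_scale = p$q_scale, k = p$k,
                   hyperemia_factor = p$hyperemia_factor,
                   radius_ref_mm = p$radius_ref_mm,
                   radius_exp = p$radius_exp)
}
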