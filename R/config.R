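#' Analysis run configuration
#'
#' Collects every tunable knob of the pipeline in one list: calibration
#' parameters, curve-analysis thresholds, and the condition-to-reference
#' normalization map. Values can be overridden from a YAML file with
#' [read_run_config()]. All quantities are SI internally (metres, newtons,
#' seconds, volts, kelvin).
#'
#' @param temperature Bath temperature in kelvin used by the thermal-noise
#'   spring-constant estimate. Default 298 K.
#' @param spring_constant_range Plausible cantilever stiffness range in N/m;
#'   calibrations outside it are flagged, not rejected. Default `c(0.001, 10)`.
#' @param threshold_fraction Pulling-length threshold as a fraction of the
#'   maximum adhesion force. Default 0.01 (the 1% rule).
#' @param contact_threshold Repulsive force, in newtons, at which the approach
#'   is considered in full contact. Default 15e-9 (15 nN).
#' @param min_run Minimum number of consecutive super-threshold samples for a
#'   span of adhesion to count as an excursion in pulling-length detection;
#'   guards against isolated baseline-noise spikes. Default 3.
#' @param noise_guard Multiple of the estimated baseline-noise SD that an
#'   excursion peak must exceed in pulling-length detection; 0 disables the
#'   guard. Default 5.
#' @param integration_rule Name of the quadrature rule for energy integration;
#'   only `"trapezoid"` is implemented (sampled grid, no resampling).
#' @param beta Dimensionless correction factor applied to the equipartition
#'   spring-constant estimate; 1 is the uncorrected form, 0.817 is the common
#'   first-flexural-mode literature value.
#' @param stress_radius Which radius enters the outer-fibre bending stress for
#'   fracture toughness: `"outer"` (default) or `"mean"`.
#' @param reference_map Named character vector mapping substrate to its
#'   reference solution for energy normalization.
#' @param equal_variance Logical; use the pooled-variance (Student) form of the
#'   unpaired t-test. Default TRUE.
#' @param seed Integer seed recorded with the run.
#'
#' @return A list of class `"run_config"`.
#' @seealso [read_run_config()]
#' @export
#' @examples
#' cfg <- run_config(threshold_fraction = 0.02)
#' cfg$contact_threshold
run_config <- function(temperature = 298,
                       spring_constant_range = c(0.001, 10),
                       threshold_fraction = 0.01,
                       contact_threshold = 15e-9,
                       min_run = 3L,
                       noise_guard = 5,
                       integration_rule = "trapezoid",
                       beta = 1,
                       stress_radius = c("outer", "mean"),
                       reference_map = c(mica = "EDTA", HA = "H2O"),
                       equal_variance = TRUE,
                       seed = 1L) {
  stress_radius <- match.arg(stress_radius)
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1).")
  }
  if (!is.numeric(contact_threshold) || contact_threshold <= 0) {
    abort("`contact_threshold` must be a positive force in newtons.")
  }
  if (!identical(integration_rule, "trapezoid")) {
    abort(sprintf("unknown integration rule '%s'", integration_rule))
  }
  if (length(reference_map) < 1L || is.null(names(reference_map)) ||
      any(!nzchar(names(reference_map)))) {
    abort("`reference_map` must be a named substrate -> solution vector.")
  }
  structure(
    list(
      temperature = temperature,
      spring_constant_range = spring_constant_range,
      threshold_fraction = threshold_fraction,
      contact_threshold = contact_threshold,
      min_run = as.integer(min_run),
      noise_guard = noise_guard,
      integration_rule = integration_rule,
      beta = beta,
      stress_radius = stress_radius,
      reference_map = reference_map,
      equal_variance = isTRUE(equal_variance),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file fall back to the [run_config()] defaults.
#'
#' @param path Path to a YAML file of configuration keys.
#' @param ... Overrides applied after the file is read.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$reference_map)) {
    vals$reference_map <- unlist(vals$reference_map)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warn(sprintf("ignoring unknown config keys: %s",
                 paste(unknown, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (key in setdiff(names(x), "reference_map")) {
    cat(sprintf("  %-22s %s\n", key, paste(format(x[[key]]), collapse = ", ")))
  }
  cat(sprintf("  %-22s %s\n", "reference_map",
              paste(names(x$reference_map), x$reference_map,
                    sep = " -> ", collapse = "; ")))
  invisible(x)
}
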