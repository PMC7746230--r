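#' Read and write calibration artifacts
#'
#' A calibration is stored as a small plain-text `key=value` artifact so an
#' analysis run can reference the calibration it used.
#'
#' @param calibration A [cantilever_calibration()].
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a [cantilever_calibration()].
#' @export
write_calibration <- function(calibration, path) {
  check_calibration(calibration)
  writeLines(c(
    sprintf("invols=%.17g", calibration$invols),
    sprintf("spring_constant=%.17g", calibration$spring_constant),
    sprintf("temperature=%.17g", calibration$temperature),
    sprintf("provenance=%s", calibration$provenance)
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  vals <- setNames(lapply(kv, function(p) parse_header_value(p[2])),
                   vapply(kv, `[[`, character(1), 1))
  cantilever_calibration(
    invols = vals$invols,
    spring_constant = vals$spring_constant,
    temperature = vals$temperature %||% 298,
    provenance = vals$provenance %||% "post_functionalization"
  )
}

#' Read and write thermal deflection series
#'
#' One deflection value (metres) per line, preceded by a `#` header carrying
#' the sampling rate and temperature.
#'
#' @param series Numeric series (see [generate_thermal_series()]).
#' @param path File path.
#' @return `write_thermal_series()` returns `path` invisibly;
#'   `read_thermal_series()` the numeric series with attributes restored.
#' @export
write_thermal_series <- function(series, path) {
  writeLines(c(
    sprintf("# sampling_rate=%.17g", attr(series, "sampling_rate") %||% NA),
    sprintf("# temperature=%.17g", attr(series, "temperature") %||% 298),
    sprintf("%.17g", as.numeric(series))
  ), path)
  invisible(path)
}

#' @rdname write_thermal_series
#' @export
read_thermal_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  md <- list()
  kv <- regmatches(lines[hdr], regexec("^#\\s*([A-Za-z_]+)=(.*)$", lines[hdr]))
  for (m in kv) if (length(m) == 3L) md[[m[2]]] <- as.numeric(m[3])
  x <- as.numeric(lines[!hdr & nzchar(lines)])
  attr(x, "sampling_rate") <- md$sampling_rate
  attr(x, "temperature") <- md$temperature
  x
}
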