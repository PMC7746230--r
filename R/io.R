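#' Force-curve file dialects
#'
#' Instrument ASCII exports vary; a dialect declares how to read one: the
#' delimiter, the column order, and the multiplicative factors taking each
#' column to SI units (seconds, metres, volts). Everything downstream of the
#' reader is SI. Undeclared layouts are rejected loudly.
#'
#' @param delimiter `"whitespace"` or `"comma"`.
#' @param columns Column order in the file; a permutation of `time`,
#'   `z_position`, `deflection_raw` and optionally `segment`.
#' @param time_unit,z_unit,deflection_unit Factors converting file values to
#'   s, m and V (e.g. `z_unit = 1e-9` for a file in nanometres).
#' @return A list of class `"curve_dialect"`.
#' @export
curve_dialect <- function(delimiter = c("whitespace", "comma"),
                          columns = c("time", "z_position", "deflection_raw"),
                          time_unit = 1, z_unit = 1, deflection_unit = 1) {
  delimiter <- match.arg(delimiter)
  required <- c("time", "z_position", "deflection_raw")
  if (!all(required %in% columns) ||
      !all(columns %in% c(required, "segment"))) {
    abort(paste("dialect columns must be a permutation of time, z_position,",
                "deflection_raw (and optionally segment)"))
  }
  structure(list(delimiter = delimiter, columns = columns,
                 time_unit = time_unit, z_unit = z_unit,
                 deflection_unit = deflection_unit),
            class = "curve_dialect")
}

parse_header_value <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

#' Read an ASCII force-curve file
#'
#' Reads one plain-text force-curve export: an optional `#`-prefixed header
#' block of `key=value` metadata lines followed by delimited numeric columns
#' in the order the dialect declares. Values are converted to SI units by the
#' dialect factors. Malformed lines raise an error naming the line number;
#' non-monotone time is a validation error naming the offending line.
#'
#' @param path Path to the file.
#' @param dialect A [curve_dialect()].
#' @return A [force_cycle()]; header keys populate the metadata, and rows
#'   without a segment column carry `segment = "unknown"`.
#' @export
read_force_curve <- function(path, dialect = curve_dialect()) {
  if (!inherits(dialect, "curve_dialect")) {
    abort("`dialect` must be a curve_dialect")
  }
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  is_header <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  header <- lines[is_header]
  data_idx <- which(!is_header & !is_blank)
  if (length(data_idx) < 2L) {
    abort(sprintf("'%s' has fewer than 2 data rows", path))
  }
  metadata <- list()
  kv <- regmatches(header, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$",
                                   header))
  for (m in kv) {
    if (length(m) == 3L) metadata[[m[2]]] <- parse_header_value(m[3])
  }
  ncol_expected <- length(dialect$columns)
  split_line <- function(line) {
    if (dialect$delimiter == "comma") {
      strsplit(line, ",", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(line), "\\s+")[[1]]
    }
  }
  fields <- lapply(lines[data_idx], split_line)
  nf <- lengths(fields)
  if (any(nf != ncol_expected)) {
    bad <- which(nf != ncol_expected)[1]
    abort(sprintf("parse error at line %d of '%s': expected %d fields, found %d",
                  data_idx[bad], path, ncol_expected, nf[bad]))
  }
  mat <- do.call(rbind, fields)
  cols <- setNames(as.data.frame(mat, stringsAsFactors = FALSE),
                   dialect$columns)
  numeric_cols <- c("time", "z_position", "deflection_raw")
  for (nm in numeric_cols) {
    v <- suppressWarnings(as.numeric(cols[[nm]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("parse error at line %d of '%s': non-numeric %s value '%s'",
                    data_idx[bad], path, nm, cols[[nm]][bad]))
    }
    cols[[nm]] <- v
  }
  time <- cols$time * dialect$time_unit
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1] + 1L
    abort(sprintf("validation error at line %d of '%s': time is not strictly increasing",
                  data_idx[bad], path))
  }
  force_cycle(
    time = time,
    z_position = cols$z_position * dialect$z_unit,
    deflection_raw = cols$deflection_raw * dialect$deflection_unit,
    segment = if ("segment" %in% dialect$columns) cols$segment else "unknown",
    metadata = metadata
  )
}

fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a force cycle as an ASCII curve file
#'
#' Emits the package's canonical curve format: a `#` header block of
#' `key=value` metadata lines, then whitespace-delimited SI columns (time [s],
#' z_position [m], deflection_raw [V], segment). Numeric values are printed
#' with 17 significant digits so a read-back reproduces them bit-identically.
#'
#' @param cycle A [force_cycle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(cycle, path) {
  if (!inherits(cycle, "force_cycle")) abort("`cycle` must be a force_cycle")
  md <- cycle_metadata(cycle)
  header <- c("# columns=time z_position deflection_raw segment",
              "# units=s m V -",
              purrr::imap_chr(md, function(v, k)
                sprintf("# %s=%s", k,
                        if (is.numeric(v)) fmt_full(v) else as.character(v))))
  rows <- sprintf("%s %s %s %s",
                  fmt_full(cycle$time), fmt_full(cycle$z_position),
                  fmt_full(cycle$deflection_raw), cycle$segment)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' The canonical dialect of files written by [write_force_curve()]
#' @return A [curve_dialect()].
#' @export
canonical_dialect <- function() {
  curve_dialect(delimiter = "whitespace",
                columns = c("time", "z_position", "deflection_raw", "segment"))
}

metric_units <- c(
  max_force = "N", pulling_length = "m", energy = "J", P_max = "N",
  span = "m", R_outer = "m", R_inner = "m", half_crack_angle = "deg",
  Kc = "MPa.m^0.5", bending_stress = "Pa", crack_length = "m",
  second_moment = "m^4", rm = "m", thickness = "m",
  absorbance = "AU", protein = "ng", level = "AU/ng", value = "unit",
  mean_energy = "J", sd_energy = "J", se_energy = "J"
)

#' Write a metrics table as delimited text
#'
#' One row per record, stable column order, units for known quantity columns
#' encoded in a `#` comment line above the CSV header. Numeric columns round-
#' trip bit-identically through [read_metrics_table()].
#'
#' @param metrics Non-empty data frame (per-pull metrics, toughness results,
#'   summaries, ...).
#' @param path Output path.
#' @return The number of rows written, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  if (!nrow(metrics)) abort("refusing to write an empty metrics table")
  units <- metric_units[names(metrics)]
  units[is.na(units)] <- "-"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s",
                     paste(names(metrics), unname(units), sep = "=",
                           collapse = " ")), con)
  out <- dplyr::mutate(as.data.frame(metrics),
                       dplyr::across(dplyr::where(is.numeric), fmt_full))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(nrow(metrics))
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  # base read.csv: correctly rounded numeric parsing for exact round-trips
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}
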