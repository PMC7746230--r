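#' Force-curve cycles
#'
#' A force cycle is one approach/dwell/retract acquisition, stored as a tibble
#' of class `"force_cycle"` with columns `time` (s), `z_position` (m, piezo
#' extension increasing toward the surface on approach), `deflection_raw` (V)
#' and `segment` (`"approach"`, `"dwell"`, `"retract"` or `"unknown"`).
#' Acquisition metadata (velocities, substrate, solution, pH, protein state)
#' travels in the `"metadata"` attribute; [deflection_to_force()] adds `force`
#' (N) and `separation_raw` (m) columns.
#'
#' @param time,z_position,deflection_raw Numeric columns of equal length >= 2.
#' @param segment Optional character segment labels (recycled if length 1).
#' @param metadata Named list of acquisition metadata.
#' @return A `force_cycle` tibble.
#' @export
force_cycle <- function(time, z_position, deflection_raw,
                        segment = "unknown", metadata = list()) {
  n <- length(time)
  if (n < 2L) abort("a force cycle needs at least 2 samples")
  if (length(z_position) != n || length(deflection_raw) != n) {
    abort("time, z_position and deflection_raw must have equal length")
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    abort(sprintf("time must be strictly increasing; violated at sample %d", bad))
  }
  if (length(segment) == 1L) segment <- rep(segment, n)
  segment <- as.character(segment)
  ok <- segment %in% c("approach", "dwell", "retract", "unknown")
  if (!all(ok)) {
    abort(sprintf("unknown segment label '%s'", segment[!ok][1]))
  }
  out <- tibble::tibble(time = as.numeric(time),
                        z_position = as.numeric(z_position),
                        deflection_raw = as.numeric(deflection_raw),
                        segment = segment)
  new_force_cycle(out, metadata = metadata)
}

new_force_cycle <- function(df, metadata = list(), calibrated = FALSE) {
  structure(df,
            metadata = metadata,
            calibrated = calibrated,
            class = c("force_cycle", class(tibble::tibble())))
}

#' @export
print.force_cycle <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<force_cycle> %d samples (%s)%s\n",
              nrow(x),
              paste(unique(x$segment), collapse = "/"),
              if (isTRUE(attr(x, "calibrated"))) ", calibrated" else ""))
  if (length(md)) {
    cat("  metadata:", paste(names(md), vapply(md, function(v)
      paste(format(v), collapse = ","), character(1)),
      sep = "=", collapse = "  "), "\n")
  }
  NextMethod()
}

#' Metadata of a force cycle
#' @param cycle A [force_cycle()].
#' @return Named list of metadata key-value pairs.
#' @export
cycle_metadata <- function(cycle) attr(cycle, "metadata") %||% list()

#' @describeIn force_cycle Diagnostic plot: deflection (or calibrated force)
#'   versus piezo position, coloured by segment.
#' @param object A `force_cycle`.
#' @param ... Unused.
#' @export
autoplot.force_cycle <- function(object, ...) {
  calibrated <- isTRUE(attr(object, "calibrated"))
  y <- if (calibrated) "force" else "deflection_raw"
  ylab <- if (calibrated) "force [N]" else "deflection [V]"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$z_position, y = .data[[y]],
                               colour = .data$segment)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "piezo position [m]", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}
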