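#' Split a cycle into approach and retraction parts
#'
#' If segment labels are present they are honoured (dwell samples belong to
#' neither part). Unlabelled cycles are split at the piezo turning point
#' (closest approach); a monotone piezo trace cannot be split and raises an
#' error.
#'
#' @param cycle A [force_cycle()], raw or calibrated.
#' @return List with elements `approach` and `retract`, both force cycles.
#' @export
split_curve <- function(cycle) {
  if (!inherits(cycle, "force_cycle")) abort("`cycle` must be a force_cycle")
  if (nrow(cycle) < 4L) abort("cycle too short to split (need >= 4 samples)")
  md <- cycle_metadata(cycle)
  cal <- isTRUE(attr(cycle, "calibrated"))
  subcycle <- function(rows) {
    out <- new_force_cycle(tibble::as_tibble(cycle)[rows, ],
                           metadata = md, calibrated = cal)
    attr(out, "calibration") <- attr(cycle, "calibration")
    out
  }
  if (any(cycle$segment != "unknown")) {
    app <- which(cycle$segment == "approach")
    ret <- which(cycle$segment == "retract")
    if (!length(app) || !length(ret)) {
      abort("labelled cycle is missing an approach or retract segment")
    }
    return(list(approach = subcycle(app), retract = subcycle(ret)))
  }
  z <- cycle$z_position
  # Turning point of the piezo trace: extremum in the approach direction.
  apex <- if (z[1] <= max(z) && z[length(z)] <= max(z) &&
              which.max(z) %in% 2:(length(z) - 1L)) {
    which.max(z)
  } else if (which.min(z) %in% 2:(length(z) - 1L)) {
    which.min(z)
  } else {
    abort("piezo position is monotone; cycle cannot be split")
  }
  list(approach = subcycle(seq_len(apex)),
       retract = subcycle(seq.int(apex, length(z))))
}

new_retraction_segment <- function(separation, force, cycle_id = NA_character_,
                                   rejected = NA_character_,
                                   contact_index = NA_integer_) {
  structure(
    tibble::tibble(separation = separation, force = force),
    cycle_id = cycle_id,
    rejected = rejected,
    contact_index = contact_index,
    class = c("retraction_segment", class(tibble::tibble()))
  )
}

#' Align a calibrated retraction trace to its contact point
#'
#' The contact point is the zero-crossing of force at the end of the initial
#' repulsive span of the retraction trace (the last zero-crossing before
#' adhesion onset), located by linear interpolation between the bracketing
#' samples. Both axes are shifted so that point is (0, 0); samples still in
#' repulsive contact keep their (now negative) separation and are excluded
#' from energy integration downstream. Traces with no such crossing
#' (all-repulsive or all-adhesive) are returned flagged as rejected rather
#' than raising an error.
#'
#' @param retraction A calibrated retract-part [force_cycle()] (with `force`
#'   and `separation_raw` columns), or a two-column data frame of
#'   `separation`/`force`.
#' @param cycle_id Identifier carried into the result.
#' @return A `retraction_segment` tibble (`separation`, `force`, sorted by
#'   separation) with attributes `rejected` (NA or a reason) and `cycle_id`.
#' @export
find_contact_point <- function(retraction, cycle_id = NA_character_) {
  if (inherits(retraction, "force_cycle")) {
    if (!isTRUE(attr(retraction, "calibrated"))) {
      abort("retraction cycle must be calibrated first (see deflection_to_force)")
    }
    s <- retraction$separation_raw
    f <- retraction$force
  } else {
    s <- retraction$separation
    f <- retraction$force
    if (is.null(s) || is.null(f)) {
      abort("need `separation` and `force` columns")
    }
  }
  ord <- order(s)  # time order and separation order coincide up to noise
  reject <- function(reason) {
    new_retraction_segment(sort(s) - min(s), f[ord], cycle_id = cycle_id,
                           rejected = reason)
  }
  if (all(f >= 0)) return(reject("all_repulsive"))
  if (all(f <= 0)) return(reject("all_adhesive"))
  # First transition from repulsive (> 0) to non-positive along the pull.
  trans <- which(f[-length(f)] > 0 & f[-1] <= 0)
  if (!length(trans)) return(reject("no_contact"))
  j <- trans[1]
  s0 <- if (f[j + 1] == 0) s[j + 1] else {
    s[j] + f[j] * (s[j + 1] - s[j]) / (f[j] - f[j + 1])
  }
  seg <- new_retraction_segment((s - s0)[ord], f[ord], cycle_id = cycle_id,
                                contact_index = j)
  seg
}

segment_rejected <- function(segment) {
  r <- attr(segment, "rejected")
  !is.na(r %||% NA_character_)
}

#' Maximum adhesion force of a retraction segment
#'
#' The magnitude of the most negative force over non-negative separations
#' (the Y-minimum of the contact-aligned retraction curve). A segment with no
#' adhesion returns 0.
#'
#' @param segment A contact-aligned `retraction_segment`
#'   (see [find_contact_point()]).
#' @return One-row tibble: `max_force` (N, >= 0) and `separation_at_max` (m).
#' @export
max_adhesion_force <- function(segment) {
  stopifnot(inherits(segment, "retraction_segment"))
  free <- segment$separation >= 0
  if (!any(free) || min(segment$force[free]) >= 0) {
    return(tibble::tibble(max_force = 0, separation_at_max = 0))
  }
  f <- segment$force[free]
  s <- segment$separation[free]
  i <- which.min(f)
  tibble::tibble(max_force = -f[i], separation_at_max = s[i])
}

#' Pulling length of a retraction segment
#'
#' The separation span, from contact, over which adhesion exceeds
#' `threshold_fraction` of the maximum adhesion force: operationally, the
#' separation at the end of the last super-threshold adhesion excursion
#' (where the adhesion last drops below the threshold for good). To keep
#' baseline noise beyond the final rupture from stretching the length, an
#' excursion must (a) contain at least `min_run` consecutive super-threshold
#' samples and (b) peak above `noise_guard` times a robust noise estimate
#' (MAD of the force increments / sqrt(2)); on noise-free data both guards
#' are inert and the literal threshold rule is recovered.
#'
#' @inheritParams max_adhesion_force
#' @param max_force Maximum adhesion force magnitude in newtons (> 0; a zero
#'   maximum force returns length 0).
#' @param threshold_fraction Fraction of `max_force` defining detectable
#'   adhesion. Default 0.01.
#' @param min_run Minimum excursion run length in samples. Default 3.
#' @param noise_guard Excursion peaks must exceed this multiple of the
#'   estimated baseline noise SD. Default 5; 0 disables the guard.
#' @return Pulling length in metres.
#' @export
pulling_length <- function(segment, max_force, threshold_fraction = 0.01,
                           min_run = 3L, noise_guard = 5) {
  stopifnot(inherits(segment, "retraction_segment"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1)")
  }
  if (max_force <= 0) return(0)
  thr <- threshold_fraction * max_force
  over <- segment$force <= -thr & segment$separation >= 0
  if (!any(over)) return(0)
  sigma <- stats::mad(diff(segment$force)) / sqrt(2)
  floor_level <- if (noise_guard > 0) max(thr, noise_guard * sigma) else thr
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peak_ok <- vapply(seq_along(runs$values), function(i) {
    runs$values[i] &&
      min(segment$force[starts[i]:ends[i]]) <= -floor_level
  }, logical(1))
  keep <- peak_ok & runs$lengths >= min_run
  if (!any(keep)) keep <- peak_ok
  if (!any(keep)) keep <- runs$values  # all spikes sub-floor: literal rule
  segment$separation[ends[max(which(keep))]]
}

#' Dissipated energy of a retraction segment
#'
#' Trapezoidal integral of the adhesive force magnitude over separation from
#' the contact point to the pulling length: the area enclosed between the
#' retraction curve and the zero-force axis. Only adhesive (negative-force)
#' spans contribute; brief positive overshoots inside the window count as
#' zero, so baseline noise cannot cancel real work. The integral runs on the
#' sampled grid as-is (no resampling) and is reported as a positive energy.
#'
#' @inheritParams max_adhesion_force
#' @param pulling_length Upper integration bound in metres
#'   (see [pulling_length()]).
#' @return Dissipated energy in joules (>= 0).
#' @export
energy_dissipation <- function(segment, pulling_length) {
  stopifnot(inherits(segment, "retraction_segment"))
  if (pulling_length < 0) abort("pulling_length must be non-negative")
  if (pulling_length == 0) return(0)
  s <- segment$separation
  eps <- 1e-6 * max(diff(sort(s)), 0) + 1e-15
  if (pulling_length > max(s) + eps) {
    abort("pulling_length exceeds the sampled separation span")
  }
  inside <- s >= -eps & s <= pulling_length + eps
  if (sum(inside) < 2L) return(0)
  x <- s[inside]
  y <- pmax(0, -segment$force[inside])
  pracma::trapz(x, y)
}

#' Process one force cycle into per-pull metrics
#'
#' The full chain: calibrate (if raw), split, contact-align, then maximum
#' adhesion force, pulling length and dissipated energy. Cycles that fail a
#' stage are returned as rejection records (one row, `accepted = FALSE`, with
#' the reason) rather than errors, so a batch keeps its bookkeeping.
#'
#' @param cycle A [force_cycle()] (raw or already calibrated).
#' @param calibration A [cantilever_calibration()]; required for raw cycles.
#' @param config A [run_config()].
#' @param cycle_id Identifier for the output row.
#' @return One-row tibble: `cycle_id`, `accepted`, `reason`, `max_force` (N),
#'   `pulling_length` (m), `energy` (J), `n_points`, plus any condition
#'   metadata fields (`substrate`, `solution`, `ph`, `opn_state`) present on
#'   the cycle.
#' @export
process_curve <- function(cycle, calibration = NULL, config = run_config(),
                          cycle_id = NA_character_) {
  if (!inherits(cycle, "force_cycle")) abort("`cycle` must be a force_cycle")
  if (!isTRUE(attr(cycle, "calibrated"))) {
    if (is.null(calibration)) {
      abort("raw cycles need a `cantilever_calibration`")
    }
    cycle <- deflection_to_force(cycle, calibration)
  }
  md <- cycle_metadata(cycle)
  condition_cols <- md[intersect(c("substrate", "solution", "ph", "opn_state"),
                                 names(md))]
  finish <- function(accepted, reason, max_force, pl, energy, n_points) {
    row <- tibble::tibble(cycle_id = cycle_id, accepted = accepted,
                          reason = reason, max_force = max_force,
                          pulling_length = pl, energy = energy,
                          n_points = n_points)
    if (length(condition_cols)) {
      row <- dplyr::bind_cols(row, tibble::as_tibble(condition_cols))
    }
    row
  }
  ret <- if (all(cycle$segment == "retract")) cycle else {
    parts <- tryCatch(split_curve(cycle), error = function(e) NULL)
    if (is.null(parts)) {
      return(finish(FALSE, "unsplittable", NA_real_, NA_real_, NA_real_,
                    nrow(cycle)))
    }
    parts$retract
  }
  seg <- find_contact_point(ret, cycle_id = cycle_id)
  if (segment_rejected(seg)) {
    return(finish(FALSE, attr(seg, "rejected"), NA_real_, NA_real_, NA_real_,
                  nrow(seg)))
  }
  mf <- max_adhesion_force(seg)
  pl <- pulling_length(seg, mf$max_force,
                       threshold_fraction = config$threshold_fraction,
                       min_run = config$min_run,
                       noise_guard = config$noise_guard)
  en <- energy_dissipation(seg, pl)
  finish(TRUE, NA_character_, mf$max_force, pl, en, nrow(seg))
}

#' Process a batch of force cycles
#'
#' @param cycles List of [force_cycle()]s (raw or calibrated).
#' @inheritParams process_curve
#' @return Tibble with one [process_curve()] row per cycle; `cycle_id`
#'   defaults to the list names or the index.
#' @export
process_curves <- function(cycles, calibration = NULL, config = run_config()) {
  if (inherits(cycles, "force_cycle")) cycles <- list(cycles)
  ids <- names(cycles) %||% as.character(seq_along(cycles))
  ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
  purrr::map2_dfr(cycles, ids, function(cyc, id) {
    process_curve(cyc, calibration = calibration, config = config,
                  cycle_id = id)
  })
}
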