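#' Cantilever calibration
#'
#' Bundles the two conversion factors taking a raw photodiode signal to force:
#' the inverse optical lever sensitivity (InvOLS, metres of tip deflection per
#' volt) and the spring constant k (N/m). `provenance` records whether the
#' spring constant was measured before or after tip functionalization; the
#' post-functionalization value is the one applied downstream when both exist.
#'
#' @param invols Inverse optical lever sensitivity, m/V (> 0).
#' @param spring_constant Cantilever stiffness k, N/m (> 0).
#' @param temperature Temperature at calibration, kelvin.
#' @param provenance `"pre_functionalization"` or `"post_functionalization"`.
#' @param k_range Plausible stiffness range in N/m; a value outside it sets
#'   the `flagged` field (with a warning) but is not rejected.
#' @return A list of class `"cantilever_calibration"`.
#' @export
#' @examples
#' cal <- cantilever_calibration(invols = 50e-9, spring_constant = 0.006)
cantilever_calibration <- function(invols, spring_constant,
                                   temperature = 298,
                                   provenance = c("post_functionalization",
                                                  "pre_functionalization"),
                                   k_range = c(0.001, 10)) {
  provenance <- match.arg(provenance)
  if (!is.numeric(invols) || invols <= 0) abort("invols must be positive")
  if (!is.numeric(spring_constant) || spring_constant <= 0) {
    abort("spring_constant must be positive")
  }
  flagged <- spring_constant < k_range[1] || spring_constant > k_range[2]
  if (flagged) {
    warn(sprintf("spring constant %.3g N/m lies outside the plausible range [%g, %g] N/m",
                 spring_constant, k_range[1], k_range[2]))
  }
  structure(
    list(invols = invols, spring_constant = spring_constant,
         temperature = temperature, provenance = provenance,
         flagged = flagged),
    class = "cantilever_calibration"
  )
}

check_calibration <- function(calibration) {
  if (!inherits(calibration, "cantilever_calibration")) {
    abort("a `cantilever_calibration` object is required")
  }
  invisible(calibration)
}

#' @export
print.cantilever_calibration <- function(x, ...) {
  cat(sprintf("<cantilever_calibration> InvOLS = %.4g nm/V, k = %.4g N/m (%s%s)\n",
              x$invols * 1e9, x$spring_constant, x$provenance,
              if (x$flagged) ", FLAGGED" else ""))
  invisible(x)
}

# Terminal contiguous loading span of an approach curve: samples where the
# deflection exceeds 10% of its maximum, extended to the end of the approach.
loading_region <- function(z, deflection) {
  thr <- 0.1 * max(deflection)
  above <- deflection > thr
  if (!any(above)) return(integer())
  last_below <- max(c(0L, which(!above)))
  seq.int(last_below + 1L, length(z))
}

#' Fit the inverse optical lever sensitivity from stiff-surface curves
#'
#' For each curve, an ordinary least-squares line is fitted to the loading
#' (contact) part of deflection versus piezo position; the slope (V/m) is
#' inverted to a per-curve InvOLS (m/V) and the mean across curves is the
#' calibration value. The loading part is the contiguous terminal span of the
#' approach where the deflection exceeds 10% of its maximum.
#'
#' @param curves A list of raw approach [force_cycle()]s acquired on a
#'   nominally infinitely stiff surface (typically 10).
#' @return A list of class `"invols_fit"`: `invols` (m/V, mean across
#'   curves), `per_curve` tibble (curve, slope V/m, invols m/V, n_loading),
#'   `sd` of the per-curve estimates.
#' @export
fit_invols <- function(curves) {
  if (inherits(curves, "force_cycle")) curves <- list(curves)
  if (!length(curves)) abort("need at least one stiff-surface curve")
  per <- purrr::map_dfr(seq_along(curves), function(i) {
    cyc <- curves[[i]]
    app <- cyc[cyc$segment %in% c("approach", "unknown"), ]
    idx <- loading_region(app$z_position, app$deflection_raw)
    if (length(idx) < 5L) {
      abort(sprintf("curve %d: loading region has fewer than 5 samples", i))
    }
    fit <- lm(deflection_raw ~ z_position, data = app[idx, ])
    slope <- unname(coef(fit)[2])  # V/m
    if (slope <= 0) {
      abort(sprintf("curve %d: negative loading slope; check z orientation", i))
    }
    tibble::tibble(curve = i, slope = slope, invols = 1 / slope,
                   n_loading = length(idx))
  })
  structure(
    list(invols = mean(per$invols), per_curve = per,
         sd = if (nrow(per) > 1) sd(per$invols) else NA_real_),
    class = "invols_fit"
  )
}

#' @export
print.invols_fit <- function(x, ...) {
  cat(sprintf("<invols_fit> InvOLS = %.5g nm/V (mean of %d curves, sd %.3g nm/V)\n",
              x$invols * 1e9, nrow(x$per_curve),
              (x$sd %||% NA_real_) * 1e9))
  invisible(x)
}

#' @rdname fit_invols
#' @param x An `invols_fit`.
#' @param ... Unused.
#' @export
tidy.invols_fit <- function(x, ...) x$per_curve

#' @rdname fit_invols
#' @export
glance.invols_fit <- function(x, ...) {
  tibble::tibble(invols = x$invols, sd = x$sd, n_curves = nrow(x$per_curve))
}

#' Spring constant by the thermal-noise method
#'
#' Equipartition estimate from the variance of the free cantilever's thermal
#' deflection fluctuations: `k = beta * k_B * T / Var(deflection)`. `beta` is
#' a documented correction factor for the first flexural mode (1 by default,
#' i.e. the uncorrected equipartition form; 0.817 is the common literature
#' value, selectable via [run_config()]).
#'
#' @param deflection_series Deflection series in metres, length >= 1e4.
#' @param temperature Temperature in kelvin (taken from the series attribute
#'   when present).
#' @param beta Correction factor. Default 1.
#' @return Spring constant in N/m.
#' @export
thermal_spring_constant <- function(deflection_series,
                                    temperature = NULL, beta = 1) {
  if (is.null(temperature)) {
    temperature <- attr(deflection_series, "temperature") %||% 298
  }
  if (temperature <= 0) abort("temperature must be positive")
  if (length(deflection_series) < 1e4) {
    abort("thermal series must have at least 1e4 samples")
  }
  v <- var(as.numeric(deflection_series))
  if (!is.finite(v) || v <= 0) abort("deflection series has zero or invalid variance")
  beta * .kB * temperature / v
}

#' Convert a raw cycle to calibrated force and separation
#'
#' Applies the calibration chain: `force = k * InvOLS * deflection_raw` and
#' tip-sample separation `= (z_contact - z_position) + InvOLS *
#' deflection_raw`, with the sign convention that separation increases away
#' from the surface (`z_position` increases toward it on approach). The
#' separation origin is provisional (referenced to the maximum piezo
#' extension); [find_contact_point()] fixes the true origin.
#'
#' @param cycle A raw [force_cycle()].
#' @param calibration A [cantilever_calibration()].
#' @return The cycle with `force` (N) and `separation_raw` (m) columns added
#'   and the calibration recorded as an attribute.
#' @export
deflection_to_force <- function(cycle, calibration) {
  if (!inherits(cycle, "force_cycle")) abort("`cycle` must be a force_cycle")
  check_calibration(calibration)
  defl_m <- calibration$invols * cycle$deflection_raw
  force <- calibration$spring_constant * defl_m
  z_ref <- max(cycle$z_position)
  out <- tibble::as_tibble(cycle)
  out$force <- force
  out$separation_raw <- (z_ref - cycle$z_position) + defl_m
  res <- new_force_cycle(out, metadata = cycle_metadata(cycle),
                         calibrated = TRUE)
  attr(res, "calibration") <- calibration
  res
}
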