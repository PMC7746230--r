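#' Pull scenarios: ground-truth descriptions of synthetic retraction curves
#'
#' A pull scenario specifies the adhesive events of a synthetic retraction:
#' each rupture event rises from the previous rupture position to its contour
#' length, where the force drops to baseline instantaneously. Two rising-limb
#' shapes are available: `"triangle"` (linear ramp; analytic area
#' `peak * base / 2`) and `"wlc"` (a concave worm-like-chain-style limb with a
#' closed-form area). Only the enclosed area matters downstream, so the shape
#' switch exists to let tests use exact analytic areas.
#'
#' Contour lengths are snapped to the sampling grid so that each instantaneous
#' rupture drop coincides with a sampled point; the stored ground truth refers
#' to the snapped positions.
#'
#' @param contour_length Numeric vector of rupture positions in metres,
#'   strictly increasing, all below `max_separation`. May be empty.
#' @param peak_adhesion Matching vector of event peak forces in newtons,
#'   stored as positive magnitudes (generated force is negative).
#' @param shape `"triangle"` or `"wlc"`.
#' @param persistence_scale Shape parameter (m) of the WLC-like rising limb;
#'   smaller values give a sharper upturn near rupture.
#' @param baseline_noise_sd Gaussian force-noise SD in newtons.
#' @param max_separation Retraction span in metres. Default 3e-6 (the probe is
#'   parked 3 um from the surface).
#' @param sampling_interval Spatial sampling step in metres. Default 1e-9.
#' @param contact_stiffness Slope of the repulsive contact ramp, N/m.
#' @param contact_depth Indentation depth of the repulsive region, metres.
#' @return A list of class `"pull_scenario"`.
#' @export
#' @examples
#' sc <- pull_scenario(contour_length = c(1e-7, 2.5e-7),
#'                     peak_adhesion = c(1e-9, 0.6e-9))
#' scenario_truth(sc)
pull_scenario <- function(contour_length = numeric(),
                          peak_adhesion = numeric(),
                          shape = c("triangle", "wlc"),
                          persistence_scale = 5e-9,
                          baseline_noise_sd = 0,
                          max_separation = 3e-6,
                          sampling_interval = 1e-9,
                          contact_stiffness = 1,
                          contact_depth = 1.5e-8) {
  shape <- match.arg(shape)
  if (length(contour_length) != length(peak_adhesion)) {
    abort("contour_length and peak_adhesion must have equal length")
  }
  if (length(contour_length)) {
    if (any(diff(contour_length) <= 0)) {
      abort("contour lengths must be strictly increasing")
    }
    if (any(contour_length >= max_separation)) {
      abort("all contour lengths must be below max_separation")
    }
    if (any(peak_adhesion <= 0)) {
      abort("peak adhesions are magnitudes and must be positive")
    }
  }
  if (baseline_noise_sd < 0) abort("baseline_noise_sd must be non-negative")
  h <- sampling_interval
  snapped <- round(contour_length / h) * h
  if (length(snapped) > 1L && any(diff(snapped) <= 0)) {
    abort("contour lengths collide after snapping to the sampling grid; use a finer sampling_interval")
  }
  structure(
    list(contour_length = snapped,
         peak_adhesion = peak_adhesion,
         shape = shape,
         persistence_scale = persistence_scale,
         baseline_noise_sd = baseline_noise_sd,
         max_separation = max_separation,
         sampling_interval = h,
         contact_stiffness = contact_stiffness,
         contact_depth = contact_depth),
    class = "pull_scenario"
  )
}

# WLC-like rising limb on u in [0, 1]: interpolation-formula profile with the
# divergence cut at extensibility a < 1, normalized to 1 at u = 1.
wlc_limb <- function(u, a) {
  raw <- 0.25 / (1 - a * u)^2 - 0.25 + a * u
  peak <- 0.25 / (1 - a)^2 - 0.25 + a
  raw / peak
}

# Closed-form integral of wlc_limb over [0, 1].
wlc_limb_area <- function(a) {
  peak <- 0.25 / (1 - a)^2 - 0.25 + a
  (0.25 / (1 - a) - 0.25 + a / 2) / peak
}

wlc_extensibility <- function(scenario, base) {
  pmin(0.99, pmax(0.5, 1 - scenario$persistence_scale / base))
}

#' Noise-free force profile of a pull scenario
#'
#' Evaluates the scenario's ideal force (N, adhesion negative, contact
#' repulsion positive) at arbitrary tip-sample separations. This closed-form
#' profile is what the synthetic generator samples and what independent
#' quadrature oracles integrate.
#'
#' @param scenario A [pull_scenario()].
#' @param separation Numeric separations in metres (negative = in contact).
#' @return Numeric force vector in newtons.
#' @export
scenario_force <- function(scenario, separation) {
  f <- numeric(length(separation))
  contact <- separation < 0
  f[contact] <- -scenario$contact_stiffness * separation[contact]
  Lc <- scenario$contour_length
  if (length(Lc)) {
    starts <- c(0, Lc[-length(Lc)])
    for (j in seq_along(Lc)) {
      base <- Lc[j] - starts[j]
      inside <- separation > starts[j] & separation <= Lc[j]
      if (!any(inside)) next
      u <- (separation[inside] - starts[j]) / base
      limb <- switch(scenario$shape,
                     triangle = u,
                     wlc = wlc_limb(u, wlc_extensibility(scenario, base)))
      f[inside] <- -scenario$peak_adhesion[j] * limb
    }
  }
  f
}

#' Ground truth of a pull scenario
#'
#' The analytic per-pull quantities the analysis chain should recover:
#' dissipated energy (sum of closed-form per-event areas), maximum adhesion
#' force (largest event peak) and pulling length (last rupture position).
#'
#' @param scenario A [pull_scenario()].
#' @return One-row tibble with `true_energy` (J), `true_max_force` (N),
#'   `true_pulling_length` (m) and `n_events`.
#' @export
scenario_truth <- function(scenario) {
  Lc <- scenario$contour_length
  if (!length(Lc)) {
    return(tibble::tibble(true_energy = 0, true_max_force = 0,
                          true_pulling_length = 0, n_events = 0L))
  }
  starts <- c(0, Lc[-length(Lc)])
  base <- Lc - starts
  area_frac <- switch(scenario$shape,
                      triangle = rep(0.5, length(Lc)),
                      wlc = wlc_limb_area(wlc_extensibility(scenario, base)))
  tibble::tibble(
    true_energy = sum(scenario$peak_adhesion * base * area_frac),
    true_max_force = max(scenario$peak_adhesion),
    true_pulling_length = Lc[length(Lc)],
    n_events = length(Lc)
  )
}

# Encode a (separation, force) trace as raw piezo + photodiode signals under a
# calibration: deflection_raw = force / (k * invols) and piezo position chosen
# so that z_contact - z + force / k reproduces the intended separation.
encode_raw <- function(separation, force, calibration, z_contact) {
  k <- calibration$spring_constant
  list(z_position = z_contact - separation + force / k,
       deflection_raw = force / (k * calibration$invols))
}

#' Generate one synthetic retraction curve with known ground truth
#'
#' Samples the scenario's force profile on a uniform separation grid from
#' `-contact_depth` (repulsive contact) to `max_separation`, adds Gaussian
#' baseline force noise, and encodes the result as a raw (volts) retraction
#' cycle under the given calibration, so the full calibrate/analyze chain can
#' be exercised end to end. Identical seeds give identical output.
#'
#' @param scenario A [pull_scenario()].
#' @param calibration A [cantilever_calibration()].
#' @param seed Integer seed for the baseline noise (NULL = use current RNG).
#' @param retract_velocity Retraction speed, m/s, reflected in `time`.
#' @return List with `cycle` (a raw [force_cycle()]) and `truth`
#'   (the [scenario_truth()] row). If any event peak lies below twice the
#'   baseline noise SD, the cycle metadata carries `weak_event_warning`.
#' @export
generate_retraction_curve <- function(scenario, calibration, seed = NULL,
                                      retract_velocity = 5e-6) {
  stopifnot(inherits(scenario, "pull_scenario"))
  check_calibration(calibration)
  h <- scenario$sampling_interval
  sep <- seq(-scenario$contact_depth, scenario$max_separation, by = h)
  force <- scenario_force(scenario, sep)
  noisy <- with_seed(seed, force +
                       if (scenario$baseline_noise_sd > 0)
                         rnorm(length(sep), 0, scenario$baseline_noise_sd)
                       else 0)
  raw <- encode_raw(sep, noisy, calibration,
                    z_contact = scenario$max_separation)
  md <- list(retract_velocity = retract_velocity,
             generator = "pull_scenario",
             noise_sd = scenario$baseline_noise_sd)
  weak <- length(scenario$peak_adhesion) &&
    any(scenario$peak_adhesion < 2 * scenario$baseline_noise_sd)
  if (weak) md$weak_event_warning <- TRUE
  cycle <- force_cycle(
    time = (sep + scenario$contact_depth) / retract_velocity,
    z_position = raw$z_position,
    deflection_raw = raw$deflection_raw,
    segment = "retract",
    metadata = md
  )
  list(cycle = cycle, truth = scenario_truth(scenario))
}

#' Generate a full approach/dwell/retract cycle
#'
#' The approach descends at `approach_velocity` until the repulsive contact
#' force reaches `contact_threshold` (default 15 nN); the probe then dwells at
#' constant position for `dwell_time`, and retracts at `retract_velocity`
#' through the scenario's adhesion profile back to `max_separation`. Segment
#' labels and a time column consistent with the segment velocities are
#' populated.
#'
#' @inheritParams generate_retraction_curve
#' @param contact_threshold Repulsive force defining full contact, N.
#' @param approach_velocity Approach speed, m/s. Default 2e-6.
#' @param dwell_time Dwell duration at full contact, s. Default 10.
#' @param dwell_samples Number of samples across the dwell.
#' @return List with `cycle` and `truth` as in [generate_retraction_curve()].
#' @export
generate_approach_retract_cycle <- function(scenario, calibration,
                                            contact_threshold = 15e-9,
                                            seed = NULL,
                                            approach_velocity = 2e-6,
                                            retract_velocity = 5e-6,
                                            dwell_time = 10,
                                            dwell_samples = 101L) {
  stopifnot(inherits(scenario, "pull_scenario"))
  check_calibration(calibration)
  if (contact_threshold <= 0) abort("contact_threshold must be positive")
  h <- scenario$sampling_interval
  depth <- contact_threshold / scenario$contact_stiffness
  depth <- ceiling(depth / h) * h  # first sampled point at/past threshold
  sc <- scenario
  sc$contact_depth <- depth

  sep_app <- seq(scenario$max_separation, -depth, by = -h)
  f_app <- numeric(length(sep_app))
  contact <- sep_app < 0
  f_app[contact] <- -scenario$contact_stiffness * sep_app[contact]
  sep_ret <- seq(-depth, scenario$max_separation, by = h)
  f_ret <- scenario_force(sc, sep_ret)

  noise <- function(n) {
    if (scenario$baseline_noise_sd > 0)
      rnorm(n, 0, scenario$baseline_noise_sd) else numeric(n)
  }
  parts <- with_seed(seed, {
    list(app = f_app + noise(length(f_app)),
         dwell = f_app[length(f_app)] + noise(dwell_samples),
         ret = f_ret + noise(length(f_ret)))
  })

  t_app <- (scenario$max_separation - sep_app) / approach_velocity
  t_dwell <- max(t_app) + seq_len(dwell_samples) * (dwell_time / dwell_samples)
  t_ret <- max(t_dwell) + (sep_ret + depth) / retract_velocity +
    h / retract_velocity  # avoid a duplicated timestamp at the dwell boundary

  sep_all <- c(sep_app, rep(-depth, dwell_samples), sep_ret)
  f_all <- c(parts$app, parts$dwell, parts$ret)
  raw <- encode_raw(sep_all, f_all, calibration,
                    z_contact = scenario$max_separation)
  cycle <- force_cycle(
    time = c(t_app, t_dwell, t_ret),
    z_position = raw$z_position,
    deflection_raw = raw$deflection_raw,
    segment = c(rep("approach", length(sep_app)),
                rep("dwell", dwell_samples),
                rep("retract", length(sep_ret))),
    metadata = list(approach_velocity = approach_velocity,
                    retract_velocity = retract_velocity,
                    dwell_time = dwell_time,
                    contact_threshold = contact_threshold,
                    generator = "pull_scenario",
                    noise_sd = scenario$baseline_noise_sd)
  )
  list(cycle = cycle, truth = scenario_truth(sc))
}

#' Generate stiff-surface calibration curves
#'
#' Simulates force curves on a nominally infinitely stiff surface: before
#' contact the photodiode reads baseline; past the contact point the
#' deflection rises linearly in piezo position with slope `1 / invols_true`
#' (V/m), plus Gaussian voltage noise. The default set size of 10 curves
#' mirrors standard optical-lever calibration practice.
#'
#' @param invols_true True inverse optical lever sensitivity, m/V.
#' @param n_curves Number of curves. Default 10.
#' @param noise_sd Deflection noise SD in volts.
#' @param seed Integer seed.
#' @param z_range Piezo travel in metres; contact sits at its midpoint.
#' @param n_samples Samples per curve.
#' @return List of raw approach [force_cycle()]s.
#' @export
generate_stiff_surface_set <- function(invols_true, n_curves = 10L,
                                       noise_sd = 0, seed = NULL,
                                       z_range = 4e-7, n_samples = 400L) {
  if (invols_true <= 0) abort("invols_true must be positive")
  if (n_curves < 1L) abort("need at least one curve")
  z <- seq(0, z_range, length.out = n_samples)
  z_c <- z_range / 2
  defl_clean <- pmax(0, z - z_c) / invols_true
  with_seed(seed, {
    purrr::map(seq_len(n_curves), function(i) {
      force_cycle(
        time = z / 2e-6,
        z_position = z,
        deflection_raw = defl_clean +
          if (noise_sd > 0) rnorm(n_samples, 0, noise_sd) else 0,
        segment = "approach",
        metadata = list(surface = "stiff", curve_index = i)
      )
    })
  })
}

#' Generate a thermal deflection series
#'
#' White Gaussian deflection fluctuations of a free cantilever at thermal
#' equilibrium: the series variance equals the equipartition target
#' `k_B * T / k_true`. This is the simplest series honouring the assumption of
#' the variance-based spring-constant estimator (no hydrodynamic colouring).
#'
#' @param k_true True spring constant, N/m.
#' @param temperature Temperature in kelvin.
#' @param n_samples Series length. Default 1e5.
#' @param sampling_rate Nominal sampling rate in Hz (metadata only).
#' @param seed Integer seed.
#' @return Numeric deflection series in metres, with attributes
#'   `sampling_rate` and `temperature`.
#' @export
generate_thermal_series <- function(k_true, temperature = 298,
                                    n_samples = 1e5, sampling_rate = 1e5,
                                    seed = NULL) {
  if (k_true <= 0) abort("k_true must be positive")
  if (temperature <= 0) abort("temperature must be positive")
  sd_eq <- sqrt(.kB * temperature / k_true)
  x <- with_seed(seed, rnorm(n_samples, 0, sd_eq))
  attr(x, "sampling_rate") <- sampling_rate
  attr(x, "temperature") <- temperature
  x
}
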