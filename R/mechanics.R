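#' Geometry-factor table for notched-femur fracture toughness
#'
#' The stress-intensity geometry factor Y(theta, Rm/t) for a circumferential
#' through-wall notch in a long bone loaded in three-point bending, tabulated
#' on a (half crack angle, mean-radius-to-thickness ratio) grid and evaluated
#' by bilinear interpolation. The factor enters `Kc = Y * sigma * sqrt(pi a)`.
#'
#' The table ships as an editable, versioned CSV. The default table,
#' `geometry_factor_synthetic.csv`, is a SYNTHETIC stand-in: a smooth,
#' plausibly shaped surface constructed for this package (published
#' maximum-load tabulations are not redistributed here). Replace it with a
#' laboratory's own calibrated table via `path` for real analyses; the whole
#' toughness pipeline is agnostic to which table is installed.
#'
#' @param path CSV with columns `half_crack_angle_deg`, `rm_over_t`,
#'   `factor`, forming a complete grid. Default: the synthetic table shipped
#'   with the package.
#' @return A list of class `"geometry_factor_table"`.
#' @export
geometry_factor_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "geometry_factor_synthetic.csv",
                                package = "osteoforce")
  tab <- utils::read.csv(path)
  need <- c("half_crack_angle_deg", "rm_over_t", "factor")
  if (!all(need %in% names(tab))) {
    abort(sprintf("geometry-factor table needs columns: %s",
                  paste(need, collapse = ", ")))
  }
  angles <- sort(unique(tab$half_crack_angle_deg))
  ratios <- sort(unique(tab$rm_over_t))
  if (nrow(tab) != length(angles) * length(ratios)) {
    abort("geometry-factor table is not a complete angle x ratio grid")
  }
  Z <- matrix(NA_real_, length(angles), length(ratios))
  Z[cbind(match(tab$half_crack_angle_deg, angles),
          match(tab$rm_over_t, ratios))] <- tab$factor
  structure(list(angles = angles, ratios = ratios, values = Z,
                 source = basename(path)),
            class = "geometry_factor_table")
}

#' @rdname geometry_factor_table
#' @param table A `geometry_factor_table`.
#' @param theta_deg Half crack angle(s) in degrees.
#' @param rm_over_t Mean radius over cortical thickness ratio(s).
#' @export
geometry_factor <- function(table, theta_deg, rm_over_t) {
  stopifnot(inherits(table, "geometry_factor_table"))
  if (any(theta_deg < min(table$angles) | theta_deg > max(table$angles)) ||
      any(rm_over_t < min(table$ratios) | rm_over_t > max(table$ratios))) {
    abort(sprintf(
      "(theta, Rm/t) outside the factor table domain [%g, %g] x [%g, %g]",
      min(table$angles), max(table$angles),
      min(table$ratios), max(table$ratios)))
  }
  # interp2 expects Z as length(y) x length(x)
  pracma::interp2(x = table$ratios, y = table$angles, Z = table$values,
                  xp = rm_over_t, yp = theta_deg, method = "linear")
}

#' Validate notched specimens before toughness analysis
#'
#' Applies the cohort-level validity rules, once, on the pre-analysis cohort:
#' a specimen is rejected if its half crack angle lies outside the accurate
#' testing range (0-110 degrees), if its angle deviates from the cohort mean
#' by more than two cohort standard deviations, if the notch extends deeper
#' than one third of the cortex, or if the notch is flagged off-centre. The
#' first matching reason is recorded.
#'
#' @param specimens Tibble with `half_crack_angle` (degrees) and optionally
#'   `notch_cortex_fraction` and logical `off_center`.
#' @param angle_range Accurate half-crack-angle range in degrees.
#' @param max_notch_fraction Maximum admissible notch depth as a fraction of
#'   the cortex. Default 1/3.
#' @param cohort_angles Angles defining the outlier rule; defaults to the
#'   cohort being validated.
#' @return The input with `valid` (logical) and `rejection_reason` columns.
#' @export
#' @examples
#' sp <- tibble::tibble(half_crack_angle = c(80, 82, 84, 86, 115))
#' validate_specimens(sp)
validate_specimens <- function(specimens, angle_range = c(0, 110),
                               max_notch_fraction = 1 / 3,
                               cohort_angles = NULL) {
  stopifnot(is.data.frame(specimens))
  if (!"half_crack_angle" %in% names(specimens)) {
    abort("specimens need a `half_crack_angle` column (degrees)")
  }
  th <- specimens$half_crack_angle
  cohort_angles <- cohort_angles %||% th
  if (!length(cohort_angles)) abort("cohort_angles must be non-empty")
  m <- mean(cohort_angles)
  s <- sd(cohort_angles)
  frac <- if ("notch_cortex_fraction" %in% names(specimens))
    specimens$notch_cortex_fraction else rep(0, nrow(specimens))
  offc <- if ("off_center" %in% names(specimens))
    specimens$off_center else rep(FALSE, nrow(specimens))
  reason <- rep(NA_character_, nrow(specimens))
  reason[is.na(reason) & (th < angle_range[1] | th > angle_range[2])] <-
    "angle_range"
  if (is.finite(s) && s > 0) {
    reason[is.na(reason) & abs(th - m) > 2 * s] <- "angle_outlier"
  }
  reason[is.na(reason) & frac > max_notch_fraction] <- "deep_notch"
  reason[is.na(reason) & offc] <- "off_center"
  specimens$valid <- is.na(reason)
  specimens$rejection_reason <- reason
  specimens
}

#' Single-valued fracture toughness at maximum load
#'
#' For each notched femur in three-point bending, computes
#' `Kc = Y(theta, Rm/t) * sigma_max * sqrt(pi * a)` where `sigma_max` is the
#' outer-fibre bending stress at maximum load (`M = P_max * span / 4`, annular
#' second moment `I = pi/4 (Ro^4 - Ri^4)`, fibre distance `R_outer` by
#' default or the mid-wall radius via `stress_radius = "mean"`), and the crack
#' length `a` is the mid-wall arc subtended by the half crack angle
#' (`a = theta[rad] * Rm`, `Rm = (Ro + Ri)/2`).
#'
#' @param specimens Tibble with columns `P_max` (N), `span` (m), `R_outer`,
#'   `R_inner` (m) and `half_crack_angle` (degrees); an `id` column is carried
#'   through.
#' @param factor_table A [geometry_factor_table()].
#' @param stress_radius `"outer"` (default) or `"mean"`: the fibre distance in
#'   the bending-stress term.
#' @return The input plus `rm` (m), `thickness` (m), `second_moment` (m^4),
#'   `bending_stress` (Pa), `crack_length` (m), `factor` and `Kc`
#'   (MPa m^0.5).
#' @export
kc_max_load <- function(specimens, factor_table = geometry_factor_table(),
                        stress_radius = c("outer", "mean")) {
  stress_radius <- match.arg(stress_radius)
  stopifnot(is.data.frame(specimens))
  need <- c("P_max", "span", "R_outer", "R_inner", "half_crack_angle")
  missing <- setdiff(need, names(specimens))
  if (length(missing)) {
    abort(sprintf("specimens are missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  with(specimens, {
    if (any(R_inner <= 0 | R_outer <= R_inner)) {
      abort("need 0 < R_inner < R_outer for every specimen")
    }
    if (any(P_max < 0) || any(span <= 0)) {
      abort("P_max must be >= 0 and span > 0")
    }
  })
  out <- specimens
  out$rm <- (out$R_outer + out$R_inner) / 2
  out$thickness <- out$R_outer - out$R_inner
  out$second_moment <- pi / 4 * (out$R_outer^4 - out$R_inner^4)
  fibre <- if (stress_radius == "outer") out$R_outer else out$rm
  out$bending_stress <- (out$P_max * out$span / 4) * fibre / out$second_moment
  out$crack_length <- out$half_crack_angle * pi / 180 * out$rm
  out$factor <- geometry_factor(factor_table, out$half_crack_angle,
                                out$rm / out$thickness)
  out$Kc <- out$factor * out$bending_stress *
    sqrt(pi * out$crack_length) / 1e6
  out
}
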