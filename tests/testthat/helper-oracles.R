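# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# Midpoint Riemann sum of the adhesive area of a scenario's noise-free force
# profile over [0, upper]. scenario_force() is the generator's closed-form
# profile; the integration itself is independent of the trapezoid pipeline.
riemann_energy_oracle <- function(scenario, upper, n = 1e6) {
  mid <- (seq_len(n) - 0.5) / n * upper
  sum(pmax(0, -scenario_force(scenario, mid))) * upper / n
}

# Closed-form pooled-variance two-sample t-test (hand formula).
student_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Closed-form paired t-test (hand formula on the differences).
paired_t_oracle <- function(x, y) {
  d <- x - y
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  df <- length(d) - 1
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Direct enumeration of the one-sample KS statistic against N(mean, sd).
ks_stat_oracle <- function(x, mean, sd) {
  x <- sort(x)
  n <- length(x)
  Fx <- pnorm(x, mean, sd)
  max(max(seq_len(n) / n - Fx), max(Fx - (seq_len(n) - 1) / n))
}

# Manual bilinear interpolation on a geometry-factor grid (independent of
# pracma::interp2 and of geometry_factor()).
bilinear_oracle <- function(angles, ratios, Z, theta, ratio) {
  i <- findInterval(theta, angles, rightmost.closed = TRUE)
  j <- findInterval(ratio, ratios, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(angles) - 1L)
  j <- pmin(pmax(j, 1L), length(ratios) - 1L)
  u <- (theta - angles[i]) / (angles[i + 1] - angles[i])
  v <- (ratio - ratios[j]) / (ratios[j + 1] - ratios[j])
  (1 - u) * (1 - v) * Z[cbind(i, j)] +
    u * (1 - v) * Z[cbind(i + 1, j)] +
    (1 - u) * v * Z[cbind(i, j + 1)] +
    u * v * Z[cbind(i + 1, j + 1)]
}

# Step-by-step fracture-toughness decomposition oracle.
kc_oracle <- function(P, span, Ro, Ri, theta_deg, factor_table,
                      stress_radius = "outer") {
  I <- pi / 4 * (Ro^4 - Ri^4)
  Rm <- (Ro + Ri) / 2
  fibre <- if (stress_radius == "outer") Ro else Rm
  sigma <- (P * span / 4) * fibre / I
  a <- theta_deg * pi / 180 * Rm
  Y <- bilinear_oracle(factor_table$angles, factor_table$ratios,
                       factor_table$values, theta_deg, Rm / (Ro - Ri))
  Y * sigma * sqrt(pi * a) / 1e6
}

# Random multi-event triangle scenarios on a dense grid; used by the energy
# oracle-equivalence checks.
random_dense_scenario <- function(shape = "triangle",
                                  sampling_interval = 1e-10,
                                  noise_sd = 0) {
  n_ev <- sample(2:4, 1)
  bases <- runif(n_ev, 150e-9, 350e-9)
  peaks <- runif(n_ev, 0.4e-9, 1.2e-9)
  pull_scenario(contour_length = cumsum(bases),
                peak_adhesion = peaks,
                shape = shape,
                baseline_noise_sd = noise_sd,
                max_separation = 1.6e-6,
                sampling_interval = sampling_interval)
}

default_calibration <- function(k = 0.18) {
  cantilever_calibration(invols = 50e-9, spring_constant = k)
}
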