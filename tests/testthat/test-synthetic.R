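test_that("a single triangular event has the analytic triangle area", {
  sc <- pull_scenario(contour_length = 100e-9, peak_adhesion = 1.0e-9,
                      max_separation = 5e-7)
  truth <- scenario_truth(sc)
  expect_equal(truth$true_energy, 0.5 * 1.0e-9 * 100e-9)
  expect_equal(truth$true_max_force, 1.0e-9)
  expect_equal(truth$true_pulling_length, 100e-9)
})

test_that("zero events give a flat curve with zero true energy", {
  sc <- pull_scenario(max_separation = 5e-7)
  expect_equal(scenario_truth(sc)$true_energy, 0)
  gen <- generate_retraction_curve(sc, default_calibration(), seed = 1)
  free <- gen$cycle$time > (sc$contact_depth + 2e-9) / 5e-6  # past contact
  expect_true(all(abs(gen$cycle$deflection_raw[free]) < 1e-12))
})

test_that("multi-event analytic energies match a fine quadrature oracle", {
  for (shape in c("triangle", "wlc")) {
    sc <- pull_scenario(contour_length = c(120e-9, 340e-9, 650e-9),
                        peak_adhesion = c(0.8e-9, 1.1e-9, 0.5e-9),
                        shape = shape, max_separation = 1.5e-6)
    truth <- scenario_truth(sc)
    oracle <- riemann_energy_oracle(sc, upper = 650e-9, n = 1e6)
    expect_lt(abs(truth$true_energy - oracle) / oracle, 1e-4)
  }
})

test_that("identical seeds give bit-identical synthetic outputs", {
  sc <- pull_scenario(contour_length = c(1e-7, 4e-7),
                      peak_adhesion = c(1e-9, 0.5e-9),
                      baseline_noise_sd = 5e-11)
  cal <- default_calibration()
  a <- generate_retraction_curve(sc, cal, seed = 123)
  b <- generate_retraction_curve(sc, cal, seed = 123)
  expect_identical(a$cycle$deflection_raw, b$cycle$deflection_raw)
  s1 <- generate_stiff_surface_set(50e-9, noise_sd = 0.01, seed = 5)
  s2 <- generate_stiff_surface_set(50e-9, noise_sd = 0.01, seed = 5)
  expect_identical(s1[[3]]$deflection_raw, s2[[3]]$deflection_raw)
  t1 <- generate_thermal_series(0.006, n_samples = 1e4, seed = 9)
  t2 <- generate_thermal_series(0.006, n_samples = 1e4, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  c1 <- generate_paired_cohort(cohort_spec(seed = 4))
  c2 <- generate_paired_cohort(cohort_spec(seed = 4))
  expect_identical(c1$toughness$value, c2$toughness$value)
  expect_identical(c1$phospho_assays$absorbance, c2$phospho_assays$absorbance)
})

test_that("sub-noise event peaks are flagged with a warning field", {
  sc <- pull_scenario(contour_length = 1e-7, peak_adhesion = 1e-11,
                      baseline_noise_sd = 5e-11, max_separation = 5e-7)
  gen <- generate_retraction_curve(sc, default_calibration(), seed = 2)
  expect_true(isTRUE(cycle_metadata(gen$cycle)$weak_event_warning))
})

test_that("approach reaches full contact at the threshold force within one sample", {
  sc <- pull_scenario(contour_length = 2e-7, peak_adhesion = 1e-9,
                      max_separation = 1e-6, contact_stiffness = 1)
  cal <- default_calibration()
  gen <- generate_approach_retract_cycle(sc, cal, contact_threshold = 15e-9)
  cyc <- deflection_to_force(gen$cycle, cal)
  peak <- max(cyc$force[cyc$segment == "approach"])
  # threshold 15 nN, one spatial sample tolerance at the contact stiffness
  expect_gte(peak, 15e-9)
  expect_lte(peak, 15e-9 + 1 * sc$sampling_interval * sc$contact_stiffness +
               1e-15)
})

test_that("cycle time encodes the approach/retract velocities and the dwell", {
  sc <- pull_scenario(contour_length = 2e-7, peak_adhesion = 1e-9,
                      max_separation = 1e-6, contact_stiffness = 1)
  gen <- generate_approach_retract_cycle(sc, default_calibration(),
                                         contact_threshold = 15e-9,
                                         approach_velocity = 2e-6,
                                         retract_velocity = 5e-6,
                                         dwell_time = 10)
  cyc <- gen$cycle
  travel <- 1e-6 + 15e-9 / 1  # max_separation + indentation depth
  app_span <- diff(range(cyc$time[cyc$segment == "approach"]))
  ret_span <- diff(range(cyc$time[cyc$segment == "retract"]))
  dwell_span <- diff(range(cyc$time[cyc$segment == "dwell"]))
  expect_equal(app_span * 2e-6, travel, tolerance = 0.01)
  expect_equal(ret_span * 5e-6, travel, tolerance = 0.01)
  expect_equal(dwell_span, 10, tolerance = 0.02)
})

test_that("stiff-surface sets default to ten linear curves of slope 1/InvOLS", {
  curves <- generate_stiff_surface_set(50e-9)
  expect_length(curves, 10L)
  cyc <- curves[[1]]
  loading <- cyc$deflection_raw > 0
  slope <- coef(lm(cyc$deflection_raw[loading] ~ cyc$z_position[loading]))[2]
  expect_equal(unname(slope), 1 / 50e-9, tolerance = 1e-10)
})

test_that("thermal series variance honours equipartition", {
  kB <- 1.380649e-23
  x <- generate_thermal_series(0.006, temperature = 298, n_samples = 1e6,
                               seed = 31)
  expect_equal(var(x), kB * 298 / 0.006, tolerance = 0.01)
  y <- generate_thermal_series(0.18, temperature = 298, n_samples = 1e6,
                               seed = 31)
  expect_equal(var(x) / var(y), 30, tolerance = 0.02)
})

test_that("paired cohorts carry the configured multiplicative effect", {
  spec <- cohort_spec(n_pairs = 50L, toughness_effect = 0.18,
                      toughness_sd = 0.1, toughness_limb_sd = 0.02,
                      seed = 7)
  cohort <- generate_paired_cohort(spec)$toughness
  wide <- tidyr::pivot_wider(
    dplyr::select(cohort, "animal", "group", "arm", "value"),
    names_from = "arm", values_from = "value")
  rel <- mean(wide$treated - wide$control) / mean(wide$control)
  expect_equal(rel, 0.18, tolerance = 0.05)
  # each animal has exactly one treated and one control limb
  expect_true(all(table(cohort$animal) == 2))
  expect_true(all(tapply(cohort$limb, cohort$animal,
                         function(l) setequal(l, c("left", "right")))))
  # limb assignment is randomized, not constant
  treated_limbs <- cohort$limb[cohort$arm == "treated"]
  expect_gt(length(unique(treated_limbs)), 1L)
})

test_that("a null-effect cohort has mean delta near zero", {
  spec <- cohort_spec(n_pairs = 100L, toughness_effect = 0,
                      toughness_limb_sd = 0.1, seed = 21)
  cohort <- generate_paired_cohort(spec)$toughness
  pa <- paired_deltas(cohort, value = "value")
  expect_lt(abs(mean(pa$deltas$delta)), 0.05)
})
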