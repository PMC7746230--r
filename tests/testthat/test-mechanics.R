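test_that("specimen validity rules reject with the correct reasons", {
  sp <- tibble::tibble(
    id = paste0("s", 1:7),
    half_crack_angle = c(80, 82, 84, 86, 88, 115, 83),
    notch_cortex_fraction = c(0.2, 0.2, 0.4, 0.2, 0.2, 0.2, 0.2),
    off_center = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  # outlier rule evaluated against a tight cohort of angles
  out <- validate_specimens(sp, cohort_angles = c(80, 82, 84, 86, 88))
  expect_identical(out$rejection_reason[out$id == "s6"], "angle_range")
  expect_identical(out$rejection_reason[out$id == "s3"], "deep_notch")
  expect_identical(out$rejection_reason[out$id == "s4"], "off_center")
  expect_true(out$valid[out$id == "s7"])  # 83 deg, inside 2 SD
  # angle far from the cohort mean but inside [0, 110]
  far <- validate_specimens(tibble::tibble(half_crack_angle = 109),
                            cohort_angles = c(80, 82, 84, 86, 88))
  expect_identical(far$rejection_reason, "angle_outlier")
})

test_that("validation is invariant to the cohort listing order", {
  angles <- c(70, 75, 80, 85, 90, 95, 108)
  sp <- tibble::tibble(id = seq_along(angles), half_crack_angle = angles)
  a <- validate_specimens(sp)
  b <- validate_specimens(sp[sample(nrow(sp)), ]) |> dplyr::arrange(id)
  expect_identical(a$valid, b$valid)
})

test_that("Kc is zero at zero load and linear in the maximum load", {
  sp <- tibble::tibble(P_max = c(0, 10, 20), span = 6e-3,
                       R_outer = 0.9e-3, R_inner = 0.5e-3,
                       half_crack_angle = 60)
  out <- kc_max_load(sp)
  expect_equal(out$Kc[1], 0)
  expect_equal(out$Kc[3], 2 * out$Kc[2], tolerance = 1e-12)
  expect_gt(out$Kc[2], 0)
})

test_that("Kc increases with load and with crack length, all else fixed", {
  base <- tibble::tibble(P_max = 15, span = 6e-3, R_outer = 0.9e-3,
                         R_inner = 0.5e-3, half_crack_angle = 50)
  k0 <- kc_max_load(base)$Kc
  expect_gt(kc_max_load(dplyr::mutate(base, P_max = 18))$Kc, k0)
  expect_gt(kc_max_load(dplyr::mutate(base, half_crack_angle = 70))$Kc, k0)
})

test_that("the toughness decomposition matches a step-by-step oracle", {
  tab <- geometry_factor_table()
  sp <- generate_notched_specimens(25, seed = 14)
  for (radius in c("outer", "mean")) {
    out <- kc_max_load(sp, tab, stress_radius = radius)
    oracle <- kc_oracle(sp$P_max, sp$span, sp$R_outer, sp$R_inner,
                        sp$half_crack_angle, tab, stress_radius = radius)
    expect_equal(out$Kc, oracle, tolerance = 1e-12)
  }
})

test_that("geometries outside the factor-table domain raise an error", {
  tab <- geometry_factor_table()
  sp <- tibble::tibble(P_max = 10, span = 6e-3, R_outer = 0.9e-3,
                       R_inner = 0.88e-3,  # Rm/t ~ 44, beyond the grid
                       half_crack_angle = 60)
  expect_error(kc_max_load(sp, tab), "outside the factor table domain")
})

test_that("phosphorylation level is mean absorbance per ng of protein", {
  lv <- phospho_level(c(0.49, 0.50, 0.51), protein = 1000)
  expect_equal(lv$level, 5.0e-4)
  expect_equal(lv$n_replicates, 3L)
  expect_true(is.finite(lv$replicate_cv))
  single <- phospho_level(0.5, protein = 1000)
  expect_true(is.na(single$replicate_cv))
  expect_error(phospho_level(0.5, protein = 0), "positive")
  # homogeneity: scaling absorbances scales the level
  expect_equal(phospho_level(c(0.98, 1.00, 1.02), 1000)$level,
               2 * lv$level, tolerance = 1e-12)
})

test_that("assay tables aggregate replicates per specimen", {
  cohort <- generate_paired_cohort(cohort_spec(n_pairs = 3, seed = 2))
  levels <- phospho_levels(cohort$phospho_assays)
  expect_equal(nrow(levels), 12L)  # 2 groups x 3 animals x 2 arms
  expect_true(all(levels$n_replicates == 3L))
  one <- cohort$phospho_assays[cohort$phospho_assays$id == levels$id[1], ]
  expect_equal(levels$level[1], mean(one$absorbance) / one$protein[1])
})

test_that("paired deltas require exactly one treated and one control per animal", {
  cohort <- generate_paired_cohort(cohort_spec(n_pairs = 4, seed = 5))$toughness
  pa <- paired_deltas(cohort, value = "value")
  expect_equal(nrow(pa$deltas), 8L)
  expect_equal(pa$deltas$delta, pa$deltas$treated - pa$deltas$control)
  broken <- cohort[-1, ]
  expect_error(paired_deltas(broken, value = "value"),
               "exactly one treated and one control")
})

test_that("an 18% effect cohort shows the matching relative delta and p < 0.05", {
  spec <- cohort_spec(n_pairs = 7, toughness_effect = 0.18,
                      toughness_limb_sd = 0.05, seed = 33)
  cohort <- generate_paired_cohort(spec)$toughness
  pa <- paired_deltas(cohort, value = "value")
  for (g in names(pa$paired_tests)) {
    d <- pa$deltas[pa$deltas$group == g, ]
    expect_equal(mean(d$delta) / mean(d$control), 0.18, tolerance = 0.15)
    expect_lt(pa$paired_tests[[g]]$p_value, 0.05)
  }
  expect_false(is.null(pa$delta_test))
})

test_that("all-zero deltas are reported as a flagged no-effect, not an error", {
  cohort <- tibble::tibble(
    animal = rep(paste0("a", 1:4), each = 2),
    group = "WT",
    arm = rep(c("treated", "control"), 4),
    value = rep(c(3.2, 3.2), 4)
  )
  pa <- paired_deltas(cohort, value = "value")
  expect_true(pa$paired_tests$WT$degenerate)
  expect_equal(mean(pa$deltas$delta), 0)
})
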