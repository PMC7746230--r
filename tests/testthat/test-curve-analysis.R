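make_segment <- function(separation, force) {
  find_contact_point(tibble::tibble(separation = separation, force = force))
}

test_that("labelled cycles split by label and unlabelled ones at the apex", {
  sc <- pull_scenario(contour_length = 2e-7, peak_adhesion = 1e-9,
                      max_separation = 6e-7)
  cal <- default_calibration()
  gen <- generate_approach_retract_cycle(sc, cal)
  parts <- split_curve(gen$cycle)
  expect_identical(nrow(parts$approach), sum(gen$cycle$segment == "approach"))
  expect_identical(nrow(parts$retract), sum(gen$cycle$segment == "retract"))

  # unlabelled triangle wave in z: split at the apex index
  z <- c(seq(0, 1e-7, length.out = 50), seq(1e-7, 0, length.out = 50)[-1])
  cyc <- force_cycle(time = seq_along(z), z_position = z,
                     deflection_raw = rep(0.1, length(z)))
  parts2 <- split_curve(cyc)
  expect_equal(nrow(parts2$approach), 50L)
  expect_equal(parts2$retract$z_position[1], 1e-7)

  mono <- force_cycle(1:10, seq(0, 1e-7, length.out = 10), rep(0.1, 10))
  expect_error(split_curve(mono), "monotone")
})

test_that("splitting a generated cycle returns the generator's retraction samples", {
  sc <- pull_scenario(contour_length = 2e-7, peak_adhesion = 1e-9,
                      max_separation = 6e-7, baseline_noise_sd = 2e-11)
  gen <- generate_approach_retract_cycle(sc, default_calibration(), seed = 3)
  ret <- split_curve(gen$cycle)$retract
  expect_identical(ret$deflection_raw,
                   gen$cycle$deflection_raw[gen$cycle$segment == "retract"])
})

test_that("contact alignment shifts the zero-crossing to the origin", {
  # force crosses zero exactly at separation 120 nm
  s <- seq(0, 5e-7, by = 1e-9)
  f <- ifelse(s < 1.2e-7, (1.2e-7 - s) * 1,          # repulsive ramp
              -1e-9 * pmin(1, (s - 1.2e-7) / 2e-7))  # adhesive dip
  seg <- make_segment(s, f)
  expect_false(osteoforce:::segment_rejected(seg))
  expect_equal(seg$separation, s - 1.2e-7, tolerance = 1e-9)
})

test_that("all-repulsive and all-adhesive traces are flagged, not errors", {
  s <- seq(0, 1e-7, by = 1e-9)
  rep_seg <- make_segment(s, rep(1e-9, length(s)))
  expect_identical(attr(rep_seg, "rejected"), "all_repulsive")
  adh_seg <- make_segment(s, rep(-1e-9, length(s)))
  expect_identical(attr(adh_seg, "rejected"), "all_adhesive")
})

test_that("contact alignment lands within one sample of the generator's contact", {
  cal <- default_calibration()
  h <- 1e-9
  # noise-free: alignment is exact to within one sample
  sc0 <- pull_scenario(contour_length = 3e-7, peak_adhesion = 1e-9,
                       max_separation = 8e-7)
  seg0 <- find_contact_point(deflection_to_force(
    generate_retraction_curve(sc0, cal)$cycle, cal))
  sep_true <- seq(-sc0$contact_depth, sc0$max_separation, by = h)
  expect_lt(abs(median(seg0$separation - sort(sep_true))), h)
  # with baseline noise the onset blurs by the noise-to-slope ratio; allow a
  # few samples
  sc1 <- pull_scenario(contour_length = 3e-7, peak_adhesion = 1e-9,
                       max_separation = 8e-7, baseline_noise_sd = 2e-11)
  seg1 <- find_contact_point(deflection_to_force(
    generate_retraction_curve(sc1, cal, seed = 6)$cycle, cal))
  expect_lt(abs(median(seg1$separation - sort(sep_true))), 5 * h)
})

test_that("maximum adhesion force is the magnitude of the force minimum", {
  s <- seq(0, 3e-9, by = 1e-9)
  seg <- structure(
    tibble::tibble(separation = s, force = c(0, -0.4e-9, -1.2e-9, -0.1e-9)),
    rejected = NA_character_,
    class = c("retraction_segment", class(tibble::tibble())))
  expect_equal(max_adhesion_force(seg)$max_force, 1.2e-9)
  pos <- structure(
    tibble::tibble(separation = s, force = c(0.1, 0.2, 0.3, 0.4) * 1e-9),
    rejected = NA_character_,
    class = c("retraction_segment", class(tibble::tibble())))
  expect_equal(max_adhesion_force(pos)$max_force, 0)
})

test_that("pulling length is the end of the last super-threshold excursion", {
  h <- 1e-9
  i <- 0:600
  s <- i * h
  # single event vanishing beyond 250 nm (index-based to avoid float edges)
  f1 <- ifelse(i <= 250, -1e-9 * i / 250, 0)
  seg1 <- structure(tibble::tibble(separation = s, force = f1),
                    class = c("retraction_segment", class(tibble::tibble())))
  expect_equal(pulling_length(seg1, 1e-9, 0.01), s[251])
  # a second event ending at 400 nm peaking at 5% of the maximum force
  f2 <- f1
  idx <- i > 300 & i <= 400
  f2[idx] <- -0.05e-9 * (i[idx] - 300) / 100
  seg2 <- structure(tibble::tibble(separation = s, force = f2),
                    class = c("retraction_segment", class(tibble::tibble())))
  expect_equal(pulling_length(seg2, 1e-9, 0.01), s[401])
  # zero maximum force short-circuits to zero length
  expect_equal(pulling_length(seg1, 0, 0.01), 0)
})

test_that("energy integrates only adhesive area and matches the triangle value", {
  h <- 1e-9
  s <- seq(0, 2e-7, by = h)
  f <- ifelse(s <= 1e-7, -1e-9 * s / 1e-7, 0)
  seg <- structure(tibble::tibble(separation = s, force = f),
                   class = c("retraction_segment", class(tibble::tibble())))
  expect_equal(energy_dissipation(seg, 1e-7), 5e-17, tolerance = 0.01)
  # zero adhesion -> zero energy
  seg0 <- structure(tibble::tibble(separation = s, force = abs(f)),
                    class = c("retraction_segment", class(tibble::tibble())))
  expect_equal(energy_dissipation(seg0, 1e-7), 0)
  expect_error(energy_dissipation(seg, 1e-6), "exceeds")
})

test_that("adding an adhesive excursion inside the window never decreases energy", {
  h <- 1e-9
  s <- seq(0, 5e-7, by = h)
  base_f <- ifelse(s <= 2e-7, -1e-9 * s / 2e-7, 0)
  seg <- structure(tibble::tibble(separation = s, force = base_f),
                   class = c("retraction_segment", class(tibble::tibble())))
  e0 <- energy_dissipation(seg, 4.5e-7)
  withr::with_seed(10, {
    for (i in 1:20) {
      extra <- base_f
      lo <- runif(1, 2.2e-7, 3.5e-7)
      hi <- lo + runif(1, 2e-8, 8e-8)
      idx <- s >= lo & s <= hi
      extra[idx] <- extra[idx] - runif(1, 0.1e-9, 1e-9)
      seg2 <- structure(tibble::tibble(separation = s, force = extra),
                        class = c("retraction_segment",
                                  class(tibble::tibble())))
      expect_gte(energy_dissipation(seg2, 4.5e-7), e0)
    }
  })
})

test_that("scaling all forces scales energy and preserves pulling length", {
  sc <- pull_scenario(contour_length = c(1e-7, 3e-7),
                      peak_adhesion = c(0.5e-9, 1e-9), max_separation = 8e-7)
  cal <- default_calibration()
  seg <- find_contact_point(deflection_to_force(
    generate_retraction_curve(sc, cal)$cycle, cal))
  mf <- max_adhesion_force(seg)$max_force
  pl <- pulling_length(seg, mf)
  en <- energy_dissipation(seg, pl)
  for (c_scale in c(0.5, 3)) {
    seg2 <- seg
    seg2$force <- seg$force * c_scale
    mf2 <- max_adhesion_force(seg2)$max_force
    pl2 <- pulling_length(seg2, mf2)
    expect_equal(mf2, mf * c_scale)
    expect_equal(pl2, pl)
    expect_equal(energy_dissipation(seg2, pl2), en * c_scale,
                 tolerance = 1e-12)
  }
})

test_that("energy is non-increasing in the threshold fraction", {
  sc <- pull_scenario(contour_length = c(1e-7, 2.5e-7, 5e-7),
                      peak_adhesion = c(1e-9, 0.3e-9, 0.05e-9),
                      max_separation = 1e-6, baseline_noise_sd = 1e-11)
  cal <- default_calibration()
  seg <- find_contact_point(deflection_to_force(
    generate_retraction_curve(sc, cal, seed = 2)$cycle, cal))
  mf <- max_adhesion_force(seg)$max_force
  energies <- vapply(c(0.005, 0.01, 0.02, 0.1, 0.4, 0.9), function(fr) {
    energy_dissipation(seg, pulling_length(seg, mf, threshold_fraction = fr))
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-25))
})

test_that("the full chain reproduces per-stage ground truth on a batch of 50 pulls", {
  cal <- default_calibration()
  cfg <- run_config()
  withr::with_seed(77, {
    for (i in 1:5) {
      sc <- random_dense_scenario(sampling_interval = 1e-9)
      gen <- generate_retraction_curve(sc, cal)
      m <- process_curve(gen$cycle, cal, cfg)
      expect_true(m$accepted)
      expect_equal(m$max_force, gen$truth$true_max_force, tolerance = 1e-6)
      expect_equal(m$pulling_length, gen$truth$true_pulling_length,
                   tolerance = 2e-9 / gen$truth$true_pulling_length)
      expect_equal(m$energy, gen$truth$true_energy, tolerance = 0.005)
    }
  })
  # batch bookkeeping: 50 records, one per cycle, deterministic
  sc <- pull_scenario(contour_length = c(1e-7, 3e-7),
                      peak_adhesion = c(0.5e-9, 1e-9),
                      max_separation = 8e-7, baseline_noise_sd = 2e-11)
  cycles <- purrr::map(1:50, function(i)
    generate_retraction_curve(sc, cal, seed = i)$cycle)
  metrics <- process_curves(cycles, cal, cfg)
  expect_equal(nrow(metrics), 50L)
  expect_true(all(metrics$accepted))
  metrics2 <- process_curves(cycles, cal, cfg)
  expect_identical(metrics$energy, metrics2$energy)
})

test_that("a flat noise-only curve yields a rejection record, not an error", {
  cal <- default_calibration()
  n <- 500
  cyc <- withr::with_seed(9, force_cycle(
    time = seq_len(n), z_position = seq(1e-6, 0, length.out = n),
    deflection_raw = rnorm(n, 0, 1e-4), segment = "retract"))
  m <- process_curve(cyc, cal)
  expect_s3_class(m, "tbl_df")
  if (!m$accepted) {
    expect_true(m$reason %in% c("all_repulsive", "all_adhesive", "no_contact"))
  } else {
    expect_lt(m$energy, 1e-18)
  }
})
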