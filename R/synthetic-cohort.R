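#' Specification of a synthetic paired bone cohort
#'
#' Describes the ground truth of a simulated ex-vivo treatment experiment:
#' per group (genotype), `n_pairs` animals each contribute one treated and one
#' contralateral control limb. A limb value is built as animal-level intercept
#' plus limb-level residual; the treated limb applies a multiplicative effect
#' to the animal's underlying value, so `treated = underlying * (1 + effect) +
#' residual`. The same construction generates triplicate phosphoprotein assay
#' readings. Defaults mirror the study arms: 7 pairs per genotype, a
#' fracture-toughness scale of a few MPa m^0.5, and a +18% treatment effect
#' (the ex-vivo phosphorylation scenario; use -0.25 for the dephosphorylation
#' scenario).
#'
#' @param n_pairs Animals per group (>= 2). Default 7.
#' @param groups Character vector of group (genotype) names.
#' @param toughness_mean,toughness_sd Control-limb toughness mean and
#'   between-animal SD, MPa m^0.5. Defaults 4.0 and 0.5.
#' @param toughness_limb_sd Limb-level residual SD, MPa m^0.5. Default 0.15.
#' @param toughness_effect Fractional treatment effect on toughness per
#'   group; recycled across groups. Default +0.18.
#' @param phospho_mean,phospho_sd Control phosphorylation level mean and
#'   between-animal SD, AU/ng.
#' @param phospho_limb_sd Limb-level residual SD, AU/ng.
#' @param phospho_effect Fractional treatment effect on phosphorylation;
#'   recycled across groups. Default +0.25.
#' @param protein_ng Protein mass loaded per assay well, ng.
#' @param replicate_cv Within-assay replicate coefficient of variation.
#' @param n_replicates Assay replicates per limb. Default 3 (triplicates).
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_pairs = 7L,
                        groups = c("WT", "OpnKO"),
                        toughness_mean = 4.0, toughness_sd = 0.5,
                        toughness_limb_sd = 0.15,
                        toughness_effect = 0.18,
                        phospho_mean = 5e-4, phospho_sd = 8e-5,
                        phospho_limb_sd = 2e-5,
                        phospho_effect = 0.25,
                        protein_ng = 1000,
                        replicate_cv = 0.05,
                        n_replicates = 3L,
                        seed = 1L) {
  if (n_pairs < 2L) abort("need at least 2 pairs per group")
  if (toughness_sd <= 0 || phospho_sd <= 0) abort("SDs must be positive")
  structure(
    list(n_pairs = as.integer(n_pairs), groups = groups,
         toughness_mean = toughness_mean, toughness_sd = toughness_sd,
         toughness_limb_sd = toughness_limb_sd,
         toughness_effect = rep_len(toughness_effect, length(groups)),
         phospho_mean = phospho_mean, phospho_sd = phospho_sd,
         phospho_limb_sd = phospho_limb_sd,
         phospho_effect = rep_len(phospho_effect, length(groups)),
         protein_ng = protein_ng, replicate_cv = replicate_cv,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

draw_paired_measure <- function(spec, mean, sd_between, sd_limb, effects) {
  purrr::imap_dfr(setNames(effects, spec$groups), function(effect, g) {
    purrr::map_dfr(seq_len(spec$n_pairs), function(i) {
      underlying <- mean + rnorm(1, 0, sd_between)
      treated_limb <- sample(c("left", "right"), 1)
      tibble::tibble(
        animal = sprintf("%s-%02d", g, i),
        group = g,
        arm = c("control", "treated"),
        limb = c(setdiff(c("left", "right"), treated_limb), treated_limb),
        true_underlying = underlying,
        true_effect = effect,
        value = c(underlying + rnorm(1, 0, sd_limb),
                  underlying * (1 + effect) + rnorm(1, 0, sd_limb))
      )
    })
  })
}

#' Generate a synthetic paired cohort with known ground truth
#'
#' Draws per-animal toughness and phosphorylation values under the
#' [cohort_spec()] model (treated limb = underlying control value times
#' `1 + effect`, plus limb-level residual; limb assignment randomized per
#' animal), and expands phosphorylation into replicate absorbance readings.
#' Identical seeds give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List of tibbles: `toughness` (animal, group, arm, limb, `value` =
#'   Kc in MPa m^0.5, plus ground-truth columns) and `phospho_assays` (one
#'   row per replicate: id, animal, group, arm, limb, replicate, `absorbance`
#'   AU, `protein` ng, plus the true level).
#' @export
generate_paired_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed %||% spec$seed, {
    toughness <- draw_paired_measure(spec, spec$toughness_mean,
                                     spec$toughness_sd,
                                     spec$toughness_limb_sd,
                                     spec$toughness_effect)
    phospho <- draw_paired_measure(spec, spec$phospho_mean, spec$phospho_sd,
                                   spec$phospho_limb_sd, spec$phospho_effect)
    assays <- phospho |>
      dplyr::rename(true_level = "value") |>
      dplyr::group_by(dplyr::across(dplyr::everything())) |>
      dplyr::reframe(replicate = seq_len(spec$n_replicates)) |>
      dplyr::mutate(
        id = paste(.data$animal, .data$arm, sep = "-"),
        protein = spec$protein_ng,
        absorbance = .data$true_level * .data$protein *
          (1 + rnorm(dplyr::n(), 0, spec$replicate_cv))
      )
    list(toughness = toughness, phospho_assays = assays)
  })
}

#' Generate random valid notched-specimen geometries
#'
#' Uniformly samples femur-like geometries inside the validity envelope of
#' the toughness pipeline (half crack angles well inside 0-110 degrees,
#' annular cross-sections with mid-wall ratios inside the factor-table
#' domain) together with maximum loads, for exercising [kc_max_load()].
#'
#' @param n Number of specimens.
#' @param seed Integer seed.
#' @param p_max_range Maximum-load range in newtons.
#' @param angle_range Half-crack-angle range in degrees.
#' @return Tibble: `id`, `P_max` (N), `span` (m), `R_outer`, `R_inner` (m),
#'   `half_crack_angle` (deg), `notch_cortex_fraction`.
#' @export
generate_notched_specimens <- function(n, seed = NULL,
                                       p_max_range = c(8, 25),
                                       angle_range = c(30, 100)) {
  with_seed(seed, {
    r_out <- runif(n, 0.7e-3, 1.1e-3)
    # wall thickness chosen so Rm/t stays inside the tabulated ratio range
    thick <- runif(n, 0.15, 0.4) * r_out
    tibble::tibble(
      id = sprintf("spec-%03d", seq_len(n)),
      P_max = runif(n, p_max_range[1], p_max_range[2]),
      span = runif(n, 5e-3, 7e-3),
      R_outer = r_out,
      R_inner = r_out - thick,
      half_crack_angle = runif(n, angle_range[1], angle_range[2]),
      notch_cortex_fraction = runif(n, 0.1, 0.3)
    )
  })
}
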