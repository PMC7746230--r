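#' Summarize per-pull energies by experimental condition
#'
#' Aggregates accepted pulls into per-condition summaries: n, mean dissipated
#' energy, SD and standard error of the mean (SE = SD / sqrt(n)). Rejected
#' pulls are excluded from the statistics but counted.
#'
#' @param metrics A tibble of per-pull metrics ([process_curves()] output or
#'   the same schema), with an `energy` column and optionally `accepted`.
#' @param by Character vector of grouping columns (e.g. `c("substrate",
#'   "solution")`). Defaults to whichever of `substrate`, `solution`, `ph`,
#'   `opn_state` are present; with none present, one overall summary row.
#' @return A tibble with the grouping columns plus `n`, `n_rejected`,
#'   `mean_energy`, `sd_energy`, `se_energy` (all energies in joules).
#' @export
#' @examples
#' m <- tibble::tibble(energy = c(2e-18, 4e-18), accepted = TRUE)
#' summarize_condition(m)
summarize_condition <- function(metrics, by = NULL) {
  stopifnot(is.data.frame(metrics))
  if (!"energy" %in% names(metrics)) abort("metrics need an `energy` column")
  if (is.null(by)) {
    by <- intersect(c("substrate", "solution", "ph", "opn_state"),
                    names(metrics))
  }
  if (!"accepted" %in% names(metrics)) metrics$accepted <- TRUE
  out <- metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = sum(.data$accepted),
      n_rejected = sum(!.data$accepted),
      mean_energy = mean(.data$energy[.data$accepted]),
      sd_energy = sd(.data$energy[.data$accepted]),
      se_energy = .data$sd_energy / sqrt(.data$n),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    abort("every condition needs at least 2 accepted pulls")
  }
  out
}

#' Normalize condition summaries to their reference environment
#'
#' Divides each condition's mean energy and SE by the mean energy of the
#' substrate's reference condition (by default EDTA on mica, water on
#' hydroxyapatite), so the reference condition's normalized mean is exactly 1.
#' Normalization is a display scaling: statistics run on raw energies.
#'
#' @param summaries A [summarize_condition()] tibble containing `substrate`
#'   and `solution` columns.
#' @param reference_map Named character vector, substrate -> reference
#'   solution. Default `c(mica = "EDTA", HA = "H2O")`.
#' @return The input with `normalized_mean`, `normalized_se` and
#'   `reference_solution` columns added.
#' @export
normalize_to_reference <- function(summaries,
                                   reference_map = c(mica = "EDTA",
                                                     HA = "H2O")) {
  stopifnot(is.data.frame(summaries))
  need <- c("substrate", "solution", "mean_energy", "se_energy")
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    abort(sprintf("summaries are missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(split(summaries, summaries$substrate), function(grp) {
    sub <- grp$substrate[1]
    ref_sol <- reference_map[[sub]] %||%
      abort(sprintf("no reference solution declared for substrate '%s'", sub))
    ref <- grp$mean_energy[grp$solution == ref_sol]
    if (!length(ref)) {
      abort(sprintf("substrate '%s' group lacks its reference condition '%s'",
                    sub, ref_sol))
    }
    ref <- ref[1]
    if (!is.finite(ref) || ref <= 0) {
      abort(sprintf("reference condition '%s' has non-positive mean energy",
                    ref_sol))
    }
    grp$normalized_mean <- grp$mean_energy / ref
    grp$normalized_se <- grp$se_energy / ref
    grp$normalized_mean[grp$solution == ref_sol] <- 1
    grp$reference_solution <- ref_sol
    grp
  })
}

#' Compare dissipated energy between two conditions
#'
#' Runs the Kolmogorov-Smirnov normality check on each group's energies and a
#' two-sided unpaired Student's t-test (significance threshold 0.05) on the
#' raw (not normalized) energies. Non-normal groups are flagged, not gated.
#'
#' @param a,b Per-pull metrics tibbles (accepted rows are used) or numeric
#'   energy vectors; each group needs n >= 3.
#' @param labels Length-2 character vector naming the conditions.
#' @param equal_variance Pooled-variance Student form (default TRUE).
#' @return A list of class `"condition_comparison"`: `t_test` (the
#'   [test_report]), `ks_a`, `ks_b`, `summary` tibble.
#' @export
compare_conditions <- function(a, b, labels = c("a", "b"),
                               equal_variance = TRUE) {
  pull_energies <- function(x, lab) {
    if (is.data.frame(x)) {
      if (!"energy" %in% names(x)) abort("metrics need an `energy` column")
      acc <- if ("accepted" %in% names(x)) x$accepted else TRUE
      x <- x$energy[acc]
    }
    x <- as.numeric(x)
    if (length(x) < 3L) {
      abort(sprintf("condition '%s' needs at least 3 accepted pulls", lab))
    }
    if (sd(x) == 0) {
      abort(sprintf("condition '%s' has zero energy variance", lab))
    }
    x
  }
  ea <- pull_energies(a, labels[1])
  eb <- pull_energies(b, labels[2])
  res <- list(
    t_test = unpaired_t(ea, eb, equal_variance = equal_variance,
                        labels = labels),
    ks_a = ks_normality(ea),
    ks_b = ks_normality(eb),
    summary = group_summary(list(ea, eb), labels)
  )
  class(res) <- "condition_comparison"
  res
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (raw energies)\n")
  print(x$t_test)
  cat(sprintf("normality (KS): p = %.4g / %.4g%s\n",
              x$ks_a$p_value, x$ks_b$p_value,
              if (isTRUE(x$ks_a$significant) || isTRUE(x$ks_b$significant))
                "  [non-normality flagged]" else ""))
  invisible(x)
}

#' @rdname compare_conditions
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @export
tidy.condition_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tidy(x$t_test),
    tidy(x$ks_a) |> dplyr::mutate(test = paste0(.data$test, " (",
                                                x$summary$group[1], ")")),
    tidy(x$ks_b) |> dplyr::mutate(test = paste0(.data$test, " (",
                                                x$summary$group[2], ")"))
  )
}

#' @rdname compare_conditions
#' @export
glance.condition_comparison <- function(x, ...) {
  tibble::tibble(
    p_value = x$t_test$p_value,
    significant = x$t_test$significant,
    normal_a = !x$ks_a$significant,
    normal_b = !x$ks_b$significant
  )
}

#' Bar plot of normalized condition energies
#'
#' @param summaries A [normalize_to_reference()] tibble.
#' @return A ggplot: normalized mean dissipated energy per condition with SE
#'   error bars, faceted by substrate.
#' @export
plot_condition_summary <- function(summaries) {
  stopifnot(all(c("solution", "normalized_mean", "normalized_se") %in%
                  names(summaries)))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$solution, y = .data$normalized_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$normalized_mean - .data$normalized_se,
                   ymax = .data$normalized_mean + .data$normalized_se),
      width = 0.25) +
    ggplot2::facet_wrap(~substrate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "normalized dissipated energy") +
    ggplot2::theme_minimal()
}
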