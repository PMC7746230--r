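#' Global matrix phosphorylation level
#'
#' The phosphoprotein assay readout per specimen: mean replicate absorbance
#' divided by the protein mass, i.e. absorbance per nanogram of protein.
#' Assays are normally run in triplicate; the replicate coefficient of
#' variation is reported, and is NA (flagged) for a single replicate.
#'
#' @param absorbance Numeric replicate absorbances (AU), length >= 1.
#' @param protein Protein mass in nanograms (> 0).
#' @return One-row tibble: `level` (AU/ng), `n_replicates`, `replicate_cv`.
#' @export
#' @examples
#' phospho_level(c(0.49, 0.50, 0.51), protein = 1000)
phospho_level <- function(absorbance, protein) {
  if (!length(absorbance)) abort("need at least one absorbance replicate")
  if (!is.numeric(protein) || length(protein) != 1L || protein <= 0) {
    abort("`protein` must be a single positive mass in ng")
  }
  m <- mean(absorbance)
  tibble::tibble(
    level = m / protein,
    n_replicates = length(absorbance),
    replicate_cv = if (length(absorbance) > 1L) sd(absorbance) / m else
      NA_real_
  )
}

#' Phosphorylation levels for an assay table
#'
#' @param assays Tibble with one row per replicate: `id`, `absorbance` (AU),
#'   `protein` (ng), plus any per-specimen columns (carried through).
#' @return One row per `id` with `level`, `n_replicates`, `replicate_cv`.
#' @export
phospho_levels <- function(assays) {
  stopifnot(is.data.frame(assays))
  need <- c("id", "absorbance", "protein")
  if (!all(need %in% names(assays))) {
    abort("assay table needs `id`, `absorbance` and `protein` columns")
  }
  carry <- setdiff(names(assays), c("absorbance", "replicate"))
  assays |>
    dplyr::group_by(dplyr::across(dplyr::all_of(carry))) |>
    dplyr::summarise(
      lv = list(phospho_level(.data$absorbance, .data$protein[1])),
      .groups = "drop"
    ) |>
    tidyr::unnest("lv") |>
    dplyr::select(-dplyr::any_of("protein"), dplyr::everything())
}

#' Paired contralateral-limb deltas and their tests
#'
#' The cohort arm's central construction: per animal, the treated-limb value
#' minus the contralateral-control value (delta). Within each genotype group a
#' paired t-test compares treated against control; between groups the deltas
#' (e.g. delta-WT vs delta-KO) are compared by a two-tailed
#' independent-samples t-test, isolating the contribution of the targeted
#' protein. Threshold 0.05 throughout.
#'
#' @param cohort Tidy tibble with columns `animal`, `group`, `arm` (exactly
#'   one `"treated"` and one `"control"` row per animal) and the measurement
#'   column named by `value`.
#' @param value Name of the measurement column. Default `"value"`.
#' @return A list of class `"paired_analysis"`: `deltas` tibble (`animal`,
#'   `group`, `treated`, `control`, `delta`), `paired_tests` (one
#'   [test_report] per group), `delta_test` (between-group unpaired
#'   [test_report], NULL with < 2 groups).
#' @export
paired_deltas <- function(cohort, value = "value") {
  stopifnot(is.data.frame(cohort))
  need <- c("animal", "group", "arm", value)
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    abort(sprintf("cohort is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  bad_arm <- setdiff(unique(cohort$arm), c("treated", "control"))
  if (length(bad_arm)) {
    abort(sprintf("unknown arm label '%s'", bad_arm[1]))
  }
  counts <- cohort |>
    dplyr::count(.data$animal, .data$arm) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n",
                       values_fill = 0L)
  n_of <- function(arm) if (arm %in% names(counts)) counts[[arm]] else 0L
  bad <- counts$animal[n_of("treated") != 1L | n_of("control") != 1L]
  if (length(bad)) {
    abort(sprintf("animal '%s' does not contribute exactly one treated and one control value",
                  bad[1]))
  }
  deltas <- cohort |>
    dplyr::select(dplyr::all_of(c("animal", "group", "arm", value))) |>
    tidyr::pivot_wider(names_from = "arm", values_from = dplyr::all_of(value)) |>
    dplyr::mutate(delta = .data$treated - .data$control) |>
    dplyr::arrange(.data$group, .data$animal)
  paired_tests <- deltas |>
    split(deltas$group) |>
    purrr::map(function(g) {
      paired_t(g$treated, g$control,
               labels = paste0(g$group[1], c("-treated", "-control")))
    })
  groups <- names(paired_tests)
  delta_test <- if (length(groups) >= 2L) {
    unpaired_t(deltas$delta[deltas$group == groups[1]],
               deltas$delta[deltas$group == groups[2]],
               labels = paste0("delta-", groups[1:2]))
  } else {
    NULL
  }
  structure(list(deltas = deltas, paired_tests = paired_tests,
                 delta_test = delta_test, value = value),
            class = "paired_analysis")
}

#' @export
print.paired_analysis <- function(x, ...) {
  cat(sprintf("Paired contralateral-limb analysis of `%s` (%d animals, %d groups)\n",
              x$value, nrow(x$deltas), length(x$paired_tests)))
  for (g in names(x$paired_tests)) {
    d <- x$deltas[x$deltas$group == g, ]
    cat(sprintf("  %s: mean delta = %.4g (%.1f%% of control mean), ",
                g, mean(d$delta), 100 * mean(d$delta) / mean(d$control)))
    print(x$paired_tests[[g]])
  }
  if (!is.null(x$delta_test)) {
    cat("  between-group test on deltas:\n  ")
    print(x$delta_test)
  }
  invisible(x)
}

#' @rdname paired_deltas
#' @param x A `paired_analysis`.
#' @param ... Unused.
#' @export
tidy.paired_analysis <- function(x, ...) {
  rows <- purrr::imap_dfr(x$paired_tests, function(tst, g) {
    d <- x$deltas[x$deltas$group == g, ]
    tidy(tst) |>
      dplyr::mutate(group = g, mean_delta = mean(d$delta),
                    relative_delta = mean(d$delta) / mean(d$control),
                    .before = 1)
  })
  if (!is.null(x$delta_test)) {
    rows <- dplyr::bind_rows(
      rows,
      tidy(x$delta_test) |>
        dplyr::mutate(group = "between-group", .before = 1))
  }
  rows
}

#' @rdname paired_deltas
#' @export
glance.paired_analysis <- function(x, ...) {
  tibble::tibble(
    n_animals = nrow(x$deltas),
    n_groups = length(x$paired_tests),
    delta_p_value = if (is.null(x$delta_test)) NA_real_ else
      x$delta_test$p_value
  )
}

#' @rdname paired_deltas
#' @param object A `paired_analysis`.
#' @export
autoplot.paired_analysis <- function(object, ...) {
  long <- object$deltas |>
    tidyr::pivot_longer(c("control", "treated"),
                        names_to = "arm", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value,
                                     group = .data$animal)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = object$value) +
    ggplot2::theme_minimal()
}
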