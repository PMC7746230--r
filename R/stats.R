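#' Statistical test reports
#'
#' The pipeline's hypothesis tests all return a one-row tibble of class
#' `"test_report"` with a common schema: test name, statistic, degrees of
#' freedom, two-tailed p-value, the decision at alpha = 0.05, per-group
#' summaries (n, mean, SD) and a `degenerate` flag. Degenerate inputs
#' (zero-variance groups) yield a flagged report rather than silent NaN.
#'
#' @name test_report
NULL

new_test_report <- function(test, statistic, df, p_value,
                            groups, degenerate = FALSE, note = NA_character_,
                            alpha = 0.05) {
  tibble::tibble(
    test = test,
    statistic = statistic,
    df = df,
    p_value = p_value,
    significant = !is.na(p_value) & p_value < alpha,
    alpha = alpha,
    degenerate = degenerate,
    note = note,
    groups = list(groups)
  ) |>
    structure(class = c("test_report", "tbl_df", "tbl", "data.frame"))
}

group_summary <- function(values, labels) {
  tibble::tibble(
    group = labels,
    n = vapply(values, length, integer(1)),
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, sd, numeric(1))
  )
}

#' Paired t-test
#'
#' Classic paired t-test on the differences `x - y`, two-tailed, with n - 1
#' degrees of freedom. Used for treated-versus-contralateral-control limb
#' comparisons within a genotype.
#'
#' @param x,y Numeric vectors of equal length (n >= 2), paired by position.
#' @param labels Length-2 character vector naming the two arms.
#' @param alpha Two-tailed significance threshold. Default 0.05.
#' @return A [test_report] tibble.
#' @export
#' @examples
#' paired_t(c(4.1, 4.4, 4.6), c(3.8, 4.0, 4.1))
paired_t <- function(x, y, labels = c("x", "y"), alpha = 0.05) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("paired samples must have equal length")
  if (length(x) < 2L) abort("need at least 2 pairs")
  groups <- group_summary(list(x, y), labels)
  d <- x - y
  ht <- tryCatch(t.test(x, y, paired = TRUE, alternative = "two.sided"),
                 error = function(e) NULL)
  if (is.null(ht) || sd(d) == 0 || !is.finite(sd(d))) {
    return(new_test_report("paired t", NA_real_, length(d) - 1, NA_real_,
                           groups, degenerate = TRUE,
                           note = "zero-variance differences", alpha = alpha))
  }
  new_test_report("paired t", unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, groups, alpha = alpha)
}

#' Unpaired two-sample t-test
#'
#' Two-sided independent-samples t-test; the pooled-variance Student form by
#' default, with the Welch unequal-variance form behind a switch.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param equal_variance Use the pooled-variance Student form (default TRUE).
#' @inheritParams paired_t
#' @return A [test_report] tibble.
#' @export
#' @examples
#' unpaired_t(rnorm(20), rnorm(20, 1))
unpaired_t <- function(x, y, equal_variance = TRUE, labels = c("x", "y"),
                       alpha = 0.05) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2L || length(y) < 2L) abort("each group needs n >= 2")
  groups <- group_summary(list(x, y), labels)
  if (sd(x) == 0 && sd(y) == 0) {
    return(new_test_report("unpaired t", NA_real_, NA_real_, NA_real_,
                           groups, degenerate = TRUE,
                           note = "both groups have zero variance",
                           alpha = alpha))
  }
  ht <- t.test(x, y, var.equal = isTRUE(equal_variance),
               alternative = "two.sided")
  name <- if (isTRUE(equal_variance)) "unpaired t (Student)" else
    "unpaired t (Welch)"
  new_test_report(name, unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, groups, alpha = alpha)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic against a normal distribution with the sample's own
#' mean and SD, with the plain asymptotic p-value. Because the reference
#' parameters are estimated from the same sample, this p-value is conservative
#' (a Lilliefors correction is deliberately not applied); the report carries
#' that caveat in `note`. The check is used to flag, not gate, non-normal
#' energy distributions.
#'
#' @param x Numeric sample, n >= 5.
#' @inheritParams paired_t
#' @return A [test_report] tibble.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  stopifnot(is.numeric(x))
  if (length(x) < 5L) abort("need at least 5 observations for the KS check")
  groups <- group_summary(list(x), "x")
  if (sd(x) == 0 || !is.finite(sd(x))) {
    return(new_test_report("KS normality", NA_real_, NA_real_, NA_real_,
                           groups, degenerate = TRUE,
                           note = "zero-variance sample"))
  }
  ht <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  new_test_report("KS normality", unname(ht$statistic), NA_real_, ht$p.value,
                  groups,
                  note = "reference mean/SD estimated from the sample",
                  alpha = alpha)
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<%s>  statistic = %s, df = %s, p = %s  [%s at alpha = %g]%s\n",
              x$test,
              format(x$statistic, digits = 5),
              format(x$df, digits = 5),
              format(x$p_value, digits = 5),
              if (isTRUE(x$significant)) "significant" else "not significant",
              x$alpha,
              if (isTRUE(x$degenerate)) sprintf("  DEGENERATE: %s", x$note)
              else ""))
  print(x$groups[[1]])
  invisible(x)
}

#' @rdname test_report
#' @param x A `test_report`.
#' @param ... Unused.
#' @export
tidy.test_report <- function(x, ...) {
  tibble::as_tibble(x[, c("test", "statistic", "df", "p_value",
                          "significant", "degenerate", "note")])
}

#' @rdname test_report
#' @export
glance.test_report <- function(x, ...) {
  g <- x$groups[[1]]
  tibble::tibble(
    test = x$test, p_value = x$p_value, significant = x$significant,
    n_total = sum(g$n), n_groups = nrow(g)
  )
}

# Plain-text rendering shared by the CLI report emitters.
format_test_report <- function(x) {
  g <- x$groups[[1]]
  c(sprintf("test: %s", x$test),
    sprintf("statistic: %.6g", x$statistic),
    sprintf("df: %s", format(x$df)),
    sprintf("p_value: %.6g", x$p_value),
    sprintf("decision: %s (alpha = %g)",
            if (isTRUE(x$significant)) "significant" else "not significant",
            x$alpha),
    if (isTRUE(x$degenerate)) sprintf("degenerate: %s", x$note),
    sprintf("group %s: n = %d, mean = %.6g, sd = %.6g",
            g$group, g$n, g$mean, g$sd))
}
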