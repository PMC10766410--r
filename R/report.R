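#' Cohort pre/post comparison report
#'
#' Assembles the table of paired pre/post comparisons for the endocrine
#' metrics: per hormone the mean endogenous level and the time-normalized
#' GnRH-stimulated AUC response, plus (when pulse statistics are supplied)
#' the LH pulse amplitude and interpulse interval. Each row is a
#' [paired_compare()] result. Subjects missing either visit for a metric are
#' dropped pairwise with a message; a metric with fewer than 2 complete
#' pairs is an error. No multiple-testing correction is applied across rows:
#' each metric's p-value is reported as-is.
#'
#' @param visit_summaries Tibble from [summarize_cohort()] covering both
#'   visits.
#' @param pulse_stats Optional tibble from [pulsatility_by_subject()] with
#'   both visits (typically LH only).
#' @return A tibble of paired results, one row per metric.
#' @export
build_report <- function(visit_summaries, pulse_stats = NULL) {
  vs <- tibble::as_tibble(visit_summaries)
  need <- c("subject_id", "visit", "hormone", "mean_endogenous",
            "auc_stimulated_norm")
  if (!all(need %in% names(vs))) {
    stop("visit_summaries must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }

  rows <- list()
  for (h in unique(vs$hormone)) {
    vh <- vs[vs$hormone == h, ]
    rows[[length(rows) + 1L]] <- paired_metric_row(
      vh, "mean_endogenous", sprintf("Mean %s (IU/L)", h)
    )
    rows[[length(rows) + 1L]] <- paired_metric_row(
      vh, "auc_stimulated_norm", sprintf("%s response to GnRH (IU/L)", h)
    )
  }
  if (!is.null(pulse_stats)) {
    ps <- tibble::as_tibble(pulse_stats)
    for (h in unique(ps$hormone)) {
      ph <- ps[ps$hormone == h, ]
      rows[[length(rows) + 1L]] <- paired_metric_row(
        ph, "mean_amplitude", sprintf("%s pulse amplitude (IU/L)", h)
      )
      rows[[length(rows) + 1L]] <- paired_metric_row(
        ph, "mean_ipi", sprintf("%s interpulse interval (min)", h)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Pivot one metric to subject-aligned pre/post columns and run the paired
# comparison.
paired_metric_row <- function(df, column, label) {
  wide <- df |>
    dplyr::select(dplyr::all_of(c("subject_id", "visit", column))) |>
    tidyr::pivot_wider(names_from = "visit",
                       values_from = dplyr::all_of(column))
  if (!all(c("pre", "post") %in% names(wide))) {
    stop("both visits must be present to compare '", label, "'",
         call. = FALSE)
  }
  complete <- is.finite(wide$pre) & is.finite(wide$post)
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message(n_drop, " subject(s) without a complete pre/post pair dropped ",
            "for '", label, "'")
  }
  if (sum(complete) < 2) {
    stop("no usable pre/post pairs for '", label,
         "': at least 2 complete pairs are required", call. = FALSE)
  }
  paired_compare(wide$pre[complete], wide$post[complete], metric = label)
}

#' Format a comparison report as a text table
#'
#' @param report Tibble from [build_report()].
#' @return A character vector of lines (also printed when assigned
#'   invisibly is not wanted); geometric means are shown for log-analyzed
#'   rows.
#' @export
format_report <- function(report) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.2f", p))
  lines <- c(
    sprintf("%-34s %9s %9s %8s %12s %7s", "Metric", "Pre", "Post",
            "Change%", "Test", "P"),
    sprintf("%-34s %9.2f %9.2f %8.1f %12s %7s",
            report$metric,
            ifelse(is.na(report$pre_gm), report$pre_mean, report$pre_gm),
            ifelse(is.na(report$post_gm), report$post_mean, report$post_gm),
            report$percent_change, report$test_used, fmt_p(report$p_value))
  )
  lines
}
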