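#' Trapezoidal area under the curve
#'
#' Composite trapezoid rule over the supplied samples; exact for piecewise
#' linear input. Units: IU.min/L for an IU/L series sampled in minutes.
#'
#' @param times Strictly increasing sampling times (minutes).
#' @param values Hormone concentrations (IU/L), same length.
#' @return The integral as a single number.
#' @examples
#' trapezoid_auc(c(0, 10, 20), c(1, 2, 3))  # 40
#' @export
trapezoid_auc <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 2) {
    stop("AUC needs at least 2 samples", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  pracma::trapz(times, values)
}

#' Per-visit endocrine response metrics
#'
#' Splits a series at the GnRH bolus and computes the Table-style scalar
#' metrics: the arithmetic mean of the endogenous samples (0 to
#' `gnrh_time`), and the trapezoidal AUC of the endogenous and stimulated
#' windows, both raw (IU.min/L) and time-normalized (divided by the window
#' length, giving IU/L commensurate with mean levels). The bolus-time sample
#' belongs to both windows (the bolus is administered at that instant).
#' No baseline subtraction is applied to the stimulated window.
#'
#' @param series A [hormone_series()] with a `gnrh_time` and full coverage
#'   of both windows.
#' @return A one-row tibble: `subject_id`, `visit`, `hormone`,
#'   `mean_endogenous`, `auc_endogenous`, `auc_endogenous_norm`,
#'   `auc_stimulated`, `auc_stimulated_norm`.
#' @export
summarize_visit <- function(series) {
  if (!inherits(series, "hormone_series")) {
    stop("series must be a hormone_series", call. = FALSE)
  }
  gt <- series$gnrh_time
  if (is.null(gt)) {
    stop("series has no gnrh_time: cannot split endogenous and stimulated ",
         "windows", call. = FALSE)
  }
  endo <- series$times <= gt + 1e-9
  stim <- series$times >= gt - 1e-9
  if (sum(endo) < 2 || sum(stim) < 2) {
    stop("series must cover both the endogenous and the stimulated window",
         call. = FALSE)
  }
  t_endo <- series$times[endo]
  t_stim <- series$times[stim]
  auc_e <- trapezoid_auc(t_endo, series$values[endo])
  auc_s <- trapezoid_auc(t_stim, series$values[stim])
  tibble::tibble(
    subject_id = series$subject_id,
    visit = series$visit,
    hormone = series$hormone,
    mean_endogenous = mean(series$values[endo]),
    auc_endogenous = auc_e,
    auc_endogenous_norm = auc_e / (max(t_endo) - min(t_endo)),
    auc_stimulated = auc_s,
    auc_stimulated_norm = auc_s / (max(t_stim) - min(t_stim))
  )
}

#' @rdname summarize_visit
#' @param cohort A `hormone_cohort` or list of series.
#' @return `summarize_cohort()` row-binds [summarize_visit()] over all
#'   series.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  dplyr::bind_rows(lapply(cohort, summarize_visit))
}

#' Percent change from pre to post
#'
#' `100 * (pre - post) / pre`: the percent suppression of a metric at the
#' post visit relative to the pre visit. Rounding happens only at reporting.
#'
#' @param pre,post Positive pre-visit value(s) and post-visit value(s).
#' @return Percent change (vectorized).
#' @examples
#' percent_change(10.1, 7.2)  # 28.7..., reported as 29%
#' @export
percent_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0)) {
    stop("pre must be strictly positive", call. = FALSE)
  }
  100 * (pre - post) / pre
}
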