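#' A single subject-visit hormone concentration trace
#'
#' Container for one uniformly sampled frequent-sampling series: times in
#' minutes from the start of sampling, concentrations in IU/L, and the time
#' of the GnRH bolus splitting the endogenous from the stimulated window.
#'
#' @param times Numeric vector of sampling times (minutes), strictly
#'   increasing on a uniform grid.
#' @param values Non-negative hormone concentrations (IU/L), same length.
#' @param subject_id Subject identifier.
#' @param visit `"pre"` or `"post"`.
#' @param hormone `"LH"` or `"FSH"`.
#' @param gnrh_time Time of the GnRH bolus (minutes), or `NULL` for a series
#'   without a stimulation phase.
#' @return An object of class `hormone_series`.
#' @export
hormone_series <- function(times, values, subject_id = "S001",
                           visit = c("pre", "post"), hormone = c("LH", "FSH"),
                           gnrh_time = NULL) {
  visit <- match.arg(visit)
  hormone <- match.arg(hormone)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 2) {
    stop("a series needs at least 2 samples", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(abs(dt - dt[1]) > 1e-8 * max(dt[1], 1))) {
    stop("times must lie on a uniform grid", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(gnrh_time)) {
    gnrh_time <- as.numeric(gnrh_time)
    if (!any(abs(times - gnrh_time) < 1e-9)) {
      stop("gnrh_time must coincide with a sampling time", call. = FALSE)
    }
  }
  structure(
    list(subject_id = as.character(subject_id), visit = visit,
         hormone = hormone, times = times, values = values,
         gnrh_time = gnrh_time),
    class = "hormone_series"
  )
}

#' @export
print.hormone_series <- function(x, ...) {
  cat("<hormone_series> ", x$subject_id, " / ", x$visit, " / ", x$hormone,
      ": ", length(x$times), " samples, ", x$times[1], "-",
      x$times[length(x$times)], " min",
      if (!is.null(x$gnrh_time)) paste0(" (GnRH at ", x$gnrh_time, " min)"),
      "\n", sep = "")
  invisible(x)
}

#' Convert series objects to a long tibble
#'
#' @param x A `hormone_series` or `hormone_cohort`.
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `visit`, `hormone`,
#'   `time_min`, `value_iu_l`.
#' @export
series_tibble <- function(x, ...) {
  UseMethod("series_tibble")
}

#' @export
series_tibble.hormone_series <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, visit = x$visit, hormone = x$hormone,
    time_min = x$times, value_iu_l = x$values
  )
}

#' @export
series_tibble.hormone_cohort <- function(x, ...) {
  dplyr::bind_rows(lapply(x, series_tibble))
}

#' @export
series_tibble.list <- function(x, ...) {
  dplyr::bind_rows(lapply(x, series_tibble))
}

#' @export
print.hormone_cohort <- function(x, ...) {
  tb <- series_tibble(x)
  cat("<hormone_cohort> ", length(x), " series (",
      dplyr::n_distinct(tb$subject_id), " subjects x ",
      dplyr::n_distinct(tb$visit), " visits x ",
      dplyr::n_distinct(tb$hormone), " hormones)\n", sep = "")
  invisible(x)
}
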