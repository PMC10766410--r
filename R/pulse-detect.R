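# Modified Santen-Bardin pulse detection.
#
# The committed sweep semantics: scan left to right keeping a running nadir
# (the earliest minimum since the last confirmed pulse). A sample qualifies
# when its rise over the running nadir is at least `threshold` (relative,
# default 20%). Under the single-point criterion one qualifying sample
# confirms a pulse; under the two-point criterion two consecutive samples
# must qualify against the same nadir. The peak is the earliest maximum from
# the first qualifying sample until the first strict decline; the running
# nadir then restarts at the sample after the peak.

sweep_detect <- function(v, threshold, two_point) {
  n <- length(v)
  pairs <- list()
  zero_nadir <- FALSE
  nad <- 1L
  i <- 2L
  while (i <= n) {
    nv <- v[nad]
    qual <- FALSE
    if (nv > 0) {
      qual <- (v[i] - nv) / nv >= threshold - 1e-12
    } else if (v[i] > nv) {
      zero_nadir <- TRUE
    }
    confirmed <- qual &&
      (!two_point || (i < n && (v[i + 1L] - nv) / nv >= threshold - 1e-12))
    if (confirmed) {
      peak <- i
      k <- i + 1L
      while (k <= n && v[k] >= v[k - 1L]) {
        if (v[k] > v[peak]) peak <- k
        k <- k + 1L
      }
      pairs[[length(pairs) + 1L]] <- c(nad, peak)
      nad <- peak + 1L
      i <- peak + 2L
      if (nad > n) break
    } else {
      if (v[i] < v[nad]) nad <- i
      i <- i + 1L
    }
  }
  list(pairs = pairs, zero_nadir = zero_nadir)
}

#' Detect LH pulses with the modified Santen-Bardin criterion
#'
#' Identifies pulses in the endogenous window of a frequent-sampling series
#' as excursions whose peak exceeds the preceding nadir by at least
#' `threshold` (a 20% nadir-to-peak rise by default). The `single_point`
#' criterion confirms a pulse from one qualifying sample; the stricter
#' `two_point` criterion requires two consecutive qualifying samples.
#' Detection is confined to the endogenous window (`window_end`, at most the
#' GnRH bolus time): the stimulated rise would otherwise always be called a
#' pulse.
#'
#' @param series A [hormone_series()].
#' @param criterion `"single_point"` (default, the headline method) or
#'   `"two_point"`.
#' @param threshold Minimum relative nadir-to-peak rise (default 0.20).
#' @param window_end End of the detection window in minutes; defaults to the
#'   series' GnRH time and must not exceed it.
#' @return A `pulse_callset`: detected pulses (nadir and peak time/value,
#'   amplitude, relative rise) plus summaries `mean_amplitude` and
#'   `mean_ipi` (mean peak-to-peak interval; `NA` with fewer than 2 pulses).
#' @examples
#' s <- hormone_series(seq(0, 40, 10), c(5, 5, 6.5, 5, 5))
#' detect_pulses(s, "single_point")
#' @export
detect_pulses <- function(series, criterion = c("single_point", "two_point"),
                          threshold = 0.2, window_end = NULL) {
  criterion <- match.arg(criterion)
  if (!inherits(series, "hormone_series")) {
    stop("series must be a hormone_series", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive fraction", call. = FALSE)
  }
  if (is.null(window_end)) {
    window_end <- if (!is.null(series$gnrh_time)) series$gnrh_time
                  else max(series$times)
  }
  if (!is.null(series$gnrh_time) && window_end > series$gnrh_time + 1e-9) {
    stop("window_end must not extend past the GnRH bolus at ",
         series$gnrh_time, " min: pulse statistics are defined for ",
         "endogenous secretion only", call. = FALSE)
  }
  keep <- series$times <= window_end + 1e-9
  tt <- series$times[keep]
  vv <- series$values[keep]
  if (length(tt) < 3) {
    stop("detection window contains fewer than 3 samples", call. = FALSE)
  }

  res <- sweep_detect(vv, threshold, criterion == "two_point")
  if (res$zero_nadir) {
    warning("running nadir of 0 IU/L encountered; relative rise is ",
            "undefined there and such samples cannot qualify",
            call. = FALSE)
  }
  if (length(res$pairs)) {
    m <- do.call(rbind, res$pairs)
    pulses <- tibble::tibble(
      nadir_time = tt[m[, 1]],
      nadir_value = vv[m[, 1]],
      peak_time = tt[m[, 2]],
      peak_value = vv[m[, 2]]
    )
    pulses$amplitude <- pulses$peak_value - pulses$nadir_value
    pulses$relative_rise <- pulses$amplitude / pulses$nadir_value
  } else {
    pulses <- tibble::tibble(
      nadir_time = numeric(0), nadir_value = numeric(0),
      peak_time = numeric(0), peak_value = numeric(0),
      amplitude = numeric(0), relative_rise = numeric(0)
    )
  }

  structure(
    list(
      subject_id = series$subject_id, visit = series$visit,
      hormone = series$hormone, criterion = criterion,
      threshold = threshold, window_end = window_end,
      pulses = pulses,
      n_pulses = nrow(pulses),
      mean_amplitude = if (nrow(pulses)) mean(pulses$amplitude) else NA_real_,
      mean_ipi = if (nrow(pulses) >= 2) mean(diff(pulses$peak_time))
                 else NA_real_
    ),
    class = "pulse_callset"
  )
}

#' @export
print.pulse_callset <- function(x, ...) {
  cat("<pulse_callset> ", x$subject_id, " / ", x$visit, " / ", x$hormone,
      ": ", x$n_pulses, " pulse(s) [", x$criterion, ", threshold ",
      x$threshold, ", window 0-", x$window_end, " min]\n", sep = "")
  if (x$n_pulses) {
    cat(sprintf("  mean amplitude %.2f IU/L; mean interpulse interval %s\n",
                x$mean_amplitude,
                if (is.na(x$mean_ipi)) "undefined (<2 pulses)"
                else sprintf("%.1f min", x$mean_ipi)))
  }
  invisible(x)
}

#' Per-subject pulsatility table
#'
#' Flattens a list of pulse call sets into one row per series with the
#' pulse count, mean amplitude and mean interpulse interval.
#'
#' @param callsets List of `pulse_callset` objects.
#' @return A tibble with columns `subject_id`, `visit`, `hormone`,
#'   `n_pulses`, `mean_amplitude`, `mean_ipi`.
#' @export
pulsatility_by_subject <- function(callsets) {
  if (inherits(callsets, "pulse_callset")) callsets <- list(callsets)
  stopifnot(all(vapply(callsets, inherits, logical(1), "pulse_callset")))
  dplyr::bind_rows(lapply(callsets, function(cs) {
    tibble::tibble(
      subject_id = cs$subject_id, visit = cs$visit, hormone = cs$hormone,
      n_pulses = cs$n_pulses, mean_amplitude = cs$mean_amplitude,
      mean_ipi = cs$mean_ipi
    )
  }))
}

#' Cohort-level pulsatility summary
#'
#' Subject-level means first, then the cohort summary per visit (and
#' hormone): mean amplitude with its SD, and mean interpulse interval with
#' its SEM, matching the reporting convention of frequent-sampling studies.
#' Subjects with fewer than two pulses have no interpulse interval and are
#' excluded from the interval summary; the excluded count is reported in the
#' output and in a message.
#'
#' @param callsets List of `pulse_callset` objects (at least one per visit).
#' @return A tibble with one row per visit x hormone: `n_subjects`,
#'   `mean_amplitude`, `sd_amplitude`, `n_ipi`, `n_excluded_ipi`,
#'   `mean_ipi`, `sem_ipi`.
#' @export
summarize_pulsatility <- function(callsets) {
  by_subj <- pulsatility_by_subject(callsets)
  if (!nrow(by_subj)) {
    stop("no pulse call sets supplied", call. = FALSE)
  }
  out <- by_subj |>
    dplyr::group_by(.data$visit, .data$hormone) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      # aggregate under new names first: summarise exposes each result to
      # later expressions, so reusing input names would mask the columns
      amp_mean = mean(.data$mean_amplitude, na.rm = TRUE),
      amp_sd = sd(.data$mean_amplitude, na.rm = TRUE),
      n_ipi = sum(!is.na(.data$mean_ipi)),
      n_excluded_ipi = sum(is.na(.data$mean_ipi)),
      ipi_mean = mean(.data$mean_ipi, na.rm = TRUE),
      ipi_sem = sd(.data$mean_ipi, na.rm = TRUE) /
        sqrt(pmax(sum(!is.na(.data$mean_ipi)), 1)),
      .groups = "drop"
    ) |>
    dplyr::rename(mean_amplitude = "amp_mean", sd_amplitude = "amp_sd",
                  mean_ipi = "ipi_mean", sem_ipi = "ipi_sem")
  n_exc <- sum(out$n_excluded_ipi)
  if (n_exc > 0) {
    message(n_exc, " subject-visit(s) with <2 pulses excluded from the ",
            "interpulse-interval summary")
  }
  out
}
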