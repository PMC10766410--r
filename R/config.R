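#' Cohort configuration for the frequent-sampling simulator
#'
#' Bundles every parameter of the synthetic crossover cohort: the sampling
#' design (10-min draws over 6 h with a GnRH bolus at 240 min), the pulsatile
#' secretion model (renewal pulse train with truncated-normal interpulse
#' intervals and amplitudes, instantaneous rise and single-exponential
#' elimination), the GnRH-stimulated response level, the paired diet effect
#' (multiplicative suppression shared within subject), and the noise model
#' (multiplicative lognormal assay noise, lognormal between-subject level
#' heterogeneity).
#'
#' Defaults are calibrated to the pre-diet early-follicular LH column of the
#' study this pipeline targets: mean interpulse interval 83 min, pulse
#' amplitude 2.4 +/- 1.1 IU/L, mean endogenous LH 4.3 IU/L, time-normalized
#' GnRH-stimulated level 10.1 IU/L, intra-assay CV 3.4%. `basal_level` is the
#' non-pulsatile floor; its default 2.4 IU/L is chosen so that the stationary
#' endogenous mean (basal plus the renewal-average pulse contribution
#' `E[amplitude] * (halflife/ln 2) / mean_ipi`) equals 4.3 IU/L.
#'
#' @param n_subjects Number of subjects (paired design; cohort simulation
#'   requires at least 2).
#' @param sampling_interval Minutes between samples (default 10). Must divide
#'   both window lengths.
#' @param t_end_endogenous End of the endogenous window / time of the GnRH
#'   bolus, minutes (default 240).
#' @param t_end_total End of sampling, minutes (default 360).
#' @param basal_level Non-pulsatile secretion floor, IU/L.
#' @param mean_ipi,ipi_sd Mean and SD of the interpulse interval (minutes) of
#'   the renewal pulse train; intervals are truncated below at
#'   `sampling_interval`.
#' @param pulse_amplitude_mean,pulse_amplitude_sd Mean and SD of the
#'   truncated-normal (positive) pulse amplitude, IU/L. A mean of 0 switches
#'   pulses off entirely.
#' @param elimination_halflife Hormone elimination half-life, minutes
#'   (default 45, within published LH kinetics).
#' @param gnrh_response_mean Target time-averaged hormone level over the
#'   stimulated window (240-360 min), IU/L.
#' @param diet_effect_mean Multiplier applied to the whole endogenous level
#'   (basal and pulses) at the post-diet visit. Default 3.8/4.3.
#' @param diet_effect_gnrh Multiplier on the stimulated response level at the
#'   post-diet visit. Default 7.2/10.1.
#' @param diet_effect_amplitude Extra multiplier on pulse amplitudes at the
#'   post-diet visit, on top of `diet_effect_mean` (default 1).
#' @param assay_cv Intra-assay coefficient of variation of the immunoassay
#'   (fraction; multiplicative lognormal noise). Default 0.034.
#' @param between_subject_cv CV of the lognormal per-subject level multiplier
#'   shared across visits and hormones (default 0.25).
#' @param hormone Hormone label for series produced from this configuration.
#' @param seed Master seed; per-subject and per-series substreams are derived
#'   from it deterministically.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [simulate_series()], [simulate_cohort()], [fsh_config()]
#' @examples
#' cfg <- cohort_config(n_subjects = 4)
#' cfg$mean_ipi
#' @export
cohort_config <- function(n_subjects = 18,
                          sampling_interval = 10,
                          t_end_endogenous = 240,
                          t_end_total = 360,
                          basal_level = 2.4,
                          mean_ipi = 83,
                          ipi_sd = 15,
                          pulse_amplitude_mean = 2.4,
                          pulse_amplitude_sd = 1.1,
                          elimination_halflife = 45,
                          gnrh_response_mean = 10.1,
                          diet_effect_mean = 3.8 / 4.3,
                          diet_effect_gnrh = 7.2 / 10.1,
                          diet_effect_amplitude = 1,
                          assay_cv = 0.034,
                          between_subject_cv = 0.25,
                          hormone = "LH",
                          seed = 19423L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    sampling_interval = as.numeric(sampling_interval),
    t_end_endogenous = as.numeric(t_end_endogenous),
    t_end_total = as.numeric(t_end_total),
    basal_level = as.numeric(basal_level),
    mean_ipi = as.numeric(mean_ipi),
    ipi_sd = as.numeric(ipi_sd),
    pulse_amplitude_mean = as.numeric(pulse_amplitude_mean),
    pulse_amplitude_sd = as.numeric(pulse_amplitude_sd),
    elimination_halflife = as.numeric(elimination_halflife),
    gnrh_response_mean = as.numeric(gnrh_response_mean),
    diet_effect_mean = as.numeric(diet_effect_mean),
    diet_effect_gnrh = as.numeric(diet_effect_gnrh),
    diet_effect_amplitude = as.numeric(diet_effect_amplitude),
    assay_cv = as.numeric(assay_cv),
    between_subject_cv = as.numeric(between_subject_cv),
    hormone = as.character(hormone),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("sampling_interval", "t_end_endogenous", "t_end_total",
              "basal_level", "mean_ipi", "ipi_sd", "pulse_amplitude_mean",
              "pulse_amplitude_sd", "elimination_halflife",
              "gnrh_response_mean", "diet_effect_mean", "diet_effect_gnrh",
              "diet_effect_amplitude", "assay_cv", "between_subject_cv")) {
    if (!num1(cfg[[f]])) {
      stop("configuration field '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (cfg$n_subjects < 1) {
    stop("n_subjects must be at least 1", call. = FALSE)
  }
  if (cfg$sampling_interval <= 0 || cfg$elimination_halflife <= 0 ||
      cfg$mean_ipi <= 0 || cfg$basal_level <= 0 ||
      cfg$gnrh_response_mean <= 0) {
    stop("sampling interval, half-life, interpulse interval, basal level ",
         "and GnRH response level must all be strictly positive",
         call. = FALSE)
  }
  if (cfg$ipi_sd < 0 || cfg$pulse_amplitude_mean < 0 ||
      cfg$pulse_amplitude_sd < 0) {
    stop("dispersion and amplitude parameters must be non-negative",
         call. = FALSE)
  }
  if (cfg$t_end_endogenous <= 0 || cfg$t_end_total <= cfg$t_end_endogenous) {
    stop("windows must satisfy 0 < t_end_endogenous < t_end_total",
         call. = FALSE)
  }
  divides <- function(a, b) abs(b / a - round(b / a)) < 1e-9
  if (!divides(cfg$sampling_interval, cfg$t_end_endogenous) ||
      !divides(cfg$sampling_interval, cfg$t_end_total - cfg$t_end_endogenous)) {
    stop("sampling_interval must divide both the endogenous and the ",
         "stimulated window length", call. = FALSE)
  }
  for (f in c("diet_effect_mean", "diet_effect_gnrh",
              "diet_effect_amplitude")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1.5) {
      stop("diet-effect multiplier '", f, "' must lie in (0, 1.5]",
           call. = FALSE)
    }
  }
  if (cfg$assay_cv < 0 || cfg$assay_cv >= 0.5) {
    stop("assay_cv must lie in [0, 0.5)", call. = FALSE)
  }
  if (cfg$between_subject_cv < 0) {
    stop("between_subject_cv must be non-negative", call. = FALSE)
  }
  if (!cfg$hormone %in% c("LH", "FSH")) {
    stop("hormone must be 'LH' or 'FSH'", call. = FALSE)
  }
  cfg
}

#' FSH companion configuration
#'
#' Derives the FSH generator settings from an LH configuration, keeping the
#' structural fields (cohort size, sampling design, between-subject
#' heterogeneity, seed) and replacing the hormone-specific calibration: FSH
#' is simulated pulse-free (no FSH pulses are detected in early-follicular
#' frequent sampling), with basal level 7.8 IU/L, stimulated level 9.5 IU/L,
#' diet multipliers 7.4/7.8 and 8.8/9.5, and intra-assay CV 5.0%.
#'
#' @param base A `cohort_config` (the LH configuration).
#' @return A `cohort_config` for FSH.
#' @export
fsh_config <- function(base = cohort_config()) {
  base <- validate_cohort_config(base)
  cohort_config(
    n_subjects = base$n_subjects,
    sampling_interval = base$sampling_interval,
    t_end_endogenous = base$t_end_endogenous,
    t_end_total = base$t_end_total,
    basal_level = 7.8,
    mean_ipi = base$mean_ipi,
    ipi_sd = base$ipi_sd,
    pulse_amplitude_mean = 0,
    pulse_amplitude_sd = 0,
    elimination_halflife = base$elimination_halflife,
    gnrh_response_mean = 9.5,
    diet_effect_mean = 7.4 / 7.8,
    diet_effect_gnrh = 8.8 / 9.5,
    diet_effect_amplitude = 1,
    assay_cv = 0.05,
    between_subject_cv = base$between_subject_cv,
    hormone = "FSH",
    seed = base$seed
  )
}

#' Read or write a cohort configuration as YAML
#'
#' The file is a flat key-value mapping mirroring the [cohort_config()]
#' fields; missing keys fall back to the defaults.
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  config <- validate_cohort_config(config)
  # full double precision so written configurations round-trip exactly
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$hormone, ", ", x$n_subjects, " subjects, q",
      x$sampling_interval, "-min sampling over 0-", x$t_end_total,
      " min (GnRH at ", x$t_end_endogenous, " min)\n", sep = "")
  cat(sprintf("  basal %.2f IU/L, pulses %.2f +/- %.2f IU/L every %.0f +/- %.0f min, t1/2 %.0f min\n",
              x$basal_level, x$pulse_amplitude_mean, x$pulse_amplitude_sd,
              x$mean_ipi, x$ipi_sd, x$elimination_halflife))
  cat(sprintf("  GnRH-stimulated level %.2f IU/L; diet effects: level %.3f, GnRH %.3f, amplitude %.2f\n",
              x$gnrh_response_mean, x$diet_effect_mean, x$diet_effect_gnrh,
              x$diet_effect_amplitude))
  cat(sprintf("  assay CV %.1f%%, between-subject CV %.1f%%, seed %d\n",
              100 * x$assay_cv, 100 * x$between_subject_cv, x$seed))
  invisible(x)
}
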