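#' Simulate one frequent-sampling hormone series
#'
#' Generates a single subject-visit trace under the pulsatile secretion
#' model: pulse onsets follow a renewal process with truncated-normal
#' interpulse intervals (floored at one sampling interval); each pulse adds
#' an instantaneous-rise, single-exponential-decay increment with
#' truncated-normal amplitude on top of the basal level; from `gnrh_time`
#' (`t_end_endogenous`) onward a stimulated component with a
#' rise-and-decay shape is superposed, scaled so the time-averaged level over
#' the stimulated window matches `gnrh_response_mean`; multiplicative
#' lognormal assay noise is applied last. At the post visit the whole
#' endogenous level is multiplied by `diet_effect_mean` (amplitudes
#' additionally by `diet_effect_amplitude`) and the stimulated level by
#' `diet_effect_gnrh`.
#'
#' The pulse train is started well before time zero (a burn-in of ten
#' half-lives plus two mean intervals) so that the sampled window sees a
#' stationary superposition of pulse tails.
#'
#' Setting `pulse_amplitude_mean = 0` switches pulses off; with
#' `assay_cv = 0` as well, the endogenous window is exactly flat at
#' `basal_level`.
#'
#' @param config A [cohort_config()].
#' @param visit `"pre"` or `"post"`.
#' @param subject_id Subject identifier stored in the series.
#' @param subject_effect Per-subject level multiplier (applied to the whole
#'   trace before noise); [simulate_cohort()] draws it once per subject.
#' @param seed Seed for this series' random stream (defaults to the
#'   configuration seed). The same `(config, seed)` pair yields a
#'   bit-identical series.
#' @return A [hormone_series()] carrying attributes `pulse_onsets` and
#'   `pulse_amplitudes` (the generated truth restricted to onsets in
#'   `[0, t_end_total]`) for detector validation.
#' @examples
#' cfg <- cohort_config(n_subjects = 2, seed = 7L)
#' s <- simulate_series(cfg, visit = "pre", subject_id = "S001")
#' s
#' @export
simulate_series <- function(config, visit = c("pre", "post"),
                            subject_id = "S001", subject_effect = 1,
                            seed = config$seed) {
  config <- validate_cohort_config(config)
  visit <- match.arg(visit)
  if (!is.numeric(subject_effect) || length(subject_effect) != 1 ||
      !is.finite(subject_effect) || subject_effect <= 0) {
    stop("subject_effect must be a single positive number", call. = FALSE)
  }
  with_seed(seed, {
    tt <- seq(0, config$t_end_total, by = config$sampling_interval)
    n_t <- length(tt)
    dt <- config$sampling_interval
    hl <- config$elimination_halflife
    lam <- log(2) / hl
    m_level <- if (visit == "post") config$diet_effect_mean else 1
    m_amp <- if (visit == "post") config$diet_effect_amplitude else 1
    m_gnrh <- if (visit == "post") config$diet_effect_gnrh else 1

    vals <- rep(config$basal_level * m_level, n_t)

    onsets <- numeric(0)
    amps_eff <- numeric(0)
    if (config$pulse_amplitude_mean > 0) {
      burn_in <- 10 * hl + 2 * config$mean_ipi
      span <- burn_in + config$t_end_total
      min_gap <- max(config$mean_ipi - 2 * config$ipi_sd, dt)
      n_guess <- ceiling(span / min_gap) + 10L
      first <- -burn_in + runif(1, 0, config$mean_ipi)
      gaps <- rnorm_trunc(n_guess, config$mean_ipi, config$ipi_sd, dt)
      on <- first + cumsum(c(0, gaps))
      while (on[length(on)] <= config$t_end_total) {
        gaps <- rnorm_trunc(n_guess, config$mean_ipi, config$ipi_sd, dt)
        on <- c(on, on[length(on)] + cumsum(gaps))
      }
      on <- on[on <= config$t_end_total]
      amps <- rnorm_trunc(length(on), config$pulse_amplitude_mean,
                          config$pulse_amplitude_sd, 0)
      a_eff <- amps * m_level * m_amp
      # pulses contribute negligibly beyond ~40 half-lives
      tail_span <- 40 * hl
      for (j in seq_along(on)) {
        i1 <- max(1L, as.integer(ceiling(on[j] / dt - 1e-9)) + 1L)
        i2 <- min(n_t, as.integer(floor((on[j] + tail_span) / dt)) + 1L)
        if (i1 <= i2) {
          idx <- i1:i2
          vals[idx] <- vals[idx] + a_eff[j] * exp(-lam * (tt[idx] - on[j]))
        }
      }
      keep <- on >= 0
      onsets <- on[keep]
      amps_eff <- a_eff[keep]
    }

    # GnRH-stimulated component: gamma-like rise-and-decay peaking ~30 min
    # after the bolus, scaled so the expected time-averaged total level over
    # the stimulated window hits the configured target.
    gt <- config$t_end_endogenous
    endo_mean_exp <- config$basal_level * m_level
    if (config$pulse_amplitude_mean > 0) {
      endo_mean_exp <- endo_mean_exp +
        trunc_norm_mean(config$pulse_amplitude_mean,
                        config$pulse_amplitude_sd, 0) *
        m_level * m_amp * (hl / log(2)) / config$mean_ipi
    }
    target <- config$gnrh_response_mean * m_gnrh
    tau <- 30
    L <- config$t_end_total - gt
    mean_shape <- exp(1) * tau * (1 - exp(-L / tau) * (1 + L / tau)) / L
    scale_stim <- max(0, target - endo_mean_exp) / mean_shape
    u <- tt - gt
    stim <- u >= 0
    vals[stim] <- vals[stim] +
      scale_stim * (u[stim] / tau) * exp(1 - u[stim] / tau)

    vals <- vals * subject_effect
    if (config$assay_cv > 0) {
      vals <- vals * rlnorm_cv(n_t, config$assay_cv)
    }

    out <- hormone_series(tt, vals, subject_id = subject_id, visit = visit,
                          hormone = config$hormone, gnrh_time = gt)
    attr(out, "pulse_onsets") <- onsets
    attr(out, "pulse_amplitudes") <- amps_eff
    out
  })
}

#' Simulate a paired crossover cohort
#'
#' Generates the full study design: for every subject, pre- and post-diet
#' series for each requested hormone (four series per subject by default).
#' A single lognormal level multiplier per subject (CV
#' `between_subject_cv`) is shared across visits and hormones, inducing the
#' positive within-subject pre/post correlation that paired testing exploits.
#' Per-subject and per-series random substreams are derived from the master
#' seed by counter, so enlarging the cohort never changes earlier subjects.
#'
#' @param config LH [cohort_config()]; also carries the cohort-level fields
#'   (`n_subjects`, `between_subject_cv`, `seed`).
#' @param fsh FSH configuration, by default [fsh_config()] derived from
#'   `config`.
#' @param hormones Which hormones to simulate, subset of `c("LH", "FSH")`.
#' @return A `hormone_cohort`: a list of [hormone_series()] objects.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 3, seed = 11L))
#' length(coh)  # 3 subjects x 2 visits x 2 hormones
#' @export
simulate_cohort <- function(config, fsh = fsh_config(config),
                            hormones = c("LH", "FSH")) {
  config <- validate_cohort_config(config)
  hormones <- match.arg(hormones, several.ok = TRUE)
  if (config$n_subjects < 2) {
    stop("simulate_cohort needs n_subjects >= 2: ",
         "paired pre/post testing is impossible with a single subject",
         call. = FALSE)
  }
  out <- vector("list", 0L)
  for (i in seq_len(config$n_subjects)) {
    eff <- with_seed(derive_seed(config$seed, 1L, i),
                     rlnorm_cv(1, config$between_subject_cv))
    sid <- sprintf("S%03d", i)
    for (h in hormones) {
      cfg_h <- if (h == "LH") config else fsh
      h_idx <- match(h, c("LH", "FSH"))
      for (v in c("pre", "post")) {
        v_idx <- match(v, c("pre", "post"))
        s <- simulate_series(
          cfg_h, visit = v, subject_id = sid, subject_effect = eff,
          seed = derive_seed(config$seed, 2L, i, h_idx, v_idx)
        )
        out[[length(out) + 1L]] <- s
      }
    }
  }
  attr(out, "config") <- config
  class(out) <- c("hormone_cohort", "list")
  out
}
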