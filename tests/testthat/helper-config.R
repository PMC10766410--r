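# Small, fast configurations used across tests.

# Noise-free, pulse-free: flat basal level.
flat_config <- function(basal = 5, n_subjects = 2, between_subject_cv = 0,
                        ...) {
  cohort_config(
    n_subjects = n_subjects, basal_level = basal, pulse_amplitude_mean = 0,
    pulse_amplitude_sd = 0, assay_cv = 0,
    between_subject_cv = between_subject_cv, ...
  )
}

# Deterministic well-separated pulses, no noise.
clean_pulse_config <- function(...) {
  cohort_config(
    n_subjects = 2, basal_level = 3, mean_ipi = 80, ipi_sd = 0,
    pulse_amplitude_mean = 3, pulse_amplitude_sd = 0,
    assay_cv = 0, between_subject_cv = 0, ...
  )
}
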