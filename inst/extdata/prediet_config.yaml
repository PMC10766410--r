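n_subjects: 200
sampling_interval: 10.0
t_end_endogenous: 240.0
t_end_total: 360.0
basal_level: 2.39999999999999991
mean_ipi: 83.0
ipi_sd: 15.0
pulse_amplitude_mean: 2.39999999999999991
pulse_amplitude_sd: 1.10000000000000009
elimination_halflife: 45.0
gnrh_response_mean: 10.09999999999999964
diet_effect_mean: 0.88372093023255816
diet_effect_gnrh: 0.71287128712871295
diet_effect_amplitude: 1.0
assay_cv: 0.034
between_subject_cv: 0.25
hormone: LH
seed: 424
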