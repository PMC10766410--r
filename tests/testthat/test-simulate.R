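test_that("noise-free, pulse-free series is exactly flat at basal level", {
  s <- simulate_series(flat_config(basal = 5), visit = "pre")
  endo <- s$times < 240
  expect_equal(s$values[endo], rep(5, sum(endo)))
  expect_equal(s$times, seq(0, 360, 10))
  expect_length(s$values, 37)
  # stimulated component only after the bolus
  expect_true(all(s$values[s$times > 240] >= 5))
})

test_that("identical config and seed give bit-identical series", {
  cfg <- cohort_config(n_subjects = 2, seed = 123L)
  a <- simulate_series(cfg, "pre", seed = 77L)
  b <- simulate_series(cfg, "pre", seed = 77L)
  expect_identical(a$values, b$values)
  expect_identical(attr(a, "pulse_onsets"), attr(b, "pulse_onsets"))
})

test_that("renewal process recovers the configured interpulse interval", {
  # one long series pooling ~10,000 inter-onset gaps
  cfg <- cohort_config(
    n_subjects = 2, mean_ipi = 80, ipi_sd = 12,
    t_end_endogenous = 800000, t_end_total = 800010,
    assay_cv = 0, between_subject_cv = 0, seed = 202L
  )
  s <- simulate_series(cfg, "pre")
  gaps <- diff(attr(s, "pulse_onsets"))
  expect_gt(length(gaps), 9000)
  expect_lt(abs(mean(gaps) - 80) / 80, 0.01)
})

test_that("simulated amplitudes match the configured distribution", {
  cfg <- cohort_config(
    n_subjects = 2, t_end_endogenous = 400000, t_end_total = 400010,
    assay_cv = 0, between_subject_cv = 0, seed = 303L
  )
  s <- simulate_series(cfg, "pre")
  amps <- attr(s, "pulse_amplitudes")
  expect_gt(length(amps), 4000)
  # truncated-normal(2.4, 1.1, >0) mean is ~2.44
  expect_lt(abs(mean(amps) - 2.44), 0.06)
  expect_true(all(amps > 0))
})

test_that("cohort bookkeeping: 4 series per subject, shared subject effect", {
  coh <- simulate_cohort(cohort_config(n_subjects = 18, seed = 9L))
  expect_length(coh, 72)
  tb <- series_tibble(coh)
  counts <- table(unique(tb[, c("subject_id", "visit", "hormone")])$subject_id)
  expect_true(all(counts == 4))
  expect_error(simulate_cohort(cohort_config(n_subjects = 1)), "paired")
})

test_that("no heterogeneity and no noise make all subjects identical", {
  coh <- simulate_cohort(flat_config(n_subjects = 3, seed = 4L))
  lh_pre <- Filter(function(s) s$hormone == "LH" && s$visit == "pre", coh)
  expect_length(lh_pre, 3)
  expect_identical(lh_pre[[1]]$values, lh_pre[[2]]$values)
  expect_identical(lh_pre[[2]]$values, lh_pre[[3]]$values)
})

test_that("between-subject CV is recovered from per-subject means", {
  cfg <- flat_config(n_subjects = 500, between_subject_cv = 0.3, seed = 11L)
  coh <- simulate_cohort(cfg, hormones = "LH")
  vs <- summarize_cohort(Filter(function(s) s$visit == "pre", coh))
  cv <- sd(vs$mean_endogenous) / mean(vs$mean_endogenous)
  expect_lt(abs(cv - 0.3) / 0.3, 0.15)
})

test_that("post/pre endogenous ratio converges to the diet effect", {
  cfg <- flat_config(n_subjects = 2, seed = 21L,
                     diet_effect_mean = 0.884, diet_effect_gnrh = 0.713)
  pre <- simulate_series(cfg, "pre")
  post <- simulate_series(cfg, "post")
  endo <- pre$times < 240
  expect_equal(mean(post$values[endo]) / mean(pre$values[endo]), 0.884,
               tolerance = 1e-12)
})

test_that("growing the cohort does not reshuffle earlier subjects", {
  small <- simulate_cohort(cohort_config(n_subjects = 3, seed = 31L))
  large <- simulate_cohort(cohort_config(n_subjects = 6, seed = 31L))
  expect_identical(small[[1]]$values, large[[1]]$values)
  expect_identical(small[[12]]$values, large[[12]]$values)
})

test_that("metabolite generator honors class ratios and reproducibility", {
  spec <- tibble::tibble(
    class = c("transient", "null"), n = c(40L, 5L),
    mid_ratio = c(2, 1), end_ratio = c(1, 1)
  )
  m1 <- simulate_metabolite_matrix(60, spec, seed = 8L)
  m2 <- simulate_metabolite_matrix(60, spec, seed = 8L)
  expect_identical(m1, m2)

  labels <- metabolite_classes(m1)
  trans <- labels$metabolite[labels$class == "transient"]
  ratios <- vapply(trans, function(met) {
    g <- function(tp) exp(mean(log(m1[[met]][m1$timepoint == tp])))
    g("on_diet") / g("pre")
  }, numeric(1))
  # geometric mid/baseline ratio centered on 2
  expect_lt(abs(mean(ratios) - 2), 0.15)
})

test_that("all-null metabolite matrices have time effects centered on zero", {
  spec <- tibble::tibble(class = "null", n = 60L, mid_ratio = 1,
                         end_ratio = 1)
  m <- simulate_metabolite_matrix(30, spec, seed = 14L)
  mets <- setdiff(names(m), c("subject", "timepoint"))
  eff <- vapply(mets, function(met) {
    mean(log(m[[met]][m$timepoint == "end"])) -
      mean(log(m[[met]][m$timepoint == "pre"]))
  }, numeric(1))
  expect_lt(abs(mean(eff)), 0.02)
})

test_that("metabolite generator validates its inputs", {
  bad <- tibble::tibble(class = "weird", n = 3L, mid_ratio = 1,
                        end_ratio = 1)
  expect_error(simulate_metabolite_matrix(10, bad, seed = 1L), "unknown")
  no_null <- tibble::tibble(class = "increasing", n = 3L, mid_ratio = 1.5,
                            end_ratio = 2)
  expect_error(simulate_metabolite_matrix(10, no_null, seed = 1L), "null")
  expect_error(
    simulate_metabolite_matrix(10, seed = 1L, n_coupled = 2L),
    "hormone_trajectories"
  )
})
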