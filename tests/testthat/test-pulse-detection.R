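series_q10 <- function(values, ...) {
  hormone_series(seq(0, by = 10, length.out = length(values)), values, ...)
}

test_that("hand-traced example: one 30% excursion", {
  s <- series_q10(c(5, 5, 6.5, 5, 5))
  cs <- detect_pulses(s, "single_point", threshold = 0.2)
  expect_equal(cs$n_pulses, 1)
  expect_equal(cs$pulses$nadir_value, 5)
  expect_equal(cs$pulses$nadir_time, 0)
  expect_equal(cs$pulses$peak_value, 6.5)
  expect_equal(cs$pulses$peak_time, 20)
  expect_equal(cs$pulses$amplitude, 1.5)
  expect_equal(cs$pulses$relative_rise, 0.3)
  expect_true(is.na(cs$mean_ipi))

  # under the two-point criterion the single qualifying sample is not enough
  cs2 <- detect_pulses(s, "two_point", threshold = 0.2)
  expect_equal(cs2$n_pulses, 0)
})

test_that("flat and sub-threshold series yield no pulses", {
  expect_equal(detect_pulses(series_q10(rep(4.3, 8)))$n_pulses, 0)
  # 18% rise stays below the 20% criterion
  expect_equal(detect_pulses(series_q10(c(5, 5.9, 5)))$n_pulses, 0)
  # a rise of exactly 20% qualifies ("at least 20%")
  expect_equal(detect_pulses(series_q10(c(5, 6, 5)))$n_pulses, 1)
})

test_that("two-point criterion confirms two consecutive qualifying samples", {
  s <- series_q10(c(5, 6.5, 6.2, 5, 5))
  cs <- detect_pulses(s, "two_point")
  expect_equal(cs$n_pulses, 1)
  expect_equal(cs$pulses$peak_value, 6.5)
})

test_that("pulse count is monotone in threshold and criterion strictness", {
  set.seed(42)
  for (rep in 1:25) {
    v <- 3 + cumsum(rnorm(24, 0, 0.8))
    v <- pmax(v, 0.5)
    s <- series_q10(v)
    counts <- vapply(c(0.1, 0.2, 0.3, 0.5), function(th) {
      detect_pulses(s, "single_point", threshold = th)$n_pulses
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_lte(detect_pulses(s, "two_point")$n_pulses,
               detect_pulses(s, "single_point")$n_pulses)
  }
})

test_that("detection is scale invariant", {
  set.seed(7)
  v <- 4 + abs(cumsum(rnorm(20, 0, 0.7)))
  a <- detect_pulses(series_q10(v))
  b <- detect_pulses(series_q10(10 * v))
  expect_equal(b$n_pulses, a$n_pulses)
  expect_equal(b$pulses$peak_time, a$pulses$peak_time)
  expect_equal(b$pulses$relative_rise, a$pulses$relative_rise)
  expect_equal(b$pulses$amplitude, 10 * a$pulses$amplitude)
})

test_that("pulses are ordered and non-overlapping", {
  set.seed(99)
  for (rep in 1:20) {
    v <- pmax(3 + cumsum(rnorm(25, 0, 1)), 0.3)
    cs <- detect_pulses(series_q10(v))
    if (cs$n_pulses >= 2) {
      expect_true(all(diff(cs$pulses$peak_time) > 0))
      expect_true(all(cs$pulses$nadir_time[-1] >=
                        cs$pulses$peak_time[-cs$n_pulses]))
    }
    expect_true(all(cs$pulses$peak_time > cs$pulses$nadir_time))
    expect_true(all(cs$pulses$relative_rise >= 0.2 - 1e-12))
  }
})

test_that("every well-separated noise-free pulse is found, none invented", {
  cfg <- clean_pulse_config(seed = 17L)
  for (seed in c(1L, 2L, 3L)) {
    s <- simulate_series(cfg, "pre", seed = seed)
    cs <- detect_pulses(s)
    onsets <- attr(s, "pulse_onsets")
    onsets <- onsets[onsets <= 240]  # endogenous detection window
    expect_equal(cs$n_pulses, length(onsets))
    # each detected peak is the first sample at or after its true onset
    expect_true(all(abs(cs$pulses$peak_time -
                          10 * ceiling(onsets / 10)) < 1e-9))
  }
})

test_that("detection refuses windows past the GnRH bolus", {
  s <- simulate_series(flat_config(), "pre")
  expect_error(detect_pulses(s, window_end = 300), "GnRH")
  expect_error(detect_pulses(series_q10(c(5, 6, 5, 5)), window_end = 10),
               "fewer than 3")
  expect_error(detect_pulses(series_q10(c(5, 6, 5)), threshold = 0),
               "positive")
})

test_that("a zero-valued running nadir triggers a warning, not a pulse", {
  s <- series_q10(c(0, 0, 1, 0, 0))
  expect_warning(cs <- detect_pulses(s), "nadir of 0")
  expect_equal(cs$n_pulses, 0)
})

test_that("pulsatility summaries aggregate subject means", {
  s1 <- series_q10(c(5, 5, 6.5, 5, 5, 7, 5))  # two pulses, peaks 20 and 50
  cs1 <- detect_pulses(s1)
  expect_equal(cs1$n_pulses, 2)
  expect_equal(cs1$mean_ipi, 30)

  # single pulse of amplitude 2: cohort mean amplitude equals it
  one <- detect_pulses(series_q10(c(4, 4, 6, 4, 4)))
  expect_equal(suppressMessages(
    summarize_pulsatility(list(one))
  )$mean_amplitude, 2)

  # two subjects with mean IPIs 30 and 50 -> cohort mean 40
  s2 <- series_q10(c(5, 7, 5, 5, 5, 5, 7, 5))  # peaks at 10 and 60
  cs2 <- detect_pulses(s2)
  cs2$subject_id <- "S002"
  expect_equal(cs2$mean_ipi, 50)
  summ <- summarize_pulsatility(list(cs1, cs2))
  expect_equal(summ$mean_ipi, mean(c(30, 50)))
  expect_equal(summ$n_subjects, 2)
  expect_equal(summ$n_excluded_ipi, 0)
})

test_that("subjects without two pulses are excluded from the IPI summary", {
  a <- detect_pulses(series_q10(c(5, 5, 6.5, 5, 5, 7, 5)))
  b <- detect_pulses(series_q10(rep(5, 7)))
  b$subject_id <- "S002"
  expect_message(summ <- summarize_pulsatility(list(a, b)), "excluded")
  expect_equal(summ$n_ipi, 1)
  expect_equal(summ$n_excluded_ipi, 1)
  expect_equal(summ$mean_ipi, 30)
})
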