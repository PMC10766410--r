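#' Paired pre/post comparison with a normality-gated test switch
#'
#' Implements the study's testing scheme: values are transformed
#' logarithmically and compared with a paired t test when the paired
#' log-differences are compatible with normality (Shapiro-Wilk at
#' `alpha_normality`); otherwise a two-sided Wilcoxon signed-rank test on
#' the raw paired differences is used (exact distribution for n <= 25 when
#' there are no ties; zero differences are dropped).
#'
#' Centers are reported as geometric means (the natural summary for
#' log-analyzed data) alongside arithmetic means; the percent change is
#' computed from the geometric means when all values are positive,
#' otherwise from the arithmetic means.
#'
#' Degenerate inputs are resolved explicitly: identical pre and post values
#' give a percent change of 0 and p = 1 with a warning (no signed ranks
#' remain); constant non-zero log-differences (an exact fold change) have
#' zero variance, so the t statistic is unbounded and p is reported at the
#' smallest positive double.
#'
#' @param pre,post Subject-aligned positive values (equal length, n >= 2).
#'   Pairs with a missing value are dropped with a message.
#' @param metric Label stored in the result row.
#' @param force_test Optional override: `"paired_t_log"` or `"wilcoxon"`
#'   skips the normality gate.
#' @param alpha_normality Significance level of the Shapiro-Wilk gate
#'   (default 0.05).
#' @return A one-row tibble: `metric`, `n_pairs`, `pre_mean`, `post_mean`
#'   (arithmetic), `pre_sd`, `post_sd`, `pre_gm`, `post_gm` (geometric),
#'   `percent_change`, `test_used`, `normality_p`, `p_value`.
#' @examples
#' paired_compare(c(4.1, 4.6, 3.9, 5.0), c(3.6, 4.1, 3.2, 4.6))
#' @export
paired_compare <- function(pre, post, metric = "metric", force_test = NULL,
                           alpha_normality = 0.05) {
  if (length(pre) != length(post)) {
    stop("pre and post must be subject-aligned vectors of equal length",
         call. = FALSE)
  }
  ok <- is.finite(pre) & is.finite(post)
  if (sum(!ok) > 0) {
    message(sum(!ok), " pair(s) with missing values dropped")
  }
  pre <- pre[ok]
  post <- post[ok]
  n <- length(pre)
  if (n < 2) {
    stop("paired comparison needs at least 2 complete pairs", call. = FALSE)
  }
  if (!is.null(force_test)) {
    force_test <- match.arg(force_test, c("paired_t_log", "wilcoxon"))
  }

  positive <- all(pre > 0) && all(post > 0)
  gm <- function(x) exp(mean(log(x)))
  pre_gm <- if (positive) gm(pre) else NA_real_
  post_gm <- if (positive) gm(post) else NA_real_
  pc <- if (positive) {
    percent_change(pre_gm, post_gm)
  } else {
    percent_change(mean(pre), mean(post))
  }

  test_used <- NA_character_
  normality_p <- NA_real_
  p_value <- NA_real_

  want_log <- is.null(force_test) || force_test == "paired_t_log"
  if (want_log && !positive) {
    warning("non-positive values: log-scale paired t test unavailable, ",
            "falling back to the Wilcoxon signed-rank test", call. = FALSE)
    force_test <- "wilcoxon"
  }

  d_raw <- post - pre
  if (all(d_raw == 0)) {
    warning("all paired differences are zero: the signed-rank test is ",
            "degenerate; p reported as 1", call. = FALSE)
    test_used <- "wilcoxon"
    p_value <- 1
  } else {
    dlog <- if (positive) log(post) - log(pre) else NULL
    # an exact fold change leaves (numerically) no variance in the
    # log-differences: the t statistic is unbounded
    exact_fold <- !is.null(dlog) &&
      sd(dlog) <= 1e-10 * max(abs(mean(dlog)), .Machine$double.xmin)
    if (is.null(force_test)) {
      if (exact_fold) {
        test_used <- "paired_t_log"
        p_value <- .Machine$double.xmin
      } else if (n < 3) {
        # normality cannot be assessed with 2 pairs; default to the log path
        test_used <- "paired_t_log"
      } else {
        normality_p <- shapiro.test(dlog)$p.value
        test_used <- if (normality_p >= alpha_normality) "paired_t_log"
                     else "wilcoxon"
      }
    } else {
      test_used <- force_test
      if (test_used == "paired_t_log" && exact_fold) {
        p_value <- .Machine$double.xmin
      }
    }
    if (is.na(p_value)) {
      if (test_used == "paired_t_log") {
        p_value <- t.test(dlog)$p.value
      } else {
        p_value <- wilcoxon_signed_rank(d_raw)
      }
    }
  }

  tibble::tibble(
    metric = metric, n_pairs = n,
    pre_mean = mean(pre), post_mean = mean(post),
    pre_sd = sd(pre), post_sd = sd(post),
    pre_gm = pre_gm, post_gm = post_gm,
    percent_change = pc,
    test_used = test_used, normality_p = normality_p, p_value = p_value
  )
}

# Two-sided Wilcoxon signed-rank p-value on paired differences, zeros
# dropped, exact for n <= 25 without ties in |d|.
wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("no non-zero differences remain after dropping zeros; ",
            "p reported as 1", call. = FALSE)
    return(1)
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  suppressWarnings(
    wilcox.test(d, exact = exact, correct = !exact)$p.value
  )
}
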