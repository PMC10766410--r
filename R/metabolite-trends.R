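#' Repeated-measures ANOVA per metabolite
#'
#' One-way within-subject ANOVA across the three study timepoints on
#' log-transformed abundances (intensities are multiplicative), computed by
#' the closed-form balanced decomposition (time, subject and residual sums
#' of squares). A Greenhouse-Geisser sphericity correction is applied to the
#' degrees of freedom whenever the timepoint covariance is estimable;
#' Benjamini-Hochberg q-values are computed across metabolites. Each
#' metabolite also receives a direction class from the ordering of its
#' timepoint means: `increasing`, `decreasing`, `transient` (the on-diet
#' timepoint is the extreme) or `flat`.
#'
#' Metabolites with fewer than 3 complete subject trajectories are skipped
#' with a message.
#'
#' @param mat A `metabolite_matrix` (or any tibble with columns `subject`,
#'   `timepoint` in `pre`, `on_diet`, `end`, plus one column per
#'   metabolite).
#' @param log_transform Log the abundances before testing (default `TRUE`).
#' @param gg_correct Apply the Greenhouse-Geisser correction (default
#'   `TRUE`).
#' @return A tibble with one row per tested metabolite: `metabolite`, `n`,
#'   `F`, `df1`, `df2`, `gg_epsilon`, `p_value`, `fdr_q`, `direction`.
#' @export
rm_anova_per_metabolite <- function(mat, log_transform = TRUE,
                                    gg_correct = TRUE) {
  mat <- tibble::as_tibble(mat)
  if (!all(c("subject", "timepoint") %in% names(mat))) {
    stop("matrix must have 'subject' and 'timepoint' columns", call. = FALSE)
  }
  tps <- c("pre", "on_diet", "end")
  if (!setequal(unique(mat$timepoint), tps)) {
    stop("timepoints must be exactly: ", paste(tps, collapse = ", "),
         call. = FALSE)
  }
  mets <- setdiff(names(mat), c("subject", "timepoint"))
  if (!length(mets)) {
    stop("no metabolite columns found", call. = FALSE)
  }

  rows <- list()
  skipped <- character(0)
  for (m in mets) {
    y <- to_subject_by_timepoint(mat, m, tps)
    y <- y[stats::complete.cases(y), , drop = FALSE]
    if (nrow(y) < 3) {
      skipped <- c(skipped, m)
      next
    }
    if (log_transform) {
      if (any(y <= 0)) {
        stop("non-positive abundance for '", m,
             "': cannot log-transform", call. = FALSE)
      }
      y <- log(y)
    }
    fit <- rm_anova_fit(y, gg_correct = gg_correct)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metabolite = m, n = nrow(y), F = fit$F, df1 = fit$df1, df2 = fit$df2,
      gg_epsilon = fit$epsilon, p_value = fit$p,
      direction = classify_direction(colMeans(y))
    )
  }
  if (length(skipped)) {
    message(length(skipped), " metabolite(s) skipped (<3 complete ",
            "trajectories): ", paste(skipped, collapse = ", "))
  }
  if (!length(rows)) {
    stop("no metabolite could be tested", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out$fdr_q <- p.adjust(out$p_value, method = "BH")
  out[, c("metabolite", "n", "F", "df1", "df2", "gg_epsilon", "p_value",
          "fdr_q", "direction")]
}

# Reshape one metabolite column to a subjects x timepoints matrix.
to_subject_by_timepoint <- function(mat, column, tps) {
  wide <- mat |>
    dplyr::select(dplyr::all_of(c("subject", "timepoint", column))) |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = dplyr::all_of(column))
  as.matrix(wide[, tps])
}

# Balanced one-way within-subject ANOVA on an n x t matrix, with the
# Greenhouse-Geisser epsilon from the double-centered timepoint covariance.
rm_anova_fit <- function(y, gg_correct = TRUE) {
  n <- nrow(y)
  t <- ncol(y)
  grand <- mean(y)
  ss_time <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- t * sum((rowMeans(y) - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_time - ss_subj
  df1 <- t - 1
  df2 <- (t - 1) * (n - 1)

  eps <- 1
  if (gg_correct && t > 2 && n >= 3) {
    S <- stats::cov(y)
    Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    denom <- (t - 1) * sum(Sc^2)
    if (is.finite(denom) && denom > 0) {
      eps <- sum(diag(Sc))^2 / denom
      eps <- min(1, max(1 / (t - 1), eps))
    }
  }

  scale_tol <- max(ss_total, 1e-300)
  if (ss_time / scale_tol < 1e-12 || ss_time == 0) {
    return(list(F = 0, df1 = df1, df2 = df2, epsilon = eps, p = 1))
  }
  if (ss_err / scale_tol < 1e-12) {
    return(list(F = Inf, df1 = df1, df2 = df2, epsilon = eps, p = 0))
  }
  f <- (ss_time / df1) / (ss_err / df2)
  p <- pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, epsilon = eps, p = p)
}

# Direction class from the ordering of the three timepoint means: the
# on-diet timepoint being the extreme marks a transient excursion, otherwise
# the end-vs-baseline sign decides.
classify_direction <- function(m) {
  if (max(m) - min(m) < 1e-10) return("flat")
  if (m[2] > m[1] && m[2] > m[3]) return("transient")
  if (m[2] < m[1] && m[2] < m[3]) return("transient")
  if (m[3] > m[1]) "increasing"
  else if (m[3] < m[1]) "decreasing"
  else "transient"
}

#' Rank metabolites for downstream clustering
#'
#' Orders trend results by ascending p-value, breaking ties by descending
#' |F| and then by metabolite name, and returns the top `k` (the usual
#' "top significant features" selection ahead of hierarchical clustering).
#'
#' @param results Tibble from [rm_anova_per_metabolite()].
#' @param k Number of features to keep (at most the number tested).
#' @return The top `k` rows in rank order.
#' @export
select_top_features <- function(results, k) {
  results <- tibble::as_tibble(results)
  if (k > nrow(results)) {
    stop("k must not exceed the number of tested metabolites", call. = FALSE)
  }
  ranked <- results |>
    dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$F)),
                   .data$metabolite)
  ranked[seq_len(k), ]
}

#' Spearman correlation of metabolites with a hormone trajectory
#'
#' Correlates each metabolite with per-subject hormone values over the three
#' study timepoints. The default pools all (subject, timepoint) pairs into
#' one Spearman correlation per metabolite (trajectory association); the
#' `per_subject` mode instead computes one rho per subject and averages.
#' Two-sided p-values use the exact null distribution for small pooled n
#' without ties and the asymptotic approximation otherwise. Constant inputs
#' have no defined rank correlation and are reported as missing.
#'
#' @param mat A `metabolite_matrix` (see [rm_anova_per_metabolite()]).
#' @param hormone_trajectories Tibble with columns `subject`, `timepoint`,
#'   `value`, or an `n_subjects x 3` matrix in timepoint order
#'   `pre`, `on_diet`, `end` with subjects in the matrix's row order.
#' @param mode `"pooled"` (default) or `"per_subject"`.
#' @return A tibble: `metabolite`, `n`, `spearman_rho`, `spearman_p`
#'   (`spearman_p` is `NA` in `per_subject` mode).
#' @export
correlate_with_hormone <- function(mat, hormone_trajectories,
                                   mode = c("pooled", "per_subject")) {
  mode <- match.arg(mode)
  mat <- tibble::as_tibble(mat)
  tps <- c("pre", "on_diet", "end")
  subjects <- unique(mat$subject)
  if (is.matrix(hormone_trajectories) ||
      (is.numeric(hormone_trajectories) && !is.data.frame(hormone_trajectories))) {
    hm <- as.matrix(hormone_trajectories)
    if (!all(dim(hm) == c(length(subjects), 3))) {
      stop("hormone matrix must be n_subjects x 3 (pre, on_diet, end)",
           call. = FALSE)
    }
    hormone_trajectories <- tibble::tibble(
      subject = rep(subjects, times = 3),
      timepoint = rep(tps, each = length(subjects)),
      value = as.vector(hm)
    )
  }
  ht <- tibble::as_tibble(hormone_trajectories)
  if (!all(c("subject", "timepoint", "value") %in% names(ht))) {
    stop("hormone_trajectories needs columns subject, timepoint, value",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(mat, ht, by = c("subject", "timepoint"))
  if (nrow(joined) != nrow(mat)) {
    stop("hormone trajectories do not align with the metabolite matrix ",
         "(subject/timepoint mismatch)", call. = FALSE)
  }
  mets <- setdiff(names(mat), c("subject", "timepoint"))

  rows <- lapply(mets, function(m) {
    x <- joined[[m]]
    y <- joined$value
    if (mode == "pooled") {
      if (sd(x) == 0 || sd(y) == 0) {
        return(tibble::tibble(metabolite = m, n = length(x),
                              spearman_rho = NA_real_,
                              spearman_p = NA_real_))
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
      tibble::tibble(metabolite = m, n = length(x),
                     spearman_rho = unname(ct$estimate),
                     spearman_p = ct$p.value)
    } else {
      rhos <- vapply(split(seq_len(nrow(joined)), joined$subject),
                     function(idx) {
                       xs <- x[idx]
                       ys <- y[idx]
                       if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
                       suppressWarnings(
                         stats::cor(xs, ys, method = "spearman")
                       )
                     }, numeric(1))
      tibble::tibble(metabolite = m, n = sum(!is.na(rhos)),
                     spearman_rho = mean(rhos, na.rm = TRUE),
                     spearman_p = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}
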