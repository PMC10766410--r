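#' Default metabolite class specification
#'
#' Trend classes emulating the three longitudinal patterns seen in diet
#' metabolomics: progressive depletion (amino-acid-like), a transient
#' on-diet increase (acyl-carnitine-like), a progressive increase (free
#' fatty-acid-like), plus null metabolites with no time effect (needed for
#' false-discovery-rate calibration).
#'
#' @return A tibble with columns `class`, `n`, `mid_ratio`, `end_ratio`:
#'   the number of metabolites per class and the geometric-mean abundance
#'   ratios of the on-diet and end-of-diet timepoints to baseline.
#' @export
default_class_spec <- function() {
  tibble::tibble(
    class = c("decreasing", "transient", "increasing", "null"),
    n = c(8L, 6L, 10L, 16L),
    mid_ratio = c(0.75, 2, 1.5, 1),
    end_ratio = c(0.55, 1, 2, 1)
  )
}

#' Simulate a three-timepoint metabolite matrix
#'
#' Lognormal abundances for `n_subjects` subjects at the three study
#' timepoints (`pre`, `on_diet`, `end`), around class-specific timepoint
#' geometric means: per metabolite a lognormal baseline, per
#' subject-metabolite a lognormal random level (CV `subject_cv`, shared
#' across timepoints, giving the within-subject correlation repeated-measures
#' testing relies on), class trend ratios from `class_spec`, and lognormal
#' residual noise (CV `residual_cv`).
#'
#' Optionally, `n_coupled` additional metabolites are generated with a
#' monotone coupling to a supplied per-subject hormone trajectory: their
#' log-abundance includes `coupling` times the standardized hormone value,
#' so Spearman correlation against the hormone is positive by construction.
#'
#' @param n_subjects Number of subjects.
#' @param class_spec Tibble like [default_class_spec()]; classes must be
#'   drawn from `decreasing`, `transient`, `increasing`, `null`, and at
#'   least one null metabolite must be present.
#' @param seed Integer seed; identical arguments give identical matrices.
#' @param hormone_trajectories Optional `n_subjects x 3` matrix of hormone
#'   values (one row per subject, columns pre/on-diet/end); required when
#'   `n_coupled > 0`.
#' @param n_coupled Number of hormone-coupled metabolites to append
#'   (class label `"coupled"`).
#' @param coupling Coupling slope on the log scale per SD of hormone.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline abundance
#'   parameters (arbitrary intensity units).
#' @param subject_cv CV of the subject-by-metabolite random level.
#' @param residual_cv CV of the residual noise.
#' @return A `metabolite_matrix`: a tibble with columns `subject`,
#'   `timepoint` and one column per metabolite, with a `class_labels`
#'   attribute (tibble `metabolite`, `class`).
#' @examples
#' m <- simulate_metabolite_matrix(6, seed = 1L)
#' dim(m)
#' @export
simulate_metabolite_matrix <- function(n_subjects,
                                       class_spec = default_class_spec(),
                                       seed = 1L,
                                       hormone_trajectories = NULL,
                                       n_coupled = 0L,
                                       coupling = 0.8,
                                       baseline_meanlog = log(500),
                                       baseline_sdlog = 1,
                                       subject_cv = 0.3,
                                       residual_cv = 0.2) {
  if (n_subjects < 2) {
    stop("n_subjects must be at least 2", call. = FALSE)
  }
  class_spec <- tibble::as_tibble(class_spec)
  stopifnot(all(c("class", "n", "mid_ratio", "end_ratio") %in%
                  names(class_spec)))
  known <- c("decreasing", "transient", "increasing", "null")
  bad <- setdiff(class_spec$class, known)
  if (length(bad)) {
    stop("unknown metabolite class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (sum(class_spec$n[class_spec$class == "null"]) < 1) {
    stop("class_spec must include at least one null metabolite",
         call. = FALSE)
  }
  n_coupled <- as.integer(n_coupled)
  if (n_coupled > 0) {
    if (is.null(hormone_trajectories)) {
      stop("hormone_trajectories is required when n_coupled > 0",
           call. = FALSE)
    }
    hormone_trajectories <- as.matrix(hormone_trajectories)
    if (!all(dim(hormone_trajectories) == c(n_subjects, 3))) {
      stop("hormone_trajectories must be an n_subjects x 3 matrix",
           call. = FALSE)
    }
  }

  timepoints <- c("pre", "on_diet", "end")
  specs <- tibble::tibble(
    metabolite = character(0), class = character(0),
    mid_ratio = numeric(0), end_ratio = numeric(0)
  )
  for (r in seq_len(nrow(class_spec))) {
    nr <- class_spec$n[r]
    if (nr < 1) next
    specs <- dplyr::bind_rows(specs, tibble::tibble(
      metabolite = sprintf("%s_%02d", substr(class_spec$class[r], 1, 4),
                           seq_len(nr)),
      class = class_spec$class[r],
      mid_ratio = class_spec$mid_ratio[r],
      end_ratio = class_spec$end_ratio[r]
    ))
  }
  if (n_coupled > 0) {
    specs <- dplyr::bind_rows(specs, tibble::tibble(
      metabolite = sprintf("coup_%02d", seq_len(n_coupled)),
      class = "coupled", mid_ratio = 1, end_ratio = 1
    ))
  }

  sd_subj <- sqrt(log(1 + subject_cv^2))
  sd_res <- sqrt(log(1 + residual_cv^2))
  hz <- NULL
  if (n_coupled > 0) {
    hv <- as.vector(hormone_trajectories)  # subject-major per timepoint
    hz <- (hormone_trajectories - mean(hv)) / stats::sd(hv)
  }

  out <- tibble::tibble(
    subject = rep(sprintf("S%03d", seq_len(n_subjects)), each = 3),
    timepoint = rep(timepoints, n_subjects)
  )
  with_seed(seed, {
    for (m in seq_len(nrow(specs))) {
      base_log <- rnorm(1, baseline_meanlog, baseline_sdlog)
      subj_log <- if (sd_subj > 0) {
        rnorm(n_subjects, -sd_subj^2 / 2, sd_subj)
      } else {
        rep(0, n_subjects)
      }
      trend_log <- log(c(1, specs$mid_ratio[m], specs$end_ratio[m]))
      # n_subjects x 3 on the log scale
      lg <- outer(base_log + subj_log, trend_log, `+`)
      if (specs$class[m] == "coupled") {
        lg <- lg + coupling * hz
      }
      if (sd_res > 0) {
        lg <- lg + matrix(rnorm(n_subjects * 3, -sd_res^2 / 2, sd_res),
                          n_subjects, 3)
      }
      # rows of `out` are subject-major: transpose to (timepoint within
      # subject) order
      out[[specs$metabolite[m]]] <- as.vector(t(exp(lg)))
    }
  })
  attr(out, "class_labels") <- specs[, c("metabolite", "class")]
  class(out) <- c("metabolite_matrix", class(out))
  out
}

#' Class labels of a metabolite matrix
#'
#' @param x A `metabolite_matrix`.
#' @return Tibble with columns `metabolite`, `class`, or `NULL` when the
#'   matrix carries no labels (e.g. read from a plain CSV).
#' @export
metabolite_classes <- function(x) {
  attr(x, "class_labels")
}
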