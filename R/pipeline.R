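#' Run the full analysis pipeline
#'
#' Executes the stages in protocol order and writes every intermediate
#' table: simulate (or load) the paired frequent-sampling cohort, detect LH
#' pulses over the endogenous window, compute per-visit response metrics,
#' build the paired pre/post comparison report, run the longitudinal
#' metabolomics stage (simulated three-timepoint matrix, repeated-measures
#' ANOVA with BH-FDR, top-feature ranking, Spearman correlation against the
#' per-subject LH trajectory), and record a run manifest with the
#' configuration snapshot, seed and file digests so any run can be
#' reproduced exactly.
#'
#' @param config A [cohort_config()] or the path to a YAML configuration.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the configuration seed.
#' @param series_csv Optional path to an external long-format series CSV;
#'   when supplied, simulation is skipped and the same downstream outputs
#'   are produced from the file.
#' @param n_coupled Number of hormone-coupled metabolites in the simulated
#'   metabolite matrix.
#' @param class_spec Metabolite class specification, see
#'   [default_class_spec()].
#' @param criterion,threshold Pulse-detection settings passed to
#'   [detect_pulses()].
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = cohort_config(), outdir, seed = NULL,
                         series_csv = NULL, n_coupled = 5L,
                         class_spec = default_class_spec(),
                         criterion = "single_point", threshold = 0.2) {
  if (is.character(config)) config <- read_cohort_config(config)
  config <- validate_cohort_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (is.null(series_csv)) {
      simulate_cohort(config)
    } else {
      read_series_csv(series_csv, gnrh_time = config$t_end_endogenous)
    }
  })
  write_series_csv(cohort, file.path(outdir, "series.csv"))

  callsets <- stage("detect", {
    lh <- Filter(function(s) s$hormone == "LH", cohort)
    if (!length(lh)) stop("no LH series available for pulse detection")
    lapply(lh, detect_pulses, criterion = criterion, threshold = threshold)
  })
  pulse_rows <- dplyr::bind_rows(lapply(callsets, function(cs) {
    if (!nrow(cs$pulses)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(subject_id = cs$subject_id, visit = cs$visit,
                     hormone = cs$hormone),
      cs$pulses
    )
  }))
  write.csv(pulse_rows, file.path(outdir, "pulses.csv"), row.names = FALSE)
  pulse_stats <- pulsatility_by_subject(callsets)
  write.csv(pulse_stats, file.path(outdir, "pulses_by_subject.csv"),
            row.names = FALSE)
  write.csv(suppressMessages(summarize_pulsatility(callsets)),
            file.path(outdir, "pulse_summary.csv"), row.names = FALSE)

  visit_summaries <- stage("summarize", summarize_cohort(cohort))
  write.csv(visit_summaries, file.path(outdir, "visit_summary.csv"),
            row.names = FALSE)

  report <- stage("report",
                  suppressMessages(build_report(visit_summaries,
                                                pulse_stats)))
  write.csv(report, file.path(outdir, "report.csv"), row.names = FALSE)
  writeLines(format_report(report), file.path(outdir, "report.txt"))

  stage("omics", {
    lh_mean <- visit_summaries |>
      dplyr::filter(.data$hormone == "LH") |>
      dplyr::select(dplyr::all_of(c("subject_id", "visit",
                                    "mean_endogenous"))) |>
      tidyr::pivot_wider(names_from = "visit",
                         values_from = "mean_endogenous")
    if (!all(c("pre", "post") %in% names(lh_mean))) {
      stop("both visits are needed to build hormone trajectories")
    }
    # on-diet hormone level proxied by the pre/post midpoint
    traj <- cbind(lh_mean$pre, (lh_mean$pre + lh_mean$post) / 2,
                  lh_mean$post)
    mat <- simulate_metabolite_matrix(
      n_subjects = nrow(traj), class_spec = class_spec,
      seed = derive_seed(config$seed, 3L),
      hormone_trajectories = traj, n_coupled = n_coupled
    )
    utils::write.csv(as.data.frame(mat),
                     file.path(outdir, "metabolite_matrix.csv"),
                     row.names = FALSE)
    write.csv(metabolite_classes(mat),
              file.path(outdir, "metabolite_classes.csv"),
              row.names = FALSE)
    trends <- suppressMessages(rm_anova_per_metabolite(mat))
    cors <- correlate_with_hormone(mat, traj)
    trends <- dplyr::left_join(trends, cors, by = "metabolite")
    write.csv(trends, file.path(outdir, "trend_results.csv"),
              row.names = FALSE)
    top <- select_top_features(trends, min(50L, nrow(trends)))
    write.csv(top, file.path(outdir, "top_features.csv"), row.names = FALSE)
  })

  files <- c("series.csv", "pulses.csv", "pulses_by_subject.csv",
             "pulse_summary.csv", "visit_summary.csv", "report.csv",
             "report.txt", "metabolite_matrix.csv",
             "metabolite_classes.csv", "trend_results.csv",
             "top_features.csv")
  paths <- file.path(outdir, files)
  manifest <- list(
    package = "reprometab",
    version = as.character(utils::packageVersion("reprometab")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = unclass(config),
    files = data.frame(name = files,
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
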