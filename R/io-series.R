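#' Read and write hormone series as long-format CSV
#'
#' The interchange format is a long CSV with columns `subject_id`, `visit`,
#' `hormone`, `time_min`, `value_iu_l` (times in minutes from the start of
#' sampling, concentrations in IU/L). `read_series_csv()` validates the
#' schema, rejects duplicated `(subject, visit, hormone, time)` rows (naming
#' the offending row), enforces a uniform sampling grid per series, and
#' groups rows into [hormone_series()] objects.
#'
#' @param path CSV file path.
#' @param gnrh_time GnRH bolus time attached to every series (minutes);
#'   `NA` for series without a stimulation phase.
#' @return A `hormone_cohort` (list of `hormone_series`).
#' @export
read_series_csv <- function(path, gnrh_time = 240) {
  if (!file.exists(path)) {
    stop("series file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "hormone", "time_min", "value_iu_l")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$time_min) || !is.numeric(df$value_iu_l)) {
    stop("time_min and value_iu_l must be numeric", call. = FALSE)
  }
  if (any(!is.finite(df$value_iu_l)) || any(df$value_iu_l < 0)) {
    bad <- which(!is.finite(df$value_iu_l) | df$value_iu_l < 0)[1]
    stop("non-finite or negative value_iu_l at data row ", bad,
         call. = FALSE)
  }
  key <- paste(df$subject_id, df$visit, df$hormone, df$time_min, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicated (subject, visit, hormone, time) at data row ", dup[1],
         " of ", path, call. = FALSE)
  }
  if (is.na(gnrh_time)) gnrh_time <- NULL

  groups <- split(seq_len(nrow(df)),
                  paste(df$subject_id, df$visit, df$hormone, sep = "\r"))
  out <- lapply(unname(groups), function(idx) {
    idx <- idx[order(df$time_min[idx])]
    hormone_series(
      times = df$time_min[idx], values = df$value_iu_l[idx],
      subject_id = df$subject_id[idx[1]], visit = df$visit[idx[1]],
      hormone = df$hormone[idx[1]], gnrh_time = gnrh_time
    )
  })
  # stable, reader-friendly order
  ord <- order(vapply(out, function(s) s$subject_id, character(1)),
               vapply(out, function(s) s$hormone, character(1)),
               vapply(out, function(s) s$visit, character(1)))
  out <- out[ord]
  class(out) <- c("hormone_cohort", "list")
  out
}

#' @rdname read_series_csv
#' @param x A `hormone_series`, list of them, or a long tibble with the
#'   interchange columns.
#' @return `write_series_csv()` returns `path` invisibly.
#' @export
write_series_csv <- function(x, path) {
  tb <- if (is.data.frame(x)) tibble::as_tibble(x) else series_tibble(x)
  need <- c("subject_id", "visit", "hormone", "time_min", "value_iu_l")
  stopifnot(all(need %in% names(tb)))
  write.csv(tb[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
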