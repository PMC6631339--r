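# Evaluation: score session logs by the fixed windowing rule and compare
# algorithms across sessions.

#' Scoring window definition
#'
#' The default window discards the first 60 s of a log (network training /
#' subject adaptation) and the last 10 s (end-of-session anticipation), then
#' keeps the centred 400 rows of what remains -- 40 s at the 10 Hz cadence.
#'
#' @param skip_head_s Seconds dropped from the start of the session (default 60).
#' @param skip_tail_s Seconds dropped from the end (default 10).
#' @param n_rows Number of scored rows (default 400).
#' @return An `eval_window`.
#' @export
eval_window <- function(skip_head_s = 60, skip_tail_s = 10, n_rows = 400L) {
  if (n_rows < 1L) eegbci_stop("eegbci_bad_argument", "n_rows must be positive")
  structure(list(skip_head_s = skip_head_s, skip_tail_s = skip_tail_s,
                 n_rows = as.integer(n_rows)),
            class = "eval_window")
}

#' Select the scoring rows of a session log
#'
#' Drops rows with `time < skip_head_s` and rows with
#' `time >= duration - skip_tail_s`, then returns the centred `n_rows` of the
#' remainder (when the surplus is odd, the extra dropped row comes off the
#' head, so head and tail surplus differ by at most one row).
#'
#' @param log A `session_log`.
#' @param window An [eval_window()].
#' @return The selected rows (a `session_log` subset), contiguous in time.
#' @export
select_scoring_rows <- function(log, window = eval_window()) {
  stopifnot(inherits(log, "session_log"))
  duration <- attr(log, "duration_s")
  if (is.null(duration) || is.na(duration)) {
    duration <- max(log$time_s) + 1 / (attr(log, "log_rate_hz") %||% 10)
  }
  keep <- log$time_s >= window$skip_head_s &
    log$time_s < duration - window$skip_tail_s
  rows <- log[keep, , drop = FALSE]
  surplus <- nrow(rows) - window$n_rows
  if (surplus < 0L) {
    need_s <- window$skip_head_s + window$skip_tail_s +
      window$n_rows / (attr(log, "log_rate_hz") %||% 10)
    eegbci_stop(
      "eegbci_short_log",
      sprintf("log provides %d scorable rows but %d are required; sessions must last at least %g s",
              nrow(rows), window$n_rows, need_s)
    )
  }
  drop_head <- ceiling(surplus / 2)
  rows[(drop_head + 1L):(drop_head + window$n_rows), , drop = FALSE]
}

#' Classification accuracy of scored rows
#'
#' Fraction of rows whose prediction matches the marker state.
#'
#' @param rows Data frame with `marker` and `prediction` columns (as from
#'   [select_scoring_rows()]).
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(rows) {
  if (is.null(nrow(rows)) || nrow(rows) == 0L) {
    eegbci_stop("eegbci_bad_argument", "cannot score an empty row set")
  }
  mean(rows$marker == rows$prediction)
}

#' Summarize accuracies across sessions and algorithms
#'
#' @param results Data frame with columns `subject`, `algorithm`, `accuracy`
#'   (extra columns such as `beep_interval_s` are carried through untouched).
#' @return An `algorithm_summary`: list with `per_session` (the input,
#'   ordered), `per_algorithm` (mean accuracy per algorithm) and
#'   `per_subject_algorithm`.
#' @export
summarize_results <- function(results) {
  stopifnot(all(c("subject", "algorithm", "accuracy") %in% names(results)))
  if (any(results$accuracy < 0 | results$accuracy > 1)) {
    eegbci_stop("eegbci_bad_argument", "accuracies must lie in [0, 1]")
  }
  per_alg <- stats::aggregate(accuracy ~ algorithm, data = results, FUN = mean)
  per_alg <- per_alg[order(per_alg$algorithm), , drop = FALSE]
  per_sub <- stats::aggregate(accuracy ~ subject + algorithm, data = results,
                              FUN = mean)
  per_sub <- per_sub[order(per_sub$algorithm, per_sub$subject), , drop = FALSE]
  rownames(per_alg) <- rownames(per_sub) <- NULL
  structure(list(per_session = results,
                 per_algorithm = per_alg,
                 per_subject_algorithm = per_sub),
            class = "algorithm_summary")
}

#' @export
print.algorithm_summary <- function(x, ...) {
  cat("<algorithm_summary> mean accuracy per algorithm:\n")
  print(x$per_algorithm, row.names = FALSE)
  invisible(x)
}

#' Published reference accuracies
#'
#' The bundled table of per-session accuracies reported for the original
#' live-EEG experiments (12 subjects, four trainers, 5 or 10 s beep
#' intervals), transcribed with decimal points. Rows recorded at the 5 s
#' interval are flagged by the `beep_interval_s` column. These live-subject
#' values are reference context for comparison reports; they are not
#' reproducible from synthetic data.
#'
#' @return Data frame with columns `date`, `time`, `subject`, `algorithm`,
#'   `beep_interval_s`, `accuracy`.
#' @export
published_results <- function() {
  path <- system.file("extdata", "published_accuracy.csv", package = "eegbci",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
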