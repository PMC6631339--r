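# Session protocol: the alternating marker schedule, the warm-up training
# phase, and the prediction log.

#' Alternating marker schedule
#'
#' The timed session cue: the marker state alternates every `interval_s`
#' seconds starting from state 0, so `state(t) = floor(t / interval_s) mod 2`.
#' State 0 is cued by the high 1500 Hz tone (eyes open / rest), state 1 by
#' the low 1000 Hz tone (eyes closed / task). Tones are metadata only; no
#' audio is synthesized.
#'
#' @param duration_s Session length in seconds.
#' @param interval_s Marker interval in seconds (default 10).
#' @return A `marker_track`.
#' @export
marker_schedule <- function(duration_s, interval_s = 10) {
  assert_scalar_number(duration_s, "duration_s", positive = TRUE)
  assert_scalar_number(interval_s, "interval_s", positive = TRUE)
  structure(
    list(duration_s = duration_s, interval_s = interval_s,
         tones_hz = c(state0 = 1500, state1 = 1000)),
    class = "marker_track"
  )
}

#' Marker state at a time point
#'
#' @param track A [marker_schedule()].
#' @param t Time(s) in seconds.
#' @return Integer 0/1 state(s).
#' @export
marker_state <- function(track, t) {
  stopifnot(inherits(track, "marker_track"))
  as.integer(floor(t / track$interval_s) %% 2)
}

#' Session configuration
#'
#' @param trainer A [trainer_config()].
#' @param duration_s Total session length in seconds (default 110).
#' @param warmup_s Warm-up phase during which (feature, marker) pairs are
#'   accumulated for training (default 60).
#' @param interval_s Marker interval (default 10).
#' @param log_rate_hz Logging/feature cadence (default 10; 400 scored rows
#'   then correspond to 40 s).
#' @param seed Integer seed controlling weight initialization.
#' @param buffer_capacity Rolling buffer size in samples (default 1000).
#' @param filter_mode `"fir"` or `"iir"` band filters.
#' @param amp_window_s Trailing amplitude window passed to [decompose()]
#'   (default 1 s, keeping the feature's total detection lag near 2.5 s).
#' @param online_update If `TRUE`, continue retraining after the warm-up on
#'   the growing pair set at each marker interval boundary; default `FALSE`
#'   (train once at `warmup_s`, then freeze).
#' @return A `session_config`.
#' @export
session_config <- function(trainer = trainer_config(),
                           duration_s = 110, warmup_s = 60, interval_s = 10,
                           log_rate_hz = 10, seed = 1L,
                           buffer_capacity = 1000L,
                           filter_mode = c("fir", "iir"),
                           amp_window_s = 1, online_update = FALSE) {
  filter_mode <- match.arg(filter_mode)
  if (duration_s <= warmup_s + 10) {
    eegbci_stop("eegbci_bad_argument",
                "duration_s must exceed warmup_s by more than 10 s")
  }
  structure(
    list(trainer = trainer, duration_s = duration_s, warmup_s = warmup_s,
         interval_s = interval_s, log_rate_hz = log_rate_hz,
         seed = as.integer(seed), buffer_capacity = as.integer(buffer_capacity),
         filter_mode = filter_mode, amp_window_s = amp_window_s,
         online_update = isTRUE(online_update)),
    class = "session_config"
  )
}

# Feature matrix for a stream at the logging cadence.
#
# Equivalent to calling decompose() on each full-buffer window, but computed
# by filtering the whole stream once per band: for steady-state output
# samples (all FIR taps inside the window), per-window DC removal only
# shifts the filtered trace by window_mean * sum(b), so the per-window
# amplitudes can be recovered from the single full-stream filtering pass.
# An equality test against the per-window decompose() path guards this.
session_features <- function(stream, config, bank) {
  fs <- stream$sampling_rate_hz
  x <- as.numeric(stream$samples)
  n <- length(x)
  cap <- config$buffer_capacity
  step <- fs / config$log_rate_hz
  m <- amp_window_samples(cap, bank, config$amp_window_s)

  # log ticks k (0-based): time k / log_rate, needs sample index k * step
  k_first <- ceiling(cap / step)                   # first tick with a full buffer
  k_last <- floor((n / step) - 1e-9)
  ks <- k_first:k_last
  ends <- as.integer(round(ks * step))
  mask <- ends <= n
  ends <- ends[mask]
  ks <- ks[mask]

  cs <- cumsum(x)
  lo_idx <- ends - cap
  win_mean <- (cs[ends] - ifelse(lo_idx >= 1L, cs[pmax(lo_idx, 1L)], 0)) / cap

  feats <- matrix(NA_real_, nrow = length(ends), ncol = length(FEATURE_BANDS),
                  dimnames = list(NULL, FEATURE_BANDS))
  for (bn in FEATURE_BANDS) {
    spec <- bank[[bn]]
    y <- apply_filter(spec, x)
    sB <- sum(spec$b) / sum(spec$a)
    for (j in seq_along(ends)) {
      seg <- y[(ends[j] - m + 1L):ends[j]]
      feats[j, bn] <- mean(abs(seg - win_mean[j] * sB))
    }
  }
  list(tick = ks, time_s = ks / config$log_rate_hz, features = feats)
}

#' Run a timed BCI session
#'
#' Phase 1 (warm-up, `t < warmup_s`): once the rolling buffer has filled,
#' band-amplitude feature vectors and the concurrent marker states are
#' collected at the logging cadence. At `t = warmup_s` the features are
#' z-scored with statistics frozen from the warm-up and the network is
#' trained. Phase 2: each log tick emits a `(time, marker, prediction)` row
#' until `duration_s`. Deterministic given the stream and configuration.
#'
#' @param stream A [sample_stream()] covering at least `duration_s`.
#' @param config A [session_config()].
#' @return A `bci_session`: list with `log` (a `session_log` data frame of
#'   phase-2 rows), `network` (trained [init_network()] object), `norm`
#'   (feature means/sds), `markers`, and `config`.
#' @export
run_session <- function(stream, config = session_config()) {
  stopifnot(inherits(stream, "sample_stream"), inherits(config, "session_config"))
  fs <- stream$sampling_rate_hz
  needed <- as.integer(round((config$duration_s - 1 / config$log_rate_hz) * fs))
  if (length(stream$samples) < needed) {
    eegbci_stop(
      "eegbci_truncated_session",
      sprintf("stream ends at %.2f s but the session needs %.2f s",
              length(stream$samples) / fs, config$duration_s),
      time_reached = length(stream$samples) / fs
    )
  }
  markers <- marker_schedule(config$duration_s, config$interval_s)
  bank <- filter_bank(fs, mode = config$filter_mode)
  sf <- session_features(stream, config, bank)
  keep <- sf$time_s < config$duration_s
  time_s <- sf$time_s[keep]
  feats <- sf$features[keep, , drop = FALSE]
  labels <- marker_state(markers, time_s)

  in_warmup <- time_s < config$warmup_s
  if (!any(in_warmup)) {
    eegbci_stop("eegbci_bad_argument", "warm-up shorter than the buffer fill time")
  }
  Xw <- feats[in_warmup, , drop = FALSE]
  mu <- colMeans(Xw)
  sd_ <- apply(Xw, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  znorm <- function(M) sweep(sweep(M, 2L, mu, "-"), 2L, sd_, "/")

  net <- init_network(default_structure(config$trainer$algorithm),
                      seed = config$seed)
  net <- train_network(net, znorm(Xw), labels[in_warmup], config$trainer)

  predict_phase <- !in_warmup
  Xp <- feats[predict_phase, , drop = FALSE]
  if (config$online_update) {
    # retrain at each marker-interval boundary on all pairs seen so far
    pred <- integer(sum(predict_phase))
    tp <- time_s[predict_phase]
    boundary <- c(TRUE, floor(tp[-1] / config$interval_s) !=
                          floor(tp[-length(tp)] / config$interval_s))
    for (i in seq_along(tp)) {
      if (i > 1L && boundary[i]) {
        seen <- time_s < tp[i]
        net <- train_network(net, znorm(feats[seen, , drop = FALSE]),
                             labels[seen], config$trainer)
      }
      pred[i] <- predict_state(net, znorm(Xp[i, , drop = FALSE]))
    }
  } else {
    pred <- predict_state(net, znorm(Xp))
  }

  log <- data.frame(time_s = time_s[predict_phase],
                    marker = labels[predict_phase],
                    prediction = pred)
  log <- as_session_log(log, config, markers)
  structure(list(log = log, network = net,
                 norm = list(mean = mu, sd = sd_),
                 markers = markers, config = config),
            class = "bci_session")
}

as_session_log <- function(df, config, markers) {
  structure(df,
            class = c("session_log", "data.frame"),
            seed = config$seed,
            trainer = config$trainer$algorithm,
            interval_s = config$interval_s,
            log_rate_hz = config$log_rate_hz,
            duration_s = config$duration_s,
            tones_hz = markers$tones_hz)
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf("<bci_session> %s trainer, %d logged rows, %.0f s session\n",
              x$config$trainer$algorithm, nrow(x$log), x$config$duration_s))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Log files: '#'-prefixed key=value header, then CSV rows time_s,marker,
# prediction. The reader also accepts the legacy two-row layout (first row =
# markers, second row = predictions, whitespace- or comma-separated).

#' Write a session log file
#'
#' @param log A `session_log` (from [run_session()]`$log` or [read_log()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  hdr <- c(
    sprintf("# seed=%d", attr(log, "seed")),
    sprintf("# trainer=%s", attr(log, "trainer")),
    sprintf("# interval_s=%g", attr(log, "interval_s")),
    sprintf("# log_rate_hz=%g", attr(log, "log_rate_hz")),
    sprintf("# duration_s=%g", attr(log, "duration_s")),
    sprintf("# tone_state0_hz=%g", attr(log, "tones_hz")[["state0"]]),
    sprintf("# tone_state1_hz=%g", attr(log, "tones_hz")[["state1"]])
  )
  body <- sprintf("%.4f,%d,%d", log$time_s, log$marker, log$prediction)
  writeLines(c(hdr, "time_s,marker,prediction", body), path, sep = "\n")
  invisible(path)
}

#' Read a session log file
#'
#' Accepts both the native header+CSV format of [write_log()] and the legacy
#' two-row layout in which the first line holds the marker states and the
#' second the predictions (times are then reconstructed at `log_rate_hz`
#' starting from `t0`).
#'
#' @param path Input path.
#' @param log_rate_hz,t0 Cadence and start time used to reconstruct times for
#'   the two-row layout (defaults 10 Hz, 60 s).
#' @return A `session_log` data frame.
#' @export
read_log <- function(path, log_rate_hz = 10, t0 = 60) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    eegbci_stop("eegbci_parse_error", sprintf("empty log file: %s", path))
  }
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]

  meta <- list()
  for (h in header) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }

  is_tworow <- length(body) == 2L &&
    !grepl("time", body[1L], ignore.case = TRUE) &&
    length(strsplit(trimws(body[1L]), "[,[:space:]]+")[[1L]]) > 3L
  if (is_tworow) {
    markers <- as.numeric(strsplit(trimws(body[1L]), "[,[:space:]]+")[[1L]])
    preds <- as.numeric(strsplit(trimws(body[2L]), "[,[:space:]]+")[[1L]])
    if (length(markers) != length(preds)) {
      eegbci_stop("eegbci_parse_error", "two-row log: rows differ in length")
    }
    check_binary_col(markers, "marker", seq_along(markers))
    check_binary_col(preds, "prediction", seq_along(preds))
    df <- data.frame(time_s = t0 + (seq_along(markers) - 1L) / log_rate_hz,
                     marker = as.integer(markers),
                     prediction = as.integer(preds))
  } else {
    if (grepl("time", body[1L], ignore.case = TRUE)) body <- body[-1L]
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad) > 0L) {
      eegbci_stop("eegbci_parse_error",
                  sprintf("malformed log row %d: '%s'", bad[1L], body[bad[1L]]),
                  row = bad[1L])
    }
    mat <- do.call(rbind, parts)
    time_s <- as.numeric(mat[, 1L])
    markers <- as.numeric(mat[, 2L])
    preds <- as.numeric(mat[, 3L])
    if (any(is.na(time_s))) {
      eegbci_stop("eegbci_parse_error",
                  sprintf("non-numeric time in log row %d", which(is.na(time_s))[1L]))
    }
    check_binary_col(markers, "marker", seq_along(markers))
    check_binary_col(preds, "prediction", seq_along(preds))
    df <- data.frame(time_s = time_s, marker = as.integer(markers),
                     prediction = as.integer(preds))
  }

  num_meta <- function(key, default) {
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  }
  structure(df,
            class = c("session_log", "data.frame"),
            seed = as.integer(num_meta("seed", NA)),
            trainer = meta[["trainer"]] %||% NA_character_,
            interval_s = num_meta("interval_s", 10),
            log_rate_hz = num_meta("log_rate_hz", log_rate_hz),
            duration_s = num_meta("duration_s",
                                  max(df$time_s) + 1 / num_meta("log_rate_hz", log_rate_hz)),
            tones_hz = c(state0 = num_meta("tone_state0_hz", 1500),
                         state1 = num_meta("tone_state1_hz", 1000)))
}

check_binary_col <- function(v, what, rows) {
  bad <- which(is.na(v) | !(v %in% c(0, 1)))
  if (length(bad) > 0L) {
    eegbci_stop("eegbci_parse_error",
                sprintf("non-binary %s value in log row %d", what, rows[bad[1L]]),
                row = rows[bad[1L]])
  }
  invisible(v)
}
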