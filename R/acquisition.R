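# Acquisition: uniform sample sources and the rolling buffer feeding the
# filter bank. All sources deliver the same contract: an ordered vector of
# 10-bit ADC counts at a fixed sampling rate, sample i (0-based) at
# t0 + i / sampling_rate_hz.

ADC_MIN <- 0L
ADC_MAX <- 1023L

#' Construct an EEG sample stream
#'
#' A `sample_stream` is the common currency of the acquisition layer: an
#' ordered vector of integer analogue-to-digital converter (ADC) counts in
#' \[0, 1023\] (10-bit converter) sampled uniformly at `sampling_rate_hz`.
#' Timestamps are implicit: sample `i` (0-based) lies at
#' `t0 + i / sampling_rate_hz` seconds.
#'
#' @param samples Integer vector of ADC counts in \[0, 1023\].
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @param t0 Session start time in seconds (default 0).
#' @return An object of class `sample_stream`.
#' @examples
#' s <- sample_stream(c(512L, 600L, 400L))
#' length(s$samples)
#' @export
sample_stream <- function(samples, sampling_rate_hz = 100, t0 = 0) {
  assert_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  assert_scalar_number(t0, "t0")
  samples <- check_adc(samples)
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz, t0 = t0),
    class = "sample_stream"
  )
}

check_adc <- function(samples, offset_label = NULL) {
  if (length(samples) == 0L) return(integer(0))
  if (!is.numeric(samples) || any(is.na(samples)) || any(samples != round(samples))) {
    eegbci_stop("eegbci_range_error", "samples must be integers")
  }
  bad <- which(samples < ADC_MIN | samples > ADC_MAX)
  if (length(bad) > 0L) {
    where <- if (is.null(offset_label)) sprintf("sample %d", bad[1L]) else
      sprintf("%s %d", offset_label, bad[1L])
    eegbci_stop(
      "eegbci_range_error",
      sprintf("ADC value %d at %s outside [0, 1023]", as.integer(samples[bad[1L]]), where)
    )
  }
  as.integer(samples)
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf("<sample_stream> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$t0))
  invisible(x)
}

#' Rolling sample buffer
#'
#' Fixed-capacity first-in-first-out buffer holding the most recent samples.
#' At the default capacity of 1000 and sampling rate of 100 Hz, a full buffer
#' spans the 10-second analysis window used by the rhythm decomposition.
#'
#' @param capacity Maximum number of retained samples (default 1000).
#' @return An object of class `ring_buffer`.
#' @seealso [rb_push()], [rb_contents()], [decompose()]
#' @export
ring_buffer <- function(capacity = 1000L) {
  assert_scalar_number(capacity, "capacity", positive = TRUE)
  if (capacity != round(capacity)) {
    eegbci_stop("eegbci_bad_argument", "`capacity` must be an integer")
  }
  structure(
    list(capacity = as.integer(capacity),
         data = integer(capacity),   # slots, filled circularly
         head = 0L,                  # index of next write (0-based)
         count = 0L),
    class = "ring_buffer"
  )
}

#' Push samples into a ring buffer
#'
#' Appends samples in arrival order, discarding the oldest once the buffer is
#' full. After pushing `k` samples in total the buffer holds the last
#' `min(k, capacity)` of them, oldest first.
#'
#' @param buffer A [ring_buffer()].
#' @param samples Integer ADC samples in \[0, 1023\] (one or more).
#' @return The updated `ring_buffer`.
#' @export
rb_push <- function(buffer, samples) {
  stopifnot(inherits(buffer, "ring_buffer"))
  samples <- check_adc(samples)
  n <- length(samples)
  if (n == 0L) return(buffer)
  cap <- buffer$capacity
  if (n >= cap) {
    buffer$data <- samples[(n - cap + 1L):n]
    buffer$head <- 0L
    buffer$count <- cap
    return(buffer)
  }
  idx <- ((buffer$head + seq_len(n) - 1L) %% cap) + 1L
  buffer$data[idx] <- samples
  buffer$head <- (buffer$head + n) %% cap
  buffer$count <- min(buffer$count + n, cap)
  buffer
}

#' Buffer contents in arrival order
#'
#' @param buffer A [ring_buffer()].
#' @return Integer vector of the retained samples, oldest first.
#' @export
rb_contents <- function(buffer) {
  stopifnot(inherits(buffer, "ring_buffer"))
  cap <- buffer$capacity
  if (buffer$count < cap) {
    return(buffer$data[seq_len(buffer$count)])
  }
  if (buffer$head == 0L) buffer$data else
    c(buffer$data[(buffer$head + 1L):cap], buffer$data[seq_len(buffer$head)])
}

#' @rdname rb_contents
#' @export
rb_is_full <- function(buffer) {
  stopifnot(inherits(buffer, "ring_buffer"))
  buffer$count == buffer$capacity
}

#' @export
print.ring_buffer <- function(x, ...) {
  cat(sprintf("<ring_buffer> %d/%d samples\n", x$count, x$capacity))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serial frame codec.
#
# Each 10-bit sample travels as two bytes:
#   high byte: 0x80 | (value >> 7)   -- sync bit set, top 3 value bits
#   low  byte: value & 0x7F          -- sync bit clear, bottom 7 value bits
# The sync bit makes the stream self-synchronizing: after byte loss the parser
# skips to the next byte with the top bit set and resumes.

#' Encode ADC samples as a 2-byte serial frame stream
#'
#' @param samples Integer ADC samples in \[0, 1023\].
#' @return A `raw` vector, two bytes per sample (high byte first).
#' @examples
#' encode_frames(c(512L, 600L, 400L))
#' @export
encode_frames <- function(samples) {
  samples <- check_adc(samples)
  if (length(samples) == 0L) return(raw(0))
  hi <- bitwOr(0x80L, bitwShiftR(samples, 7L))
  lo <- bitwAnd(samples, 0x7FL)
  as.raw(as.vector(rbind(hi, lo)))
}

#' Decode a serial frame byte stream into a sample stream
#'
#' Scans for frames (a sync byte with the top bit set followed by a data byte
#' with it clear), resynchronizing past any stray bytes. A truncated trailing
#' frame is discarded and counted in the `discarded_bytes` attribute.
#'
#' @param bytes A `raw` vector in the frame dialect of [encode_frames()].
#' @param sampling_rate_hz Sampling rate to stamp on the stream (default 100).
#' @return A [sample_stream()]; attribute `discarded_bytes` counts bytes that
#'   did not form a complete frame.
#' @export
parse_frame_stream <- function(bytes, sampling_rate_hz = 100) {
  stopifnot(is.raw(bytes))
  ints <- as.integer(bytes)
  n <- length(ints)
  vals <- integer(n %/% 2L)
  nv <- 0L
  discarded <- 0L
  i <- 1L
  while (i <= n) {
    if (ints[i] < 128L) {        # not a sync byte: skip (resynchronize)
      discarded <- discarded + 1L
      i <- i + 1L
      next
    }
    if (i == n) {                # sync byte with no data byte: truncated frame
      discarded <- discarded + 1L
      break
    }
    if (ints[i + 1L] >= 128L) {  # two sync bytes in a row: drop the first
      discarded <- discarded + 1L
      i <- i + 1L
      next
    }
    value <- bitwOr(bitwShiftL(bitwAnd(ints[i], 0x7FL), 7L), ints[i + 1L])
    if (value > ADC_MAX) {
      eegbci_stop(
        "eegbci_frame_corruption",
        sprintf("decoded value %d at byte offset %d outside [0, 1023]", value, i - 1L),
        byte_offset = i - 1L
      )
    }
    nv <- nv + 1L
    vals[nv] <- value
    i <- i + 2L
  }
  out <- sample_stream(vals[seq_len(nv)], sampling_rate_hz = sampling_rate_hz)
  attr(out, "discarded_bytes") <- discarded
  out
}

# ---------------------------------------------------------------------------
# Replay files: plain text, one decimal integer per line, LF line endings.

#' Write a sample stream to a replay file
#'
#' @param stream A [sample_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_replay <- function(stream, path) {
  stopifnot(inherits(stream, "sample_stream"))
  writeLines(as.character(stream$samples), path, sep = "\n")
  invisible(path)
}

#' Read a replay file as a sample stream
#'
#' Replay files are plain text with one decimal ADC count per line.
#'
#' @param path Input file path.
#' @param sampling_rate_hz Sampling rate of the recording (default 100).
#' @return A [sample_stream()].
#' @export
replay_source <- function(path, sampling_rate_hz = 100) {
  if (!file.exists(path)) {
    eegbci_stop("eegbci_io_error", sprintf("replay file not found: %s", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(sample_stream(integer(0), sampling_rate_hz = sampling_rate_hz))
  }
  vals <- suppressWarnings(as.integer(lines))
  bad <- which(is.na(vals) | lines != as.character(vals))
  if (length(bad) > 0L) {
    eegbci_stop(
      "eegbci_parse_error",
      sprintf("line %d of %s is not a decimal integer: '%s'", bad[1L], path, lines[bad[1L]]),
      line = bad[1L]
    )
  }
  tryCatch(
    sample_stream(vals, sampling_rate_hz = sampling_rate_hz),
    eegbci_range_error = function(e) {
      eegbci_stop("eegbci_range_error",
                  sprintf("%s while reading %s", conditionMessage(e), path))
    }
  )
}
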