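# Rhythm decomposition: band-pass filter bank over the clinical EEG bands and
# amplitude feature extraction from the rolling buffer.

#' EEG rhythm band table
#'
#' The clinical rhythm bands used throughout the package: delta 0.5--3 Hz,
#' alpha 8--13 Hz, three beta sub-bands (beta0 13--16, beta1 16--23,
#' beta2 23--31 Hz) partitioning the beta range, and gamma. The physiological
#' gamma band extends to 100 Hz; at the default 100 Hz sampling rate it is
#' clipped to 32--45 Hz so the filter is realizable below Nyquist, and gamma
#' is excluded from the 5-element network feature vector (see
#' [feature_vector()]).
#'
#' @param sampling_rate_hz Sampling rate the bands must respect (default 100).
#' @return A data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
rhythm_bands <- function(sampling_rate_hz = 100) {
  bands <- data.frame(
    name    = c("delta", "alpha", "beta0", "beta1", "beta2", "gamma"),
    low_hz  = c(0.5, 8, 13, 16, 23, 32),
    high_hz = c(3, 13, 16, 23, 31, 45),
    stringsAsFactors = FALSE
  )
  nyq <- sampling_rate_hz / 2
  if (any(bands$high_hz >= nyq)) {
    eegbci_stop("eegbci_design_error",
                sprintf("band table requires Nyquist > %g Hz; clip bands below %g Hz",
                        max(bands$high_hz), nyq))
  }
  bands
}

# Order of the 5 amplitudes fed to the network.
FEATURE_BANDS <- c("alpha", "beta0", "beta1", "beta2", "delta")

#' Design a band-pass filter for one rhythm band
#'
#' Default mode is a linear-phase FIR band-pass (windowed-sinc, Hamming
#' window) whose magnitude approximates the maximally flat Butterworth shape;
#' an explicit 4th-order Butterworth IIR mode is also available. Both modes
#' satisfy the same response contract: unity gain (within 1 dB) at band
#' centre, at least 20 dB attenuation at DC and at Nyquist.
#'
#' @param band One row of [rhythm_bands()] (or a list with `name`, `low_hz`,
#'   `high_hz`).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param mode `"fir"` (linear-phase windowed-sinc, default) or `"iir"`
#'   (Butterworth).
#' @param taps_or_order FIR tap count (odd, default 401) or IIR order
#'   (default 4).
#' @return A `filter_spec` with elements `band`, `mode`, `taps_or_order`,
#'   `b` (numerator coefficients) and `a` (denominator; `1` for FIR).
#' @examples
#' spec <- design_bandpass(rhythm_bands()[2, ], 100)
#' length(spec$b)
#' @export
design_bandpass <- function(band, sampling_rate_hz = 100,
                            mode = c("fir", "iir"),
                            taps_or_order = NULL) {
  mode <- match.arg(mode)
  band <- as.list(band)
  lo <- band$low_hz; hi <- band$high_hz
  nyq <- sampling_rate_hz / 2
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo) {
    eegbci_stop("eegbci_design_error", "band must satisfy 0 < low_hz < high_hz")
  }
  if (hi >= nyq) {
    eegbci_stop(
      "eegbci_design_error",
      sprintf("band %s (%g-%g Hz) reaches Nyquist (%g Hz); clip the band below Nyquist",
              band$name %||% "?", lo, hi, nyq)
    )
  }
  w <- c(lo, hi) / nyq
  if (mode == "fir") {
    taps <- taps_or_order %||% 401L
    if (taps < 3L || taps %% 2L == 0L) {
      eegbci_stop("eegbci_design_error", "FIR tap count must be odd and >= 3")
    }
    b <- as.numeric(signal::fir1(taps - 1L, w, type = "pass"))
    b <- b - mean(b)        # exact DC rejection; passband change is negligible
    a <- 1
  } else {
    ord <- taps_or_order %||% 4L
    flt <- signal::butter(ord, w, type = "pass")
    b <- as.numeric(flt$b); a <- as.numeric(flt$a)
    poles <- polyroot(rev(a))
    if (any(Mod(poles) >= 1)) {
      eegbci_stop("eegbci_design_error",
                  sprintf("IIR design for band %s is unstable; lower the order",
                          band$name %||% "?"))
    }
    taps <- ord
  }
  structure(
    list(band = band, mode = mode, taps_or_order = as.integer(taps),
         b = b, a = a, sampling_rate_hz = sampling_rate_hz),
    class = "filter_spec"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Design the default filter bank
#'
#' One band-pass filter per row of the band table.
#'
#' @inheritParams design_bandpass
#' @param bands Band table as from [rhythm_bands()].
#' @return Named list of `filter_spec` objects.
#' @export
filter_bank <- function(sampling_rate_hz = 100, mode = c("fir", "iir"),
                        taps_or_order = NULL,
                        bands = rhythm_bands(sampling_rate_hz)) {
  mode <- match.arg(mode)
  specs <- lapply(seq_len(nrow(bands)), function(i) {
    design_bandpass(bands[i, ], sampling_rate_hz, mode, taps_or_order)
  })
  names(specs) <- bands$name
  specs
}

#' Evaluate a filter's frequency response
#'
#' Magnitude of the transfer function at the requested frequencies, computed
#' directly from the coefficients.
#'
#' @param spec A `filter_spec`.
#' @param freq_hz Numeric vector of frequencies in Hz.
#' @return Numeric vector of magnitudes (linear, not dB).
#' @export
filter_response <- function(spec, freq_hz) {
  stopifnot(inherits(spec, "filter_spec"))
  fs <- spec$sampling_rate_hz
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    num <- sum(spec$b * z^(seq_along(spec$b) - 1L))
    den <- sum(spec$a * z^(seq_along(spec$a) - 1L))
    Mod(num / den)
  }, numeric(1))
}

#' Apply a designed filter to a signal window
#'
#' Causal filtering with zero initial conditions ("zero-padded startup"):
#' output length equals input length, and for an FIR filter output sample
#' `n >= taps` depends only on window samples, so the tail of the output is
#' in steady state.
#'
#' @param spec A `filter_spec`.
#' @param window Numeric vector; for FIR mode must be at least as long as the
#'   tap count.
#' @return Numeric vector, same length as `window`.
#' @export
apply_filter <- function(spec, window) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$mode == "fir" && length(window) < length(spec$b)) {
    eegbci_stop(
      "eegbci_insufficient_data",
      sprintf("window of %d samples is shorter than the %d filter taps",
              length(window), length(spec$b))
    )
  }
  as.numeric(signal::filter(spec$b, spec$a, as.numeric(window)))
}

#' Mean amplitude of a signal
#'
#' The package's "average amplitude" convention: the mean absolute value of
#' the samples. For a sinusoid of amplitude A sampled over whole periods this
#' is (2/pi) * A.
#'
#' @param signal Non-empty numeric vector.
#' @return Non-negative scalar; zero iff the signal is identically zero.
#' @export
mean_amplitude <- function(signal) {
  if (length(signal) == 0L) {
    eegbci_stop("eegbci_bad_argument", "mean_amplitude of an empty signal is undefined")
  }
  mean(abs(signal))
}

#' Decompose a full buffer into rhythm band amplitudes
#'
#' Subtracts the window mean (DC removal), runs each band-pass filter of the
#' bank over the window, and summarizes each band by its mean amplitude over
#' the most recent `amp_window_s` seconds of steady-state filter output
#' (samples unaffected by the startup transient). The raw amplitude is the
#' mean absolute deviation of the unfiltered window from its mean.
#'
#' Restricting the amplitude estimate to a short trailing window keeps the
#' feature responsive: averaging over the whole 10-second buffer would smear
#' a state change over the full marker interval (see the methods vignette).
#'
#' @param buffer A full [ring_buffer()] or a numeric window.
#' @param bank Filter bank from [filter_bank()].
#' @param amp_window_s Trailing span, in seconds, over which band amplitudes
#'   are averaged (default 1).
#' @return A `rhythm_frame`: list with `filtered` (named list of band traces,
#'   window length each), `amplitude` (named non-negative vector),
#'   `raw_amplitude`, and the configuration used.
#' @export
decompose <- function(buffer, bank = filter_bank(), amp_window_s = 1) {
  if (inherits(buffer, "ring_buffer")) {
    if (!rb_is_full(buffer)) {
      eegbci_stop(
        "eegbci_not_ready",
        sprintf("buffer holds %d of %d samples; wait until it fills", buffer$count,
                buffer$capacity)
      )
    }
    window <- as.numeric(rb_contents(buffer))
  } else {
    window <- as.numeric(buffer)
  }
  fs <- bank[[1L]]$sampling_rate_hz
  n <- length(window)
  centred <- window - mean(window)
  m <- amp_window_samples(n, bank, amp_window_s)
  tail_idx <- (n - m + 1L):n
  filtered <- lapply(bank, function(spec) apply_filter(spec, centred))
  amplitude <- vapply(filtered, function(y) mean(abs(y[tail_idx])), numeric(1))
  structure(
    list(filtered = filtered,
         amplitude = amplitude,
         raw_amplitude = mean(abs(centred)),
         amp_window_s = amp_window_s,
         sampling_rate_hz = fs),
    class = "rhythm_frame"
  )
}

# Trailing amplitude window in samples, constrained so that (in FIR mode) it
# stays inside the steady-state region of the causal filter output.
amp_window_samples <- function(n, bank, amp_window_s) {
  fs <- bank[[1L]]$sampling_rate_hz
  m <- as.integer(round(amp_window_s * fs))
  max_taps <- max(vapply(bank, function(s)
    if (s$mode == "fir") length(s$b) else 1L, numeric(1)))
  steady <- n - max_taps + 1L
  if (m < 1L || m > steady) {
    eegbci_stop(
      "eegbci_bad_argument",
      sprintf("amp_window_s of %g s needs %d steady-state samples but only %d are available",
              amp_window_s, m, steady)
    )
  }
  m
}

#' @export
print.rhythm_frame <- function(x, ...) {
  cat("<rhythm_frame> band amplitudes (ADC counts):\n")
  print(round(x$amplitude, 3))
  cat(sprintf("raw amplitude: %.3f\n", x$raw_amplitude))
  invisible(x)
}

#' Network feature vector from a rhythm frame
#'
#' The 5 amplitudes fed to the perceptron, in order: alpha, beta0, beta1,
#' beta2, delta. Gamma is excluded (clipped band, no feature).
#'
#' @param frame A `rhythm_frame` from [decompose()].
#' @return Named numeric vector of length 5.
#' @export
feature_vector <- function(frame) {
  stopifnot(inherits(frame, "rhythm_frame"))
  frame$amplitude[FEATURE_BANDS]
}

#' Alpha to raw amplitude ratio
#'
#' The eyes-open / eyes-closed reactivity index: 1000 times the ratio of the
#' alpha-band mean amplitude to the raw signal's mean amplitude. Returns `NA`
#' (with a warning) when the raw amplitude is zero.
#'
#' @param frame A `rhythm_frame` from [decompose()].
#' @return Non-negative scalar, or `NA_real_` for a flat window.
#' @export
alpha_ratio <- function(frame) {
  stopifnot(inherits(frame, "rhythm_frame"))
  if (frame$raw_amplitude == 0) {
    warning("raw amplitude is zero; alpha ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  1000 * unname(frame$amplitude["alpha"]) / frame$raw_amplitude
}

#' Export filter bank coefficients as CSV
#'
#' One row per coefficient: band, mode, role (`b`/`a`), index, value.
#'
#' @param bank Filter bank from [filter_bank()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_csv <- function(bank, path) {
  rows <- do.call(rbind, lapply(names(bank), function(nm) {
    spec <- bank[[nm]]
    rbind(
      data.frame(band = nm, mode = spec$mode, role = "b",
                 index = seq_along(spec$b) - 1L, value = spec$b),
      if (spec$mode == "iir")
        data.frame(band = nm, mode = spec$mode, role = "a",
                   index = seq_along(spec$a) - 1L, value = spec$a)
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
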