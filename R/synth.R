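# Synthetic EEG source: seeded, state-modulated band oscillations plus pink
# background noise, quantized to the 10-bit ADC range. Stands in for the
# amplifier/Arduino chain and the human subject so the whole pipeline can be
# exercised reproducibly.

# Baseline per-band oscillation amplitudes in ADC counts (state 0). Alpha is
# the dominant posterior rhythm; delta carries slow background; the beta
# sub-bands and gamma are weaker. Chosen once as a plausible resting profile
# for a single bipolar channel on a 10-bit scale.
DEFAULT_AMPS <- c(delta = 20, alpha = 30, beta0 = 10, beta1 = 10, beta2 = 8,
                  gamma = 5)

#' State-dependent amplitude model for the synthetic EEG source
#'
#' Describes, per rhythm band and per marker state (0/1), the oscillation
#' amplitude in ADC counts, plus the broadband pink-noise level and the ADC
#' baseline offset.
#'
#' @param amp_state0 Named amplitude vector (ADC counts) for marker state 0;
#'   names must match [rhythm_bands()].
#' @param amp_state1 Amplitudes for marker state 1 (default: same as state 0).
#' @param noise_sd Standard deviation of the pink background noise in ADC
#'   counts (default 15).
#' @param baseline ADC offset (default 512, mid-scale).
#' @param jitter Fractional frequency wobble per band (default 0.1): the
#'   instantaneous oscillation frequency wanders smoothly around the drawn
#'   band frequency by about this relative amount (clipped to the band), the
#'   way real rhythm peak frequencies drift within a state.
#' @param amp_jitter Log-scale standard deviation of the slow multiplicative
#'   amplitude modulation per band (default 0.3): rhythms wax and wane on a
#'   roughly one-second timescale around the state's nominal amplitude
#'   instead of holding it constant. Set to 0 for strictly stationary tones.
#' @return An `amplitude_model`.
#' @seealso [preset()] for the ready-made experiment models.
#' @export
amplitude_model <- function(amp_state0 = DEFAULT_AMPS,
                            amp_state1 = amp_state0,
                            noise_sd = 15, baseline = 512, jitter = 0.1,
                            amp_jitter = 0.3) {
  stopifnot(length(amp_state0) == length(amp_state1),
            !is.null(names(amp_state0)))
  if (any(amp_state0 < 0) || any(amp_state1 < 0) || noise_sd < 0) {
    eegbci_stop("eegbci_bad_argument", "amplitudes and noise_sd must be >= 0")
  }
  if (jitter < 0 || jitter > 1) {
    eegbci_stop("eegbci_bad_argument", "jitter must lie in [0, 1]")
  }
  if (amp_jitter < 0) {
    eegbci_stop("eegbci_bad_argument", "amp_jitter must be >= 0")
  }
  structure(
    list(amp = rbind(state0 = amp_state0, state1 = amp_state1[names(amp_state0)]),
         noise_sd = noise_sd, baseline = baseline, jitter = jitter,
         amp_jitter = amp_jitter),
    class = "amplitude_model"
  )
}

# Smooth unit-variance modulation signal: white noise averaged over a 1 s
# sliding window, so the wobble timescale is about a second.
smooth_noise <- function(n, sampling_rate_hz) {
  w <- stats::rnorm(n + sampling_rate_hz)
  m <- stats::filter(w, rep(1 / sampling_rate_hz, sampling_rate_hz),
                     sides = 1)
  m <- as.numeric(m)[(sampling_rate_hz + 1L):(sampling_rate_hz + n)]
  m / stats::sd(m)
}

#' Built-in experiment presets
#'
#' Three amplitude models mirroring the session types the pipeline is meant
#' to detect:
#' \describe{
#'   \item{`eo_ec_alpha`}{Eyes-open / eyes-closed reactivity: the alpha
#'     amplitude doubles in state 1 (eyes closed), all else unchanged.}
#'   \item{`task_beta`}{Mental-task activation: the three beta sub-bands rise
#'     by 50\% and alpha drops by 30\% in state 1.}
#'   \item{`null`}{No state effect; both states share the resting profile.
#'     Drives the pipeline to chance-level accuracy.}
#' }
#'
#' @param name Preset name.
#' @return An [amplitude_model()].
#' @export
preset <- function(name) {
  known <- c("eo_ec_alpha", "task_beta", "null")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    eegbci_stop("eegbci_bad_argument",
                sprintf("unknown preset '%s'; available: %s",
                        paste(name, collapse = ","), paste(known, collapse = ", ")))
  }
  a0 <- DEFAULT_AMPS
  a1 <- a0
  if (name == "eo_ec_alpha") {
    a1["alpha"] <- 2 * a0["alpha"]
  } else if (name == "task_beta") {
    a1[c("beta0", "beta1", "beta2")] <- 1.5 * a0[c("beta0", "beta1", "beta2")]
    a1["alpha"] <- 0.7 * a0["alpha"]
  }
  amplitude_model(a0, a1)
}

# Pink (1/f) noise of length n, unit variance, from the seeded RNG in effect.
# White Gaussian noise is shaped in the frequency domain by 1/sqrt(f), with
# the spectrum flattened below f_floor so the variance stays finite.
pink_noise <- function(n, sampling_rate_hz, f_floor = 0.5) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- seq(0, sampling_rate_hz, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sampling_rate_hz - f)            # two-sided frequency axis
  scale <- 1 / sqrt(pmax(f, f_floor))
  scale[1L] <- 0                                # no DC component
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic EEG session stream
#'
#' For each rhythm band, a sinusoid whose frequency is drawn uniformly inside
#' the band (re-drawn at each marker interval, phase-continuous across the
#' switch) is scaled by the amplitude of the current marker state; the band
#' oscillations, the pink noise and the baseline are summed and rounded to
#' integer ADC counts. Generation fails if more than 0.1\% of samples would
#' clip against the \[0, 1023\] range.
#'
#' @param model An [amplitude_model()].
#' @param markers A [marker_schedule()] giving duration, interval and state.
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @param seed Integer seed; the same seed yields a bit-identical stream.
#' @return A [sample_stream()].
#' @export
generate_session <- function(model, markers, sampling_rate_hz = 100, seed) {
  stopifnot(inherits(model, "amplitude_model"), inherits(markers, "marker_track"))
  fs <- sampling_rate_hz
  n <- as.integer(round(markers$duration_s * fs))
  bands <- rhythm_bands(fs)
  band_names <- colnames(model$amp)
  bands <- bands[match(band_names, bands$name), ]
  t_idx <- seq_len(n) - 1L                       # sample i at (i-1)/fs
  interval_idx <- floor((t_idx / fs) / markers$interval_s)   # 0-based interval
  state <- interval_idx %% 2
  n_int <- max(interval_idx) + 1L

  with_seed(seed, {
    sig <- numeric(n)
    for (k in seq_along(band_names)) {
      lo <- bands$low_hz[k]; hi <- bands$high_hz[k]
      freqs <- stats::runif(n_int, lo, hi)       # one frequency per interval
      f_per_sample <- freqs[interval_idx + 1L]
      if (model$jitter > 0) {
        wobble <- 1 + model$jitter * smooth_noise(n, fs)
        f_per_sample <- pmin(pmax(f_per_sample * wobble, lo), hi)
      }
      phase <- cumsum(2 * pi * f_per_sample / fs)   # phase-continuous
      amp <- model$amp[state + 1L, k]
      if (model$amp_jitter > 0) {
        # lognormal waxing/waning with mean multiplier 1
        amp <- amp * exp(model$amp_jitter * smooth_noise(n, fs) -
                           model$amp_jitter^2 / 2)
      }
      sig <- sig + amp * sin(phase)
    }
    if (model$noise_sd > 0) {
      sig <- sig + model$noise_sd * pink_noise(n, fs)
    }
    raw <- round(model$baseline + sig)
    clipped <- sum(raw < ADC_MIN | raw > ADC_MAX)
    if (clipped / n >= 0.001) {
      eegbci_stop(
        "eegbci_config_error",
        sprintf("amplitude model clips %.2f%% of samples (limit 0.1%%); reduce amplitudes or noise",
                100 * clipped / n)
      )
    }
    raw <- pmin(pmax(raw, ADC_MIN), ADC_MAX)
    sample_stream(as.integer(raw), sampling_rate_hz = fs)
  })
}
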