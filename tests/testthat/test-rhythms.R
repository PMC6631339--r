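# Filter design, filtering, and amplitude features.

test_that("band-pass designs meet the response contract in both modes", {
  bands <- rhythm_bands(100)
  for (mode in c("fir", "iir")) {
    bank <- filter_bank(100, mode = mode)
    for (i in seq_len(nrow(bands))) {
      spec <- bank[[bands$name[i]]]
      centre <- mean(c(bands$low_hz[i], bands$high_hz[i]))
      mag <- freqz_mag(spec, c(centre, 1e-6, 50))
      expect_lt(abs(20 * log10(mag[1])), 1)          # centre within +-1 dB
      expect_lt(20 * log10(mag[2]), -20)             # DC <= -20 dB
      expect_lt(20 * log10(mag[3]), -20)             # Nyquist <= -20 dB
      if (mode == "fir") {
        expect_equal(spec$b, rev(spec$b))            # linear phase
        # no sidelobe above -15 dB outside a 2 Hz transition region
        stop_f <- setdiff(seq(0.05, 49.95, by = 0.05),
                          seq(bands$low_hz[i] - 2, bands$high_hz[i] + 2, by = 0.05))
        stop_f <- c(stop_f[stop_f < bands$low_hz[i] - 2],
                    stop_f[stop_f > bands$high_hz[i] + 2])
        if (length(stop_f) > 0) {
          expect_lt(max(20 * log10(freqz_mag(spec, stop_f))), -15)
        }
      } else {
        expect_true(all(Mod(polyroot(rev(spec$a))) < 1))   # stable
      }
    }
  }
  expect_error(
    design_bandpass(list(name = "gamma", low_hz = 32, high_hz = 100), 100),
    class = "eegbci_design_error"
  )
})

test_that("designed responses pass and reject sinusoids as predicted", {
  alpha <- design_bandpass(rhythm_bands(100)[2, ], 100)
  # oracle: the design's own frequency response evaluated at the test tones
  expect_gte(freqz_mag(alpha, 10), 0.89)
  expect_lte(freqz_mag(alpha, 10), 1.12)
  expect_lt(freqz_mag(alpha, 4), 0.1)

  # DC input through any band filter decays to ~0 after the transient
  for (spec in filter_bank(100)) {
    y <- apply_filter(spec, rep(512, 1500))
    expect_lt(abs(mean(tail(y, 500))), 512 * 1e-6)
  }
})

test_that("apply_filter is linear, matches FFT convolution, and validates input", {
  spec <- design_bandpass(rhythm_bands(100)[2, ], 100)
  n <- 1000

  expect_identical(apply_filter(spec, rep(0, n)), rep(0, n))

  imp <- c(1, rep(0, n - 1))
  expect_equal(apply_filter(spec, imp)[seq_along(spec$b)], spec$b,
               tolerance = 1e-12)

  set.seed(3)
  x <- rnorm(n); y <- rnorm(n)
  a <- 2.5; b <- -1.25
  expect_equal(apply_filter(spec, a * x + b * y),
               a * apply_filter(spec, x) + b * apply_filter(spec, y),
               tolerance = 1e-9)

  # FFT-convolution oracle for the causal FIR result
  h <- spec$b
  ff <- Re(fft(fft(c(x, rep(0, length(h)))) *
                 fft(c(h, rep(0, n))), inverse = TRUE)) / (n + length(h))
  expect_lt(max(abs(apply_filter(spec, x) - ff[seq_len(n)])), 1e-8)

  # time invariance: shifting the input shifts the interior of the output
  shift <- 100L
  xs <- c(rep(0, shift), x[seq_len(n - shift)])
  ys <- apply_filter(spec, xs)
  y0 <- apply_filter(spec, x)
  interior <- (length(h) + shift + 1L):n
  expect_equal(ys[interior], y0[interior - shift], tolerance = 1e-10)

  expect_error(apply_filter(spec, rnorm(100)), class = "eegbci_insufficient_data")
})

test_that("mean_amplitude follows the mean-absolute-value convention", {
  expect_identical(mean_amplitude(c(1, -1, 1, -1)), 1.0)
  expect_identical(mean_amplitude(c(0, 0, 0)), 0.0)
  t <- seq(0, 10 - 0.01, by = 0.01)                 # 10 full periods at 1 Hz
  expect_equal(mean_amplitude(sin(2 * pi * t)), 2 / pi, tolerance = 0.01)
  expect_error(mean_amplitude(numeric(0)), class = "eegbci_bad_argument")
})

test_that("decompose recovers in-band sinusoid amplitudes", {
  bank <- filter_bank(100)
  t <- (0:999) / 100

  frame <- decompose(512 + 50 * sin(2 * pi * 10 * t), bank)
  expect_equal(unname(frame$amplitude["alpha"]), 50 * 2 / pi, tolerance = 0.1)
  expect_lt(frame$amplitude["delta"], 5)
  expect_lt(frame$amplitude["beta1"], 5)

  slow <- decompose(512 + 40 * sin(2 * pi * 2 * t), bank)
  expect_gt(slow$amplitude["delta"], 10)
  expect_lt(slow$amplitude["alpha"], 0.1 * slow$amplitude["delta"])

  flat <- decompose(rep(512, 1000), bank)
  expect_true(all(flat$amplitude == 0))
  expect_identical(flat$raw_amplitude, 0)

  # multi-component signal: each band amplitude within 15% of its analytic value
  multi <- 512 + 30 * sin(2 * pi * 10 * t) + 20 * sin(2 * pi * 2 * t) +
    15 * sin(2 * pi * 19 * t)
  mf <- decompose(multi, bank)
  expect_equal(unname(mf$amplitude["alpha"]), 30 * 2 / pi, tolerance = 0.15)
  expect_equal(unname(mf$amplitude["delta"]), 20 * 2 / pi, tolerance = 0.15)
  expect_equal(unname(mf$amplitude["beta1"]), 15 * 2 / pi, tolerance = 0.15)

  # determinism: identical windows give bit-identical frames
  set.seed(5)
  w <- 512 + rnorm(1000, sd = 20)
  expect_identical(decompose(w, bank), decompose(w, bank))

  expect_error(decompose(rb_push(ring_buffer(1000L), 1:10), bank),
               class = "eegbci_not_ready")
})

test_that("feature_vector exposes the five network inputs in order", {
  bank <- filter_bank(100)
  fv <- feature_vector(decompose(512 + rnorm(1000, sd = 10), bank))
  expect_identical(names(fv), c("alpha", "beta0", "beta1", "beta2", "delta"))
  expect_true(all(fv >= 0))
})

test_that("alpha_ratio scales by 1000 and handles the degenerate cases", {
  frame <- structure(
    list(filtered = list(), amplitude = c(alpha = 12), raw_amplitude = 12),
    class = "rhythm_frame"
  )
  expect_equal(alpha_ratio(frame), 1000)
  frame$amplitude["alpha"] <- 0
  expect_equal(alpha_ratio(frame), 0)
  frame$raw_amplitude <- 0
  expect_warning(r <- alpha_ratio(frame), "undefined")
  expect_true(is.na(r))
})

test_that("eyes-closed windows show a higher alpha ratio than eyes-open", {
  # Within a single window the waxing/waning of the rhythm makes the ratio
  # noisy, so each state is summarized by two windows per seed and a few
  # seed-level inversions are tolerated; the seed-averaged ratios must
  # separate cleanly.
  bank <- filter_bank(100)
  model <- preset("eo_ec_alpha")
  ratio_at <- function(stream, from) {
    alpha_ratio(decompose(stream$samples[from:(from + 999)], bank))
  }
  eo <- ec <- numeric(20)
  for (seed in 1:20) {
    stream <- generate_session(model, marker_schedule(40, 10), 100, seed = seed)
    eo[seed] <- mean(c(ratio_at(stream, 1), ratio_at(stream, 2001)))    # state 0
    ec[seed] <- mean(c(ratio_at(stream, 1001), ratio_at(stream, 3001))) # state 1
  }
  expect_gte(sum(ec > eo), 17)
  expect_gt(mean(ec), mean(eo))
})

test_that("filter coefficients export to CSV and read back", {
  path <- withr::local_tempfile(fileext = ".csv")
  bank <- filter_bank(100)
  write_filter_csv(bank, path)
  tab <- read.csv(path)
  expect_setequal(unique(tab$band), rhythm_bands(100)$name)
  expect_equal(tab$value[tab$band == "alpha"], bank$alpha$b)
})
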