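# Independent oracles used across the test files.

# Central-difference numerical gradient of scalar function f at theta.
num_grad <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

# Frequency-response oracle independent of filter_response(): signal::freqz
# evaluated at the requested frequencies in Hz.
freqz_mag <- function(spec, freq_hz) {
  # a scalar n would be read as a grid size, so always pass >= 2 frequencies
  f <- if (length(freq_hz) == 1L) rep(freq_hz, 2L) else freq_hz
  h <- signal::freqz(spec$b, spec$a, n = f, Fs = spec$sampling_rate_hz)
  Mod(h$h)[seq_along(freq_hz)]
}

# Naive "keep the last n of a list" reference for the ring buffer.
naive_last_n <- function(values, n) {
  if (length(values) <= n) values else values[(length(values) - n + 1L):length(values)]
}

# Straight-line forward pass oracle: explicit loops, no shared code with the
# package's matrix implementation.
oracle_forward <- function(net, x) {
  a <- as.numeric(x)
  for (l in seq_along(net$W)) {
    z <- numeric(nrow(net$W[[l]]))
    for (j in seq_len(nrow(net$W[[l]]))) {
      acc <- net$b[[l]][j]
      for (k in seq_len(ncol(net$W[[l]]))) acc <- acc + net$W[[l]][j, k] * a[k]
      z[j] <- acc
    }
    a <- if (net$activation == "sigmoid") 1 / (1 + exp(-z)) else z
  }
  a
}

# XOR truth table embedded in 5 inputs (2 informative, 3 zero).
xor5_data <- function() {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  list(X = cbind(X, matrix(0, 4, 3)), y = c(0, 1, 1, 0))
}

# A linearly separable AND-like set on all 16 sign patterns of the first
# four inputs: class 1 iff x1 + x2 > 1.5 (margin 0.5 around the plane).
and5_data <- function() {
  grid <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1, x4 = 0:1)
  X <- cbind(as.matrix(grid), 0)
  y <- as.integer(grid$x1 + grid$x2 > 1.5)
  list(X = unname(X), y = y)
}

# One synthetic session accuracy for a given trainer/preset/seed.
session_accuracy <- function(seed, algorithm = "levenberg_marquardt",
                             preset_name = "eo_ec_alpha", duration_s = 110,
                             interval_s = 10) {
  model <- preset(preset_name)
  markers <- marker_schedule(duration_s, interval_s)
  stream <- generate_session(model, markers, 100, seed = seed)
  cfg <- session_config(trainer = trainer_config(algorithm),
                       duration_s = duration_s, interval_s = interval_s,
                       seed = seed)
  accuracy(select_scoring_rows(run_session(stream, cfg)$log))
}
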