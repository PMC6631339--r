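# eegbci

A single-channel EEG brain–computer interface pipeline in R: stream 10-bit
ADC samples, decompose a rolling 10-second buffer into the clinical rhythm
bands, feed band amplitudes to a small sigmoid perceptron trained online with
one of four classic algorithms, and score the network's binary state
predictions against a timed auditory marker protocol. A seeded synthetic EEG
generator stands in for the amplifier/microcontroller hardware and the human
subject, so every experiment in the package is reproducible bit for bit.

The package is aimed at people studying minimal BCI designs: how much state
information (eyes open vs eyes closed, rest vs mental task) survives a
pipeline built from nothing but band-pass filters, time-domain amplitude
averages and a tiny perceptron.

## The pipeline

1. **Acquisition** — samples are integers in [0, 1023] at 100 Hz, from a
   replay file (one decimal per line), a self-synchronizing 2-byte serial
   frame stream, or the synthetic generator. A ring buffer keeps the most
   recent 1000 samples (10 s).
2. **Rhythms** — the buffer, after DC removal, passes through a band-pass
   filter bank: delta 0.5–3 Hz, alpha 8–13 Hz, beta0 13–16 Hz, beta1
   16–23 Hz, beta2 23–31 Hz, gamma 32–45 Hz (gamma is clipped below the
   50 Hz Nyquist limit and excluded from the feature vector). Filters are
   401-tap linear-phase windowed-sinc FIR by default, with a 4th-order
   Butterworth IIR alternative. Each band is summarized by the mean absolute
   value of the most recent second of steady-state filter output, in ADC
   counts; the alpha/raw amplitude ratio (×1000) is the classic eyes-closed
   reactivity index.
3. **Network** — a feature vector of the five amplitudes (alpha, beta0,
   beta1, beta2, delta), z-scored with statistics frozen from the warm-up,
   drives a sigmoid perceptron: 5-1 for the perceptron error-correction
   rule, 5-6-6-1 for backpropagation, Rprop and Levenberg–Marquardt. The
   output is thresholded at 0.5 into state 0/1.
4. **Protocol** — the marker state alternates every 10 s
   (`state(t) = floor(t/10) mod 2`; 1500 Hz tone cues state 0, 1000 Hz
   state 1). The first 60 s of a 110 s session accumulate (features, marker)
   pairs and train the network; the remaining 50 s log
   `time,marker,prediction` rows at 10 Hz.
5. **Evaluation** — drop the first 60 s and the last 10 s of the log, keep
   the centred 400 rows (40 s), and report the fraction of rows where the
   prediction matches the marker.

## Worked example

```r
library(eegbci)

model   <- preset("eo_ec_alpha")            # alpha doubles when eyes close
markers <- marker_schedule(110, 10)
stream  <- generate_session(model, markers, 100, seed = 1)
stream
#> <sample_stream> 11000 samples @ 100 Hz (110.00 s), t0 = 0 s

frame <- decompose(stream$samples[1:1000], filter_bank(100))
round(frame$amplitude, 2)
#> delta alpha beta0 beta1 beta2 gamma
#> 14.80 17.38 12.34  7.63  4.63  6.62
alpha_ratio(frame)
#> [1] 662.7491

cfg <- session_config(trainer = trainer_config("levenberg_marquardt"), seed = 1)
session <- run_session(stream, cfg)
session
#> <bci_session> levenberg_marquardt trainer, 500 logged rows, 110 s session
session$network
#> <eeg_network> structure 5-6-6-1, sigmoid activation, 85 parameters

rows <- select_scoring_rows(session$log)
accuracy(rows)
#> [1] 0.59
```

The first window's amplitudes are eyes-open (state 0): alpha ≈ 17 ADC counts.
After the 60 s warm-up the Levenberg–Marquardt-trained network labels each
0.1 s log tick; on this seed 59% of the 400 scored rows match the marker.
Averaged over seeds 1–10 the same configuration reaches ≈ 61% — comparable
to the accuracies reported for live-subject sessions with this design, where
the intrinsic ~2.5 s latency of a trailing amplitude window bounds what any
classifier can score against an instantaneous marker (see the methods
vignette).

## Command line

```sh
Rscript inst/cli/eegbci.R synth --preset eo_ec_alpha --duration 110 --seed 1 --out replay.txt
Rscript inst/cli/eegbci.R run   --replay replay.txt --algo lm --seed 1 --out session.csv
Rscript inst/cli/eegbci.R eval  --out results.csv session.csv
Rscript inst/cli/eegbci.R filters --mode fir --out coefficients.csv
```

Every output is accompanied by a `.manifest.json` recording the command,
seed and package version needed to re-run it identically. Exit codes: 0
success, 1 runtime failure, 2 usage error.

### Serial frame dialect

Each sample is two bytes: high byte `0x80 | (value >> 7)` (sync bit set),
low byte `value & 0x7F` (sync bit clear). Example: 612 = `0b1001100100`
travels as `0x84 0x64`. Because only high bytes carry the top bit, the
parser resynchronizes after any byte loss; a truncated trailing frame is
discarded and counted.

## Reference accuracies

`published_results()` returns the bundled table of per-session accuracies
reported for the original twelve-subject live-EEG study of this design
(four algorithms, 5 or 10 s beep intervals), for side-by-side comparison
with synthetic runs via `summarize_results()`. Live values are context, not
a target: human alpha reactivity is far noisier than the synthetic presets.
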