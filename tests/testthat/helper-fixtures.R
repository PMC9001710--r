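# Shared fixture builders. Everything is generated in code; no data files.

# Sinusoidal grating patch (zero mean). With `cpd * n / ppd` an integer the
# grating sits exactly on a DFT bin (no spectral leakage).
make_grating <- function(cpd, theta = 0, n = 80, ppd = 40, amplitude = 0.4,
                         phase = 0) {
  ax <- seq_len(n) - (n + 1) / 2
  xx <- matrix(ax, n, n, byrow = TRUE)
  yy <- matrix(ax, n, n)
  u <- xx * cos(theta) + yy * sin(theta)
  g <- amplitude * cos(2 * pi * cpd * u / ppd + phase)
  g - mean(g)
}

# Grating whose frequency sits exactly on the DFT bin (kx, ky) of an
# n x n patch (no spectral leakage even for oblique orientations).
make_grating_bin <- function(kx, ky, n = 80, amplitude = 0.4) {
  cc <- matrix(0:(n - 1), n, n, byrow = TRUE)
  rr <- matrix(0:(n - 1), n, n)
  g <- amplitude * cos(2 * pi * (kx * cc + ky * rr) / n)
  g - mean(g)
}

# Spike-like biphasic waveform template of `n` samples.
make_template <- function(n = 40, trough = 12, peak = 25, width = 18,
                          peak_amp = 0.35) {
  -exp(-((seq_len(n) - trough)^2) / width) +
    peak_amp * exp(-((seq_len(n) - peak)^2) / (3 * width))
}

# Spike times with an enforced refractory gap (no ISI violations).
make_clean_spike_times <- function(n, t_max = 100, min_gap = 0.005) {
  cumsum(stats::runif(n, min_gap, 2 * t_max / n))
}

# Regular triggers with enough spacing for a 1-s baseline + 3-s trial.
make_trial_table <- function(n_trials, period = 4.2, pre = 1.2, view = 3) {
  start <- (seq_len(n_trials) - 1) * period
  data.frame(trial = seq_len(n_trials), start = start,
             img_on = start + pre, img_off = start + pre + view)
}
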