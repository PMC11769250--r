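# Shared fixture builders: small synthetic specifications exercised by many
# tests. Everything is generated in code; no stored fixtures.

# two-channel, two-class spec with planted diagonal source variances
# (class a: diag(a1^2, a2^2), class b: diag(b1^2, b2^2)) and near-zero noise
diag_variance_spec <- function(a = c(2, 1), b = c(1, 1), snr_db = 60,
                               seed = 7) {
  synthetic_spec(n_eeg_channels = 2, n_eog_channels = 0,
                 classes = c("a", "b"),
                 mixing = list(diag(a), diag(b)),
                 rhythm_bands = list(c(9, 13), c(18, 24)),
                 snr_db = snr_db, seed = seed)
}

# small four-class IV-2a-like session spec
small_session_spec <- function(trials_per_class_per_run = 4,
                               runs_per_session = 2, snr_db = 5, seed = 1,
                               n_eog_channels = 3) {
  synthetic_spec(trials_per_class_per_run = trials_per_class_per_run,
                 runs_per_session = runs_per_session,
                 snr_db = snr_db, n_eog_channels = n_eog_channels,
                 seed = seed)
}

# the 22 EEG + 3 EOG montage labels of the IV-2a recording
iv2a_channel_labels <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C5", "C3", "C1", "Cz", "C2",
    "C4", "C6", "CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz", "P2", "POz",
    "EOG-left", "EOG-central", "EOG-right")
}

# FFT band-energy oracle: fraction of total power inside [low, high] Hz
fft_band_fraction <- function(x, fs, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= low & f <= high]) / sum(p)
}

# independent shape-propagation oracle for a branch: returns flatten length
# and total parameter count, written without touching the model code paths
oracle_branch_shapes <- function(n_conv, n_dense, n_filters, input_shape,
                                 dense_width = 32) {
  h <- input_shape[1]; w <- input_shape[2]; c <- 1
  params <- 0
  for (b in seq_len(n_conv)) {
    params <- params + 3 * 3 * c * n_filters + n_filters
    c <- n_filters
    if (h > 1 && w > 1) { h <- floor(h / 2); w <- floor(w / 2) }
    else w <- floor(w / 2)
    stopifnot(h >= 1, w >= 1)
  }
  flat <- h * w * c
  d_in <- flat
  for (b in seq_len(n_dense)) {
    params <- params + d_in * dense_width + dense_width
    d_in <- dense_width
  }
  list(flat = flat, out_width = d_in, params = params)
}
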