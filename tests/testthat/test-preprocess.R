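# frequency-response oracle: |H(f)|^2 of the designed Butterworth filter,
# evaluated by direct polynomial evaluation at z = exp(-2*pi*i*f/fs)
# (filtfilt applies the filter twice, hence the squared magnitude)
filtfilt_gain <- function(low, high, order, f, fs) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- exp(-2i * pi * f / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2
}

sine_recording <- function(f, fs = 250, n = 5000) {
  x <- sin(2 * pi * f * (0:(n - 1)) / fs)
  eeg_recording(matrix(x, 1), fs, "C3", "EEG",
                data.frame(onset = 0L, code = 0L))
}

test_that("DC is suppressed by the band-pass filter", {
  rec <- eeg_recording(matrix(1, 1, 2000), 250, "C3", "EEG",
                       data.frame(onset = 0L, code = 0L))
  out <- bandpass(rec, bandpass_spec())
  expect_lt(max(abs(out$signal)), 1e-3)
})

test_that("passband and stopband gains match the frequency-response oracle", {
  fs <- 250
  g15 <- filtfilt_gain(7, 30, 5, 15, fs)
  expect_lt(abs(g15 - 1), 0.05)          # 15 Hz sits in the passband
  g50 <- filtfilt_gain(7, 30, 5, 50, fs)
  expect_lt(10 * log10(g50), -20)        # 50 Hz attenuated by >= 20 dB

  # and the implementation reproduces the oracle empirically
  mid <- 1001:4000                       # trim filter edge transients
  out15 <- bandpass(sine_recording(15), bandpass_spec())
  rms_ratio <- sqrt(mean(out15$signal[1, mid]^2) / 0.5)
  expect_lt(abs(rms_ratio - sqrt(g15)), 0.05)
  out50 <- bandpass(sine_recording(50), bandpass_spec())
  att_db <- 10 * log10(mean(out50$signal[1, mid]^2) / 0.5)
  expect_lt(att_db, -20)
})

test_that("filtering is linear and preserves length and events", {
  set.seed(3)
  n <- 1500
  x <- matrix(rnorm(2 * n), 2); y <- matrix(rnorm(2 * n), 2)
  mk <- function(s) eeg_recording(s, 250, c("C3", "C4"), c("EEG", "EEG"),
                                  data.frame(onset = 7L, code = 2L))
  bp <- function(s) bandpass(mk(s), bandpass_spec())$signal
  lhs <- bp(2.5 * x - 1.3 * y)
  rhs <- 2.5 * bp(x) - 1.3 * bp(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
  out <- bandpass(mk(x), bandpass_spec())
  expect_equal(ncol(out$signal), n)
  expect_identical(out$events, mk(x)$events)
  expect_error(bandpass(mk(x), bandpass_spec(high_hz = 130)), "Nyquist")
})

test_that("drop_eog keeps exactly the EEG channels in order", {
  rec <- simulate_recording(small_session_spec(1, 1))
  out <- drop_eog(rec)
  expect_equal(nrow(out$signal), 22)
  expect_identical(out$channel_labels,
                   rec$channel_labels[rec$channel_kinds == "EEG"])
  expect_identical(drop_eog(out), out)      # no EOG channels: identity
  all_eog <- eeg_recording(matrix(0, 2, 10), 250, c("E1", "E2"),
                           c("EOG", "EOG"))
  expect_error(drop_eog(all_eog), "no EEG")
})

test_that("cue-locked extraction slices [onset+2s, onset+6s) per event", {
  fs <- 250
  sig <- matrix(seq_len(2 * 3000), 2, byrow = TRUE)
  rec <- eeg_recording(sig, fs, c("C3", "C4"), c("EEG", "EEG"),
                       data.frame(onset = c(0L, 1200L), code = c(1L, 2L)))
  ep <- extract_trials(rec, 2, 6)
  expect_equal(dim(ep$data), c(2, 2, 1000))
  expect_equal(ep$labels, c(1L, 2L))
  # event at onset 0 with start 2 s: epoch starts at sample 500 (0-based)
  expect_equal(ep$data[1, 1, 1], sig[1, 501])
  expect_equal(ep$provenance$offset_sample, c(500L, 500L))
})

test_that("trials running past the signal end are dropped with a warning", {
  rec <- eeg_recording(matrix(0, 1, 2000), 250, "C3", "EEG",
                       data.frame(onset = c(0L, 600L), code = c(0L, 1L)))
  expect_warning(ep <- extract_trials(rec, 2, 6), "dropped")
  expect_equal(n_epochs(ep), 1)
  rec2 <- eeg_recording(matrix(0, 1, 900), 250, "C3", "EEG",
                        data.frame(onset = 0L, code = 0L))
  expect_error(suppressWarnings(extract_trials(rec2, 2, 6)), "all trials")
})

test_that("sliding windows follow the floor((T-W)/S)+1 count", {
  mk_ep <- function(T) epoch_set(array(seq_len(T), c(1, 1, T)), 0L, 250)
  # 1000 samples, 2 s window, 50% overlap: 3 windows
  w <- slide_windows(mk_ep(1000), window_spec(2, 0.5))
  expect_equal(n_epochs(w), 3)
  expect_equal(w$provenance$offset_sample, c(0L, 250L, 500L))
  # exact fit: one window
  expect_equal(n_epochs(slide_windows(mk_ep(500), window_spec(2, 0.5))), 1)
  # 1250 samples: 4 windows, last starting at sample 750
  w4 <- slide_windows(mk_ep(1250), window_spec(2, 0.5))
  expect_equal(n_epochs(w4), 4)
  expect_equal(max(w4$provenance$offset_sample), 750L)
  expect_equal(w4$data[4, 1, 1], 751)
  expect_error(slide_windows(mk_ep(400), window_spec(2, 0.5)), "longer")
})

test_that("window counts match brute-force enumeration of start offsets", {
  set.seed(99)
  fs <- 100
  for (i in 1:1000) {
    T <- sample(50:400, 1)
    W <- sample(10:T, 1)
    ov <- runif(1, 0, 0.9)
    S <- max(1, round(W * (1 - ov)))
    brute <- sum(seq(0, T, by = S) + W <= T)
    ep <- epoch_set(array(0, c(1, 1, T)), 0L, fs)
    got <- n_epochs(slide_windows(ep, window_spec(W / fs, ov)))
    expect_equal(got, brute)
  }
})

test_that("per-window standardization zeroes means and unitizes variances", {
  ep <- make_separable_epochs(diag_variance_spec(), 3)
  st <- standardize_windows(ep)
  for (i in 1:2) {
    x <- st$data[i, , ]
    expect_lt(max(abs(rowMeans(x))), 1e-10)
    pop_sd <- sqrt(rowMeans((x - rowMeans(x))^2))
    expect_equal(unname(pop_sd), rep(1, nrow(x)), tolerance = 1e-10)
  }
})
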