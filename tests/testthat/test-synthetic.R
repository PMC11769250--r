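test_that("session schedule is balanced, ordered by run, and seeded", {
  spec <- small_session_spec(trials_per_class_per_run = 3, runs_per_session = 2)
  sched <- session_schedule(spec)
  expect_equal(nrow(sched), 3 * 4 * 2)
  expect_equal(as.vector(table(sched$class_code)), rep(6L, 4))
  # balance holds within every run, not just overall
  for (r in unique(sched$run))
    expect_equal(as.vector(table(sched$class_code[sched$run == r])),
                 rep(3L, 4))
  # onsets are consecutive trial slots
  expect_equal(sched$onset, (seq_len(nrow(sched)) - 1L) *
                 round(spec$trial_length_s * spec$fs))
  expect_identical(sched, session_schedule(spec))
})

test_that("full-protocol scheduler yields 288 trials per class", {
  sched <- session_schedule(synthetic_spec())
  expect_equal(as.vector(table(sched$class_code)), rep(288L, 4))
})

test_that("simulated recordings are deterministic and carry one event per trial", {
  spec <- small_session_spec(seed = 42)
  rec <- simulate_recording(spec)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$signal), 25)
  expect_equal(as.vector(table(rec$events$code)), rep(8L, 4))
  expect_identical(rec, simulate_recording(spec))
  # different seed changes the signal
  rec2 <- simulate_recording(small_session_spec(seed = 43))
  expect_false(identical(rec$signal, rec2$signal))
})

test_that("near-noiseless MI-segment covariance matches the planted mixing", {
  spec <- small_session_spec(snr_db = 60, n_eog_channels = 0, seed = 5)
  rec <- simulate_recording(spec)
  a <- round(spec$cue_onset_s * spec$fs); b <- round(spec$mi_end_s * spec$fs)
  for (cl in 0:3) {
    onsets <- rec$events$onset[rec$events$code == cl]
    # independent brute-force covariance accumulation over MI segments
    X <- do.call(cbind, lapply(onsets, function(o)
      rec$signal[, (o + a + 1):(o + b), drop = FALSE]))
    X <- X - rowMeans(X)
    C <- tcrossprod(X) / ncol(X)
    A <- spec$mixing[[cl + 1]]
    Tgt <- A %*% t(A)
    C <- C / sum(diag(C)); Tgt <- Tgt / sum(diag(Tgt))
    expect_lt(norm(C - Tgt, "F") / norm(Tgt, "F"), 0.05)
  }
})

test_that("MI-segment power concentrates inside the configured rhythm bands", {
  spec <- small_session_spec(snr_db = 80, n_eog_channels = 0, seed = 2)
  rec <- simulate_recording(spec)
  a <- round(spec$cue_onset_s * spec$fs); b <- round(spec$mi_end_s * spec$fs)
  o <- rec$events$onset[1]
  seg <- rec$signal[, (o + a + 1):(o + b)]
  ch <- which.max(rowSums(seg^2))       # a channel the mixing projects onto
  frac <- fft_band_fraction(seg[ch, ], spec$fs, 9, 13) +
    fft_band_fraction(seg[ch, ], spec$fs, 18, 24)
  expect_gt(frac, 0.9)
})

test_that("make_separable_epochs counts, balances and reproduces", {
  spec <- small_session_spec(seed = 4)
  ep <- make_separable_epochs(spec, 10)
  expect_equal(n_epochs(ep), 40)
  expect_equal(as.vector(table(ep$labels)), rep(10L, 4))
  expect_equal(dim(ep$data)[2], 22)
  expect_identical(ep, make_separable_epochs(spec, 10))
  expect_error(make_separable_epochs(spec, 0), "n_per_class")
})

test_that("invalid specifications are rejected naming the offending field", {
  expect_error(synthetic_spec(cue_onset_s = 6, mi_end_s = 2), "cue_onset_s")
  expect_error(synthetic_spec(mi_end_s = 9, trial_length_s = 7.5), "mi_end_s")
  expect_error(synthetic_spec(rhythm_bands = list(c(9, 300))), "rhythm_bands")
  expect_error(synthetic_spec(trials_per_class_per_run = 0),
               "trials_per_class_per_run")
  expect_error(synthetic_spec(mixing = list(diag(22)[, 1:2])), "mixing")
  # coinciding class patterns violate the pairwise-distinct invariant
  A <- matrix(stats::rnorm(44), 22, 2)
  expect_error(synthetic_spec(classes = c("a", "b"),
                              mixing = list(A, A)), "mixing")
})
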