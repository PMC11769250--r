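#' Band-pass filter specification
#'
#' Defaults to the 7-30 Hz band that covers the sensorimotor mu (~8-13 Hz)
#' and beta (~13-30 Hz) rhythms, realized as a Butterworth filter applied
#' forward-backward (zero phase) so event alignment is preserved.
#'
#' @param low_hz lower band edge in Hz (default 7).
#' @param high_hz upper band edge in Hz (default 30).
#' @param order Butterworth order (default 5).
#' @param zero_phase apply forward-backward (`filtfilt`) if `TRUE` (default);
#'   single-pass causal filtering otherwise.
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 7, high_hz = 30, order = 5L,
                          zero_phase = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("invalid band: need 0 < low_hz < high_hz", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)), class = "bandpass_spec")
}

#' Band-pass filter every channel of a recording
#'
#' @param recording an [eeg_recording()].
#' @param spec a [bandpass_spec()]; band edges must lie below the Nyquist
#'   frequency of the recording.
#' @return A filtered [eeg_recording()] of identical shape; events unchanged.
#' @export
bandpass <- function(recording, spec = bandpass_spec()) {
  recording <- validate_recording(recording)
  if (spec$high_hz >= recording$fs / 2)
    stop("band edge ", spec$high_hz, " Hz is not below Nyquist (",
         recording$fs / 2, " Hz)", call. = FALSE)
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / (recording$fs / 2),
                       type = "pass")
  # odd-symmetric reflection padding long enough for the slowest pole to
  # settle, so the forward-backward pass is transient-free at the edges
  n <- ncol(recording$signal)
  pad <- min(n - 1L, ceiling(9 * recording$fs / spec$low_hz))
  out <- recording
  for (ch in seq_len(nrow(recording$signal))) {
    x <- recording$signal[ch, ]
    if (spec$zero_phase) {
      xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      y <- signal::filtfilt(bf, xp)
      out$signal[ch, ] <- y[pad + seq_len(n)]
    } else {
      out$signal[ch, ] <- as.numeric(signal::filter(bf, x))
    }
  }
  out
}

#' Drop EOG channels, keeping EEG channels in order
#'
#' @param recording an [eeg_recording()] with `channel_kinds` populated.
#' @return The recording restricted to its EEG channels.
#' @export
drop_eog <- function(recording) {
  recording <- validate_recording(recording)
  keep <- recording$channel_kinds == "EEG"
  if (!any(keep)) stop("recording has no EEG channels", call. = FALSE)
  out <- recording
  out$signal <- recording$signal[keep, , drop = FALSE]
  out$channel_labels <- recording$channel_labels[keep]
  out$channel_kinds <- recording$channel_kinds[keep]
  out
}

#' Extract cue-locked trials from a continuous recording
#'
#' Cuts one epoch per class-coded event, covering samples
#' `[onset + start_s*fs, onset + end_s*fs)` — by default the 2-6 s imagery
#' period following the trial start. Trials whose segment would run past the
#' end of the signal are dropped with a warning.
#'
#' @param recording an [eeg_recording()] whose events carry class codes 0..3.
#' @param start_s segment start relative to the event onset, seconds (default 2).
#' @param end_s segment end (exclusive), seconds (default 6).
#' @return An [epoch_set()] with one epoch per retained event; provenance
#'   records the 0-based event index as `trial_id`.
#' @export
extract_trials <- function(recording, start_s = 2, end_s = 6) {
  recording <- validate_recording(recording)
  if (!(start_s < end_s)) stop("need start_s < end_s", call. = FALSE)
  ev <- recording$events
  ev <- ev[ev$code %in% 0:3, , drop = FALSE]
  if (nrow(ev) == 0) stop("recording has no class-coded events", call. = FALSE)
  fs <- recording$fs
  a <- round(start_s * fs); b <- round(end_s * fs)
  len <- b - a
  ns <- ncol(recording$signal)
  starts <- ev$onset + a
  ok <- starts >= 0 & (starts + len) <= ns
  if (!all(ok))
    warning(sum(!ok), " trial(s) dropped: segment exceeds signal bounds",
            call. = FALSE)
  if (!any(ok)) stop("all trials dropped: no segment fits the signal", call. = FALSE)
  idx <- which(ok)
  dat <- array(0, c(length(idx), nrow(recording$signal), len))
  for (i in seq_along(idx))
    dat[i, , ] <- recording$signal[, starts[idx[i]] + seq_len(len), drop = FALSE]
  epoch_set(dat, ev$code[idx], fs,
            data.frame(trial_id = idx - 1L, offset_sample = rep(a, length(idx))),
            channel_labels = recording$channel_labels)
}

#' Sliding-window specification
#'
#' Defaults to the 2 s window with 50 % overlap used to segment the imagery
#' period.
#'
#' @param length_s window length in seconds (default 2).
#' @param overlap_frac overlap fraction in `[0, 1)` (default 0.5).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 2, overlap_frac = 0.5) {
  if (!(length_s > 0)) stop("`length_s` must be positive", call. = FALSE)
  if (!(overlap_frac >= 0 && overlap_frac < 1))
    stop("`overlap_frac` must lie in [0, 1)", call. = FALSE)
  structure(list(length_s = length_s, overlap_frac = overlap_frac),
            class = "window_spec")
}

#' Segment epochs into overlapping sliding windows
#'
#' Each input epoch of `T` samples yields `floor((T - W) / S) + 1` windows of
#' `W = length_s * fs` samples at step `S = W * (1 - overlap_frac)`; windows
#' that would extend past the epoch end are discarded (no padding). Labels
#' are inherited; provenance offsets accumulate.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [window_spec()]; the window must not exceed the epoch length.
#' @return An [epoch_set()] of windows.
#' @export
slide_windows <- function(epochs, spec = window_spec()) {
  epochs <- validate_epoch_set(epochs)
  d <- dim(epochs$data)
  W <- round(spec$length_s * epochs$fs)
  S <- max(1L, round(W * (1 - spec$overlap_frac)))
  if (W > d[3L])
    stop("window (", W, " samples) longer than epoch (", d[3L], ")", call. = FALSE)
  starts <- seq(0L, d[3L] - W, by = S)      # 0-based window offsets
  n_out <- d[1L] * length(starts)
  dat <- array(0, c(n_out, d[2L], W))
  labels <- integer(n_out); trial_id <- integer(n_out); off <- integer(n_out)
  k <- 0L
  for (i in seq_len(d[1L])) {
    for (s0 in starts) {
      k <- k + 1L
      dat[k, , ] <- epochs$data[i, , s0 + seq_len(W)]
      labels[k] <- epochs$labels[i]
      trial_id[k] <- epochs$provenance$trial_id[i]
      off[k] <- epochs$provenance$offset_sample[i] + s0
    }
  }
  epoch_set(dat, labels, epochs$fs,
            data.frame(trial_id = trial_id, offset_sample = off),
            channel_labels = epochs$channel_labels)
}

#' Per-window channel-wise standardization
#'
#' Subtracts each channel's mean and divides by its standard deviation
#' within every window (guard `eps` against flat channels). A simple
#' normalization that removes per-window offset and gross scale.
#'
#' @param epochs an [epoch_set()].
#' @param eps variance floor (default 1e-8).
#' @return The standardized [epoch_set()].
#' @export
standardize_windows <- function(epochs, eps = 1e-8) {
  epochs <- validate_epoch_set(epochs)
  d <- dim(epochs$data)
  for (i in seq_len(d[1L])) {
    x <- epochs$data[i, , , drop = TRUE]
    if (d[2L] == 1L) x <- matrix(x, 1L)
    m <- rowMeans(x)
    s <- sqrt(pmax(rowMeans((x - m)^2), eps))
    epochs$data[i, , ] <- (x - m) / s
  }
  epochs
}
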