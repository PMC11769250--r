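#' Continuous multichannel EEG recording
#'
#' Bundles a channels-by-samples signal matrix (microvolts) with its sampling
#' rate, per-channel metadata and an event table. Sample indices are 0-based
#' throughout the package and windows are half-open `[start, stop)`.
#'
#' @param signal numeric matrix, `n_channels x n_samples`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of channel names, one per row of
#'   `signal`.
#' @param channel_kinds character vector with entries `"EEG"` or `"EOG"`,
#'   aligned with `channel_labels`.
#' @param events data frame with columns `onset` (0-based sample index of the
#'   trial start) and `code` (class code 0..3 for cue events, or a raw
#'   protocol code). May have zero rows.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels, channel_kinds,
                          events = data.frame(onset = integer(), code = integer())) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)", call. = FALSE)
  rec <- structure(list(
    signal = signal, fs = as.numeric(fs),
    channel_labels = as.character(channel_labels),
    channel_kinds = as.character(channel_kinds),
    events = as.data.frame(events)
  ), class = "eeg_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  nch <- nrow(rec$signal); ns <- ncol(rec$signal)
  if (length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0)
    stop("`fs` must be a positive scalar", call. = FALSE)
  if (length(rec$channel_labels) != nch)
    stop("`channel_labels` length (", length(rec$channel_labels),
         ") does not match channel count (", nch, ")", call. = FALSE)
  if (length(rec$channel_kinds) != nch)
    stop("`channel_kinds` length (", length(rec$channel_kinds),
         ") does not match channel count (", nch, ")", call. = FALSE)
  if (!all(rec$channel_kinds %in% c("EEG", "EOG")))
    stop("`channel_kinds` entries must be \"EEG\" or \"EOG\"", call. = FALSE)
  if (!all(c("onset", "code") %in% names(rec$events)))
    stop("`events` must have columns `onset` and `code`", call. = FALSE)
  if (nrow(rec$events) > 0 &&
      (any(rec$events$onset < 0) || any(rec$events$onset >= ns)))
    stop("`events$onset` must lie in [0, n_samples)", call. = FALSE)
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels (%d EEG, %d EOG) x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), sum(x$channel_kinds == "EEG"),
              sum(x$channel_kinds == "EOG"), ncol(x$signal), x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Stacked EEG epochs with labels and provenance
#'
#' @param data numeric array `n_epochs x n_channels x n_samples`.
#' @param labels integer vector of class codes in `{0,1,2,3}`, one per epoch.
#' @param fs sampling rate in Hz.
#' @param provenance data frame with columns `trial_id` and `offset_sample`
#'   (0-based offset of the epoch within its trial), one row per epoch.
#'   Defaults to identity bookkeeping.
#' @param channel_labels optional character vector of channel names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, provenance = NULL, channel_labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (epochs x channels x samples)", call. = FALSE)
  n <- dim(data)[1L]
  if (is.null(provenance))
    provenance <- data.frame(trial_id = seq_len(n) - 1L,
                             offset_sample = rep(0L, n))
  es <- structure(list(
    data = data, labels = as.integer(labels), fs = as.numeric(fs),
    provenance = as.data.frame(provenance),
    channel_labels = channel_labels
  ), class = "epoch_set")
  validate_epoch_set(es)
}

validate_epoch_set <- function(es) {
  n <- dim(es$data)[1L]
  if (length(es$labels) != n)
    stop("`labels` length (", length(es$labels),
         ") does not match epoch count (", n, ")", call. = FALSE)
  if (n > 0 && !all(es$labels %in% 0:3))
    stop("`labels` must lie in {0,1,2,3}", call. = FALSE)
  if (length(es$fs) != 1L || !is.finite(es$fs) || es$fs <= 0)
    stop("`fs` must be a positive scalar", call. = FALSE)
  if (!all(c("trial_id", "offset_sample") %in% names(es$provenance)))
    stop("`provenance` must have columns `trial_id` and `offset_sample`",
         call. = FALSE)
  if (nrow(es$provenance) != n)
    stop("`provenance` rows (", nrow(es$provenance),
         ") do not match epoch count (", n, ")", call. = FALSE)
  if (!is.null(es$channel_labels) && length(es$channel_labels) != dim(es$data)[2L])
    stop("`channel_labels` length does not match channel count", call. = FALSE)
  es
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  if (d[1L] > 0) {
    tb <- table(factor(x$labels, levels = 0:3))
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es an `epoch_set`.
#' @return integer count.
#' @export
n_epochs <- function(es) dim(es$data)[1L]

# subset an epoch_set by epoch index (1-based), keeping bookkeeping aligned
epoch_subset <- function(es, idx) {
  epoch_set(es$data[idx, , , drop = FALSE], es$labels[idx], es$fs,
            es$provenance[idx, , drop = FALSE], es$channel_labels)
}
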