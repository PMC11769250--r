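#' Specification for a synthetic motor-imagery EEG session
#'
#' Describes a simulated recording session that follows the BCI Competition
#' IV-2a protocol: 22 EEG + 3 EOG channels sampled at 250 Hz, four
#' motor-imagery classes (left-hand, right-hand, feet, tongue), cue at
#' t = 2 s, imagery until t = 6 s, 48 trials per class per run and 6 runs
#' per session. Class identity is planted as a class-specific spatial mixing
#' of band-limited oscillatory sources — the statistical structure CSP
#' assumes — on top of broadband 1/f + white noise and low-frequency EOG
#' artifacts.
#'
#' @param n_eeg_channels number of EEG channels (default 22).
#' @param n_eog_channels number of EOG channels (default 3).
#' @param fs sampling rate in Hz (default 250).
#' @param classes ordered class labels (default the four MI tasks).
#' @param mixing list with one `n_eeg_channels x n_sources` spatial pattern
#'   matrix per class; `NULL` builds distinct smooth default patterns.
#' @param rhythm_bands list of `c(low, high)` Hz per source (default one mu
#'   and one beta band); all bands must lie inside `(0, fs/2)`.
#' @param snr_db signal-to-noise ratio in dB, defined over the motor-imagery
#'   segment on EEG channels only (default 5).
#' @param trials_per_class_per_run trials of each class in one run (default 48).
#' @param runs_per_session runs per session (default 6).
#' @param trial_length_s total trial length in seconds, inter-trial gap
#'   included (default 7.5).
#' @param cue_onset_s cue time within the trial in seconds (default 2).
#' @param mi_end_s end of the imagery period in seconds (default 6).
#' @param seed integer RNG seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_eeg_channels = 22L, n_eog_channels = 3L,
                           fs = 250, classes = c("left-hand", "right-hand",
                                                 "feet", "tongue"),
                           mixing = NULL, rhythm_bands = list(c(9, 13), c(18, 24)),
                           snr_db = 5, trials_per_class_per_run = 48L,
                           runs_per_session = 6L, trial_length_s = 7.5,
                           cue_onset_s = 2, mi_end_s = 6, seed = 1L) {
  if (is.null(mixing))
    mixing <- default_mixing(n_eeg_channels, length(classes),
                             length(rhythm_bands))
  spec <- structure(list(
    n_eeg_channels = as.integer(n_eeg_channels),
    n_eog_channels = as.integer(n_eog_channels),
    fs = as.numeric(fs), classes = as.character(classes), mixing = mixing,
    rhythm_bands = rhythm_bands, snr_db = as.numeric(snr_db),
    trials_per_class_per_run = as.integer(trials_per_class_per_run),
    runs_per_session = as.integer(runs_per_session),
    trial_length_s = as.numeric(trial_length_s),
    cue_onset_s = as.numeric(cue_onset_s), mi_end_s = as.numeric(mi_end_s),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid `", field, "`: ", why, call. = FALSE)
  chk(spec$n_eeg_channels >= 1, "n_eeg_channels", "need at least one EEG channel")
  chk(spec$n_eog_channels >= 0, "n_eog_channels", "must be non-negative")
  chk(is.finite(spec$fs) && spec$fs > 0, "fs", "must be positive")
  nc <- length(spec$classes)
  chk(nc >= 2, "classes", "need at least two classes")
  chk(nc <= 4, "classes", "at most four classes (codes 0..3)")
  chk(is.list(spec$mixing) && length(spec$mixing) == nc, "mixing",
      "need one pattern matrix per class")
  nsrc <- length(spec$rhythm_bands)
  for (i in seq_len(nc)) {
    A <- spec$mixing[[i]]
    chk(is.matrix(A) && nrow(A) == spec$n_eeg_channels, "mixing",
        sprintf("matrix %d must have n_eeg_channels rows", i))
    chk(ncol(A) == nsrc, "mixing",
        sprintf("matrix %d must have one column per rhythm band", i))
  }
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      if (j > i) chk(sqrt(sum((spec$mixing[[i]] - spec$mixing[[j]])^2)) > 0,
                     "mixing", sprintf("patterns for classes %d and %d coincide", i, j))
  for (b in spec$rhythm_bands) {
    chk(length(b) == 2 && b[1] < b[2], "rhythm_bands",
        "each band must be c(low, high) with low < high")
    chk(b[1] > 0 && b[2] < spec$fs / 2, "rhythm_bands",
        "bands must lie inside (0, fs/2)")
  }
  chk(spec$trials_per_class_per_run >= 1, "trials_per_class_per_run", "must be >= 1")
  chk(spec$runs_per_session >= 1, "runs_per_session", "must be >= 1")
  chk(spec$cue_onset_s < spec$mi_end_s, "cue_onset_s", "must precede mi_end_s")
  chk(spec$mi_end_s <= spec$trial_length_s, "mi_end_s",
      "must not exceed trial_length_s")
  chk(spec$cue_onset_s >= 0, "cue_onset_s", "must be non-negative")
  spec
}

# Smooth, class-distinct spatial patterns: Gaussian bumps over the channel
# axis with centers spread so that no two classes share a pattern.
default_mixing <- function(n_channels, n_classes, n_sources) {
  idx <- seq_len(n_channels)
  lapply(seq_len(n_classes), function(c) {
    A <- sapply(seq_len(n_sources), function(s) {
      center <- ((c - 1) * n_sources + s - 0.5) / (n_classes * n_sources) *
        n_channels + 0.5
      exp(-(idx - center)^2 / (2 * 2^2))
    })
    matrix(A, nrow = n_channels)
  })
}

#' Balanced, seeded class schedule for one synthetic session
#'
#' Lays out the cue order of a full session: within each run every class
#' appears exactly `trials_per_class_per_run` times in a seeded random
#' permutation, mirroring the randomized cue order of the IV-2a protocol.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame with one row per trial: `trial_id` (0-based), `run`
#'   (1-based), `class_code` (0-based), `onset` (0-based sample index of the
#'   trial start).
#' @export
session_schedule <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  with_preserved_rng({
    set.seed(spec$seed)
    n_classes <- length(spec$classes)
    per_run <- spec$trials_per_class_per_run * n_classes
    codes <- unlist(lapply(seq_len(spec$runs_per_session), function(r)
      sample(rep(seq_len(n_classes) - 1L, spec$trials_per_class_per_run))))
    n_trial_samples <- round(spec$trial_length_s * spec$fs)
    data.frame(
      trial_id = seq_along(codes) - 1L,
      run = rep(seq_len(spec$runs_per_session), each = per_run),
      class_code = as.integer(codes),
      onset = (seq_along(codes) - 1L) * n_trial_samples
    )
  })
}

# run code with the caller's RNG state untouched
with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

# Unit-variance noise whose spectrum is confined to [low, high] Hz, built by
# masking the DFT of white noise. Exact band limitation makes the spectral
# placement of planted rhythms verifiable by FFT integration.
bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  mask <- f >= band[1] & f <= band[2]
  if (!any(mask)) stop("band too narrow for series length", call. = FALSE)
  X <- stats::fft(x) * mask
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band-limited series", call. = FALSE)
  y / s
}

# 1/f-shaped ("pink") unit-variance noise via DFT amplitude shaping
pink_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  amp <- ifelse(f <= 0, 0, 1 / sqrt(f))
  y <- Re(stats::fft(stats::fft(x) * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate one synthetic motor-imagery EEG session
#'
#' Assembles the full continuous recording of one session: trials are laid
#' out back-to-back in run order per [session_schedule()]; during each
#' trial's imagery period `[cue_onset_s, mi_end_s)` the class-specific
#' spatial mixture of band-limited oscillatory sources is active; broadband
#' noise (white + 1/f in equal power) is scaled so the EEG-channel
#' signal-to-noise ratio over imagery segments equals `snr_db`; EOG channels
#' carry a 0.1-4 Hz smoothed random walk that leaks with small fixed
#' coefficients into the frontal EEG rows.
#'
#' @param spec a [synthetic_spec()].
#' @return An [eeg_recording()] with one event per trial
#'   (`onset` = trial start sample, `code` = 0-based class code).
#' @export
simulate_recording <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  sched <- session_schedule(spec)
  with_preserved_rng({
    set.seed(spec$seed + 1L)               # schedule consumed seed itself
    fs <- spec$fs
    n_trial <- round(spec$trial_length_s * fs)
    n_total <- nrow(sched) * n_trial
    n_eeg <- spec$n_eeg_channels
    n_ch <- n_eeg + spec$n_eog_channels
    mi_a <- round(spec$cue_onset_s * fs)   # 0-based offsets within trial
    mi_b <- round(spec$mi_end_s * fs)
    mi_len <- mi_b - mi_a
    n_src <- length(spec$rhythm_bands)

    signal <- matrix(0, n_ch, n_total)
    for (t in seq_len(nrow(sched))) {
      A <- spec$mixing[[sched$class_code[t] + 1L]]
      S <- matrix(0, n_src, mi_len)
      for (s in seq_len(n_src))
        S[s, ] <- bandlimited_noise(mi_len, fs, spec$rhythm_bands[[s]])
      cols <- sched$onset[t] + mi_a + seq_len(mi_len)
      signal[seq_len(n_eeg), cols] <- signal[seq_len(n_eeg), cols] + A %*% S
    }

    mi_cols <- unlist(lapply(sched$onset, function(o) o + mi_a + seq_len(mi_len)))
    p_sig <- mean(signal[seq_len(n_eeg), mi_cols]^2)

    # white + pink in equal power, per EEG channel, scaled to snr_db
    noise <- matrix(0, n_eeg, n_total)
    for (ch in seq_len(n_eeg))
      noise[ch, ] <- (stats::rnorm(n_total) + pink_noise(n_total, fs)) / sqrt(2)
    p_noise <- mean(noise[, mi_cols]^2)
    scale <- sqrt(p_sig / (p_noise * 10^(spec$snr_db / 10)))
    signal[seq_len(n_eeg), ] <- signal[seq_len(n_eeg), ] + scale * noise

    if (spec$n_eog_channels > 0) {
      eog_amp <- 3 * max(scale, sqrt(p_sig))
      leak <- c(0.12, 0.09, 0.06, 0.04, 0.03)
      for (e in seq_len(spec$n_eog_channels)) {
        drift <- bandlimited_noise(n_total, fs, c(0.1, 4)) * eog_amp
        signal[n_eeg + e, ] <- drift
        rows <- seq_len(min(length(leak), n_eeg))
        signal[rows, ] <- signal[rows, ] + outer(leak[rows], drift)
      }
    }

    labels <- c(paste0("EEG", sprintf("%02d", seq_len(n_eeg))),
                if (spec$n_eog_channels > 0)
                  paste0("EOG", seq_len(spec$n_eog_channels)))
    eeg_recording(signal, fs, labels,
                  c(rep("EEG", n_eeg), rep("EOG", spec$n_eog_channels)),
                  data.frame(onset = sched$onset, code = sched$class_code))
  })
}

#' Directly generate windowed, class-separable epochs
#'
#' Shortcut generator for unit tests and feature-level experiments: returns
#' EEG-only epochs carrying the planted class-specific spatial mixture for
#' their whole duration (no continuous assembly, no EOG, no cue timing),
#' with balanced labels.
#'
#' @param spec a [synthetic_spec()]; `snr_db`, `mixing`, `rhythm_bands`,
#'   `classes`, `fs` and `seed` are honoured.
#' @param n_per_class epochs per class (>= 1).
#' @param epoch_length_s epoch duration in seconds (default 2).
#' @return An [epoch_set()] with `n_per_class * length(classes)` epochs.
#' @export
make_separable_epochs <- function(spec, n_per_class, epoch_length_s = 2) {
  spec <- validate_synthetic_spec(spec)
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  with_preserved_rng({
    set.seed(spec$seed)
    fs <- spec$fs
    n_classes <- length(spec$classes)
    n_src <- length(spec$rhythm_bands)
    len <- round(epoch_length_s * fs)
    n <- n_per_class * n_classes
    labels <- rep(seq_len(n_classes) - 1L, n_per_class)
    dat <- array(0, c(n, spec$n_eeg_channels, len))
    noise_scale <- NULL
    for (i in seq_len(n)) {
      A <- spec$mixing[[labels[i] + 1L]]
      S <- matrix(0, n_src, len)
      for (s in seq_len(n_src))
        S[s, ] <- bandlimited_noise(len, fs, spec$rhythm_bands[[s]])
      x <- A %*% S
      if (is.null(noise_scale)) {
        # one scale for the whole set, anchored to mean planted power
        p_sig <- mean(sapply(seq_len(n_classes), function(c)
          sum(spec$mixing[[c]]^2) / spec$n_eeg_channels))
        noise_scale <- sqrt(p_sig / 10^(spec$snr_db / 10))
      }
      nz <- (matrix(stats::rnorm(length(x)), nrow(x)) +
               t(sapply(seq_len(nrow(x)), function(ch) pink_noise(len, fs)))) /
        sqrt(2)
      dat[i, , ] <- x + noise_scale * nz
    }
    epoch_set(dat, labels, fs,
              data.frame(trial_id = seq_len(n) - 1L, offset_sample = 0L))
  })
}
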