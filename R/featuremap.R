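# Assembly of the 2-D feature maps fed to the convolutional branches.
#
# Per window the map stacks, as rows:
#   1..K     the K CSP-filtered time courses (optionally block-averaged down
#            to fewer columns), and
#   K+1..K+B the log short-time energies of the B selected wavelet packet
#            bands (0.25 s sub-frames, channel-averaged, linearly resampled
#            to the same number of columns).
# Rows are standardized with statistics estimated on the TRAINING set and
# frozen in a scaler, so between-epoch amplitude differences — the very
# signal CSP extracts — survive standardization.

#' Build 2-D feature maps from CSP and wavelet packet features
#'
#' @param epochs an [epoch_set()] of windows.
#' @param csp a fitted [csp_fit()] model.
#' @param wpd a [wpd_spec()], or `NULL` for a CSP-only map.
#' @param time_decim integer block length for averaging the CSP time courses
#'   down to `floor(T / time_decim)` columns (default 1 = no decimation).
#' @param subframe_s sub-frame length for the band-energy envelopes,
#'   seconds (default 0.25).
#' @param scaler per-row standardization statistics from a previous
#'   (training-set) call; `NULL` estimates them from `epochs`.
#' @return An object of class `feature_map`: `map`
#'   (`n_epochs x n_rows x n_cols`), `row_semantics` (`"csp"`/`"wpd"` per
#'   row), `labels`, `provenance`, and the `scaler` to reuse on held-out
#'   data.
#' @export
build_feature_map <- function(epochs, csp, wpd = NULL, time_decim = 1L,
                              subframe_s = 0.25, scaler = NULL) {
  epochs <- validate_epoch_set(epochs)
  d <- dim(epochs$data)
  ct <- csp_transform(epochs, csp)
  K <- dim(ct$series)[2]
  Tc <- d[3L] %/% time_decim
  if (Tc < 1L) stop("`time_decim` larger than the window", call. = FALSE)

  # CSP rows, block-averaged over time_decim samples
  csp_rows <- array(0, c(d[1L], K, Tc))
  if (time_decim == 1L) {
    csp_rows <- ct$series
  } else {
    for (i in seq_len(d[1L])) {
      S <- matrix(ct$series[i, , seq_len(Tc * time_decim)], K)
      dim(S) <- c(K, time_decim, Tc)
      csp_rows[i, , ] <- apply(S, c(1, 3), mean)
    }
  }

  B <- 0L; wpd_rows <- NULL
  if (!is.null(wpd)) {
    sel <- wpd_select_leaves(wpd$level, epochs$fs, wpd$selected_bands_hz)
    B <- length(sel)
    if (B == 0L)
      stop("no wavelet packet leaf intersects the selected bands", call. = FALSE)
    X <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3L])
    leaves <- wpt_leaves_matrix(X, wpd$level, wpd$wavelet)
    n_coef <- nrow(leaves[[1]])
    stride_s <- 2^wpd$level / epochs$fs           # time per leaf coefficient
    centers <- (seq_len(n_coef) - 0.5) * stride_s
    frame_id <- pmin(floor(centers / subframe_s), floor(max(centers) / subframe_s))
    n_frames <- max(frame_id) + 1L
    f_centers <- (seq_len(n_frames) - 0.5) * subframe_s
    xout <- (seq_len(Tc) - 0.5) * (d[3L] / epochs$fs) / Tc
    wpd_rows <- array(0, c(d[1L], B, Tc))
    for (j in seq_len(B)) {
      E <- leaves[[sel[j] + 1L]]^2                # n_coef x (ch*epochs)
      # mean energy per sub-frame, channel-averaged per epoch
      fr <- rowsum(E, frame_id) / as.vector(table(frame_id))
      dim(fr) <- c(n_frames, d[2L], d[1L])
      env <- apply(fr, c(1, 3), mean)             # n_frames x n_epochs
      for (i in seq_len(d[1L]))
        wpd_rows[i, j, ] <- stats::approx(f_centers, log(env[, i] + 1e-12),
                                          xout = xout, rule = 2)$y
    }
  }

  R <- K + B
  map <- array(0, c(d[1L], R, Tc))
  map[, seq_len(K), ] <- csp_rows
  if (B > 0L) map[, K + seq_len(B), ] <- wpd_rows
  row_semantics <- c(rep("csp", K), rep("wpd", B))

  if (is.null(scaler)) {
    mu <- apply(map, 2, mean)
    sd_ <- pmax(apply(map, 2, stats::sd), 1e-8)
    scaler <- list(mean = mu, sd = sd_)
  }
  for (r in seq_len(R))
    map[, r, ] <- (map[, r, ] - scaler$mean[r]) / scaler$sd[r]

  structure(list(map = map, row_semantics = row_semantics,
                 labels = epochs$labels, provenance = epochs$provenance,
                 fs = epochs$fs, scaler = scaler,
                 time_decim = as.integer(time_decim)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$map)
  cat(sprintf("<feature_map> %d maps of %dx%d (%d CSP rows, %d WPD rows)\n",
              d[1], d[2], d[3], sum(x$row_semantics == "csp"),
              sum(x$row_semantics == "wpd")))
  invisible(x)
}

# subset a feature_map by epoch index (1-based)
feature_map_subset <- function(fm, idx) {
  fm$map <- fm$map[idx, , , drop = FALSE]
  fm$labels <- fm$labels[idx]
  fm$provenance <- fm$provenance[idx, , drop = FALSE]
  fm
}
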