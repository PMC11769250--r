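# Wavelet packet decomposition (periodized orthogonal filter banks).
#
# The full binary tree is computed by recursively splitting every node with
# the quadrature-mirror pair (h, g) and downsampling by two, using periodic
# extension so coefficient counts halve exactly and the transform is
# orthogonal (energy-preserving, perfectly invertible) whenever the signal
# length is divisible by 2^level. Leaves are indexed in FREQUENCY (sequency)
# order: because high-pass filtering followed by downsampling mirrors the
# spectrum, the natural (Paley) child order must be swapped under every
# odd-band parent; band k at depth L then spans [k, k+1) * fs / 2^(L+1) Hz.

# scaling (low-pass) coefficients in natural order, orthonormal (sum = sqrt 2)
.wavelet_lowpass <- list(
  haar = c(1, 1) / sqrt(2),
  db1 = c(1, 1) / sqrt(2),
  db2 = c(0.48296291314469025, 0.836516303737469,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

#' Quadrature-mirror analysis filters for an orthogonal wavelet
#'
#' @param wavelet one of `"haar"`, `"db1"`, `"db2"`, `"db4"`.
#' @return list with low-pass `h`, high-pass `g` (QMF of `h`) and the name.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  h <- .wavelet_lowpass[[wavelet]]
  if (is.null(h)) stop("unknown wavelet: ", wavelet, call. = FALSE)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(h = h, g = g, name = wavelet)
}

# one analysis step on a matrix of column series (periodic extension);
# odd-length input is extended by repeating the last sample
wpt_step <- function(X, h, g) {
  N <- nrow(X)
  if (N %% 2L == 1L) { X <- rbind(X, X[N, , drop = FALSE]); N <- N + 1L }
  N2 <- N %/% 2L
  A <- matrix(0, N2, ncol(X)); D <- A
  base <- 2L * (seq_len(N2) - 1L)
  for (k in seq_along(h)) {
    rows <- (base + k - 1L) %% N + 1L
    A <- A + h[k] * X[rows, , drop = FALSE]
    D <- D + g[k] * X[rows, , drop = FALSE]
  }
  list(A = A, D = D)
}

# adjoint of wpt_step (exact inverse for even N)
wpt_step_inv <- function(A, D, h, g, n_out) {
  N <- 2L * nrow(A)
  X <- matrix(0, N, ncol(A))
  base <- 2L * (seq_len(nrow(A)) - 1L)
  for (k in seq_along(h)) {
    rows <- (base + k - 1L) %% N + 1L
    X[rows, ] <- X[rows, , drop = FALSE] + h[k] * A + g[k] * D
  }
  X[seq_len(n_out), , drop = FALSE]
}

# Decompose many series at once down to `level`, returning only the leaves
# as a list of matrices in frequency order. X: n_samples x n_series.
wpt_leaves_matrix <- function(X, level, wavelet = "db4") {
  flt <- wavelet_filters(wavelet)
  nodes <- list(X); bands <- 0L
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes)); nb <- integer(length(nxt))
    for (i in seq_along(nodes)) {
      sp <- wpt_step(nodes[[i]], flt$h, flt$g)
      b <- bands[i]
      if (b %% 2L == 0L) { lo <- 2L * b; hi <- 2L * b + 1L }
      else               { lo <- 2L * b + 1L; hi <- 2L * b }
      nxt[[2L * i - 1L]] <- sp$A; nb[2L * i - 1L] <- lo
      nxt[[2L * i]] <- sp$D;      nb[2L * i] <- hi
    }
    ord <- order(nb)
    nodes <- nxt[ord]; bands <- nb[ord]
  }
  nodes
}

#' Wavelet packet configuration
#'
#' Defaults: `db4` at depth 4 — at 250 Hz this tiles the spectrum into
#' sixteen 7.8125 Hz leaves — retaining the 8-30 Hz selection that covers the
#' sensorimotor mu and beta rhythms.
#'
#' @param wavelet mother wavelet name (see [wavelet_filters()]).
#' @param level decomposition depth (>= 1).
#' @param selected_bands_hz list of `c(low, high)` frequency selections in Hz.
#' @return An object of class `wpd_spec`.
#' @export
wpd_spec <- function(wavelet = "db4", level = 4L,
                     selected_bands_hz = list(c(8, 30))) {
  if (level < 1) stop("`level` must be >= 1", call. = FALSE)
  wavelet_filters(wavelet)   # validates the name
  for (b in selected_bands_hz)
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 0)
      stop("selected bands must be c(low, high) with 0 <= low < high",
           call. = FALSE)
  structure(list(wavelet = wavelet, level = as.integer(level),
                 selected_bands_hz = selected_bands_hz), class = "wpd_spec")
}

# frequency band of leaf k (0-based) at depth L
wpd_leaf_bands <- function(level, fs) {
  width <- fs / 2^(level + 1)
  k <- seq_len(2^level) - 1
  cbind(low = k * width, high = (k + 1) * width)
}

# 0-based indices of leaves whose band intersects any selection (open overlap)
wpd_select_leaves <- function(level, fs, selected_bands_hz) {
  bands <- wpd_leaf_bands(level, fs)
  keep <- vapply(seq_len(nrow(bands)), function(i)
    any(vapply(selected_bands_hz, function(s)
      bands[i, 1] < s[2] && bands[i, 2] > s[1], logical(1))), logical(1))
  which(keep) - 1L
}

#' Full wavelet packet tree of a single series
#'
#' @param x numeric series; must be at least `2^level` samples long.
#' @param spec a [wpd_spec()] (only `wavelet` and `level` are used).
#' @param fs sampling rate in Hz (attaches physical bands to the leaves).
#' @return An object of class `wpd_tree`: `coeffs[[l]]` holds the nodes of
#'   level `l` in frequency order, `leaf_bands_hz` the leaf band edges.
#' @export
wpd_decompose <- function(x, spec, fs) {
  if (length(x) < 2^spec$level)
    stop("series too short: need at least 2^level = ", 2^spec$level,
         " samples", call. = FALSE)
  flt <- wavelet_filters(spec$wavelet)
  levels <- vector("list", spec$level)
  nodes <- list(matrix(x, ncol = 1)); bands <- 0L
  for (l in seq_len(spec$level)) {
    nxt <- vector("list", 2L * length(nodes)); nb <- integer(length(nxt))
    for (i in seq_along(nodes)) {
      sp <- wpt_step(nodes[[i]], flt$h, flt$g)
      b <- bands[i]
      if (b %% 2L == 0L) { lo <- 2L * b; hi <- 2L * b + 1L }
      else               { lo <- 2L * b + 1L; hi <- 2L * b }
      nxt[[2L * i - 1L]] <- sp$A; nb[2L * i - 1L] <- lo
      nxt[[2L * i]] <- sp$D;      nb[2L * i] <- hi
    }
    ord <- order(nb); nodes <- nxt[ord]; bands <- nb[ord]
    levels[[l]] <- lapply(nodes, function(m) m[, 1])
  }
  structure(list(coeffs = levels, wavelet = spec$wavelet, level = spec$level,
                 fs = fs, n = length(x),
                 leaf_bands_hz = wpd_leaf_bands(spec$level, fs)),
            class = "wpd_tree")
}

#' Reconstruct a series from its wavelet packet leaves
#'
#' Inverts [wpd_decompose()] from the deepest level; exact (to rounding) when
#' the original length is divisible by `2^level`.
#'
#' @param tree a `wpd_tree`.
#' @return numeric series of the original length.
#' @export
wpd_reconstruct <- function(tree) {
  flt <- wavelet_filters(tree$wavelet)
  nodes <- lapply(tree$coeffs[[tree$level]], function(v) matrix(v, ncol = 1))
  bands <- seq_along(nodes) - 1L
  for (l in rev(seq_len(tree$level))) {
    n_par <- length(nodes) %/% 2L
    par_nodes <- vector("list", n_par)
    n_out <- if (l == 1L) tree$n else length(tree$coeffs[[l - 1L]][[1L]])
    for (p in seq_len(n_par)) {
      b_par <- p - 1L
      ia <- which(bands == (if (b_par %% 2L == 0L) 2L * b_par else 2L * b_par + 1L))
      id <- which(bands == (if (b_par %% 2L == 0L) 2L * b_par + 1L else 2L * b_par))
      par_nodes[[p]] <- wpt_step_inv(nodes[[ia]], nodes[[id]],
                                     flt$h, flt$g, n_out)
    }
    nodes <- par_nodes; bands <- seq_len(n_par) - 1L
  }
  nodes[[1L]][, 1L]
}

#' Wavelet packet band energies of an epoch set
#'
#' For every epoch and channel, the energy (sum of squared coefficients) of
#' each depth-`level` leaf whose frequency band intersects the selection.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [wpd_spec()].
#' @return An object of class `wpd_features`: `energies` array
#'   `n_epochs x n_channels x n_leaves`, `node_bands_hz` the per-leaf bands,
#'   `leaf_index` the retained 0-based leaf indices.
#' @export
wpd_band_energies <- function(epochs, spec) {
  epochs <- validate_epoch_set(epochs)
  d <- dim(epochs$data)
  sel <- wpd_select_leaves(spec$level, epochs$fs, spec$selected_bands_hz)
  if (length(sel) == 0)
    stop("no wavelet packet leaf intersects the selected bands", call. = FALSE)
  # all epochs/channels as columns of one matrix for a single batched pass
  X <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3L])
  leaves <- wpt_leaves_matrix(X, spec$level, spec$wavelet)
  en <- array(0, c(d[1L], d[2L], length(sel)))
  for (j in seq_along(sel)) {
    e <- colSums(leaves[[sel[j] + 1L]]^2)
    en[, , j] <- t(matrix(e, nrow = d[2L]))
  }
  bands <- wpd_leaf_bands(spec$level, epochs$fs)[sel + 1L, , drop = FALSE]
  structure(list(energies = en, node_bands_hz = bands, leaf_index = sel,
                 spec = spec), class = "wpd_features")
}
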