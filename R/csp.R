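# Common spatial patterns, one-vs-rest multiclass extension.
#
# For each class c the generalized eigenproblem
#   Sigma_c w = lambda (Sigma_c + Sigma_rest) w
# is solved by whitening the composite covariance and eigendecomposing the
# whitened class covariance; eigenvalues lie in [0, 1] and the filters W
# satisfy W (Sigma_c + Sigma_rest) W' = I. The largest-lambda filters
# maximize class-c variance relative to the rest, the smallest minimize it.

# per-epoch spatial covariance (rows = channels), mean-centred;
# "trace" normalization equalizes epoch power, "none" keeps raw scale
epoch_covariance <- function(X, cov_norm = "trace") {
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / ncol(X)
  if (cov_norm == "trace") C / sum(diag(C)) else C
}

#' Fit one-vs-rest common spatial patterns
#'
#' For every class, the class-mean covariance is contrasted against the
#' balanced mean of the remaining classes; the `n_pairs` largest- and
#' `n_pairs` smallest-eigenvalue spatial filters are retained and the
#' per-class blocks stacked.
#'
#' @param epochs an [epoch_set()] with at least 2 epochs in every class.
#' @param n_pairs filter pairs kept per class (default 2); at most
#'   `n_channels / 2`.
#' @param cov_norm `"trace"` (default) for per-epoch trace-normalized
#'   covariances, `"none"` for raw sample covariances.
#' @return An object of class `csp_model`: `filters`
#'   (`n_components x n_channels`, one-vs-rest blocks stacked),
#'   `eigenvalues` (in `[0,1]`, descending within each block), `n_pairs`,
#'   `class_order`, and per-block composite covariances.
#' @export
csp_fit <- function(epochs, n_pairs = 2L, cov_norm = c("trace", "none")) {
  epochs <- validate_epoch_set(epochs)
  cov_norm <- match.arg(cov_norm)
  d <- dim(epochs$data)
  if (n_pairs < 1 || 2L * n_pairs > d[2L])
    stop("`n_pairs` must satisfy 1 <= n_pairs <= n_channels/2", call. = FALSE)
  classes <- sort(unique(epochs$labels))
  counts <- table(factor(epochs$labels, levels = classes))
  if (any(counts < 2))
    stop("every class needs at least 2 epochs (class ",
         classes[which.min(counts)], " has ", min(counts), ")", call. = FALSE)

  class_cov <- lapply(classes, function(cl) {
    idx <- which(epochs$labels == cl)
    covs <- lapply(idx, function(i)
      epoch_covariance(matrix(epochs$data[i, , ], d[2L]), cov_norm))
    Reduce(`+`, covs) / length(covs)
  })

  blocks <- lapply(seq_along(classes), function(ci) {
    Sc <- class_cov[[ci]]
    Sr <- Reduce(`+`, class_cov[-ci]) / (length(classes) - 1L)
    comp <- Sc + Sr
    ev <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
    tol <- max(ev$values) * 1e-10
    if (min(ev$values) < tol) {
      ridge <- 1e-6 * sum(diag(comp)) / d[2L]
      warning("rank-deficient composite covariance for class ", classes[ci],
              "; ridge ", signif(ridge, 3), " applied", call. = FALSE)
      comp <- comp + ridge * diag(d[2L])
      ev <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
    }
    P <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)   # whitener
    S <- P %*% Sc %*% t(P)
    e2 <- eigen((S + t(S)) / 2, symmetric = TRUE)      # values descending
    W <- t(e2$vectors) %*% P                           # rows: all filters
    keep <- c(seq_len(n_pairs), d[2L] - n_pairs + seq_len(n_pairs))
    lam <- pmin(pmax(e2$values[keep], 0), 1)
    ord <- order(lam, decreasing = TRUE)
    list(filters = W[keep, , drop = FALSE][ord, , drop = FALSE],
         eigenvalues = lam[ord], composite_cov = comp, class = classes[ci])
  })

  structure(list(
    filters = do.call(rbind, lapply(blocks, `[[`, "filters")),
    eigenvalues = unlist(lapply(blocks, `[[`, "eigenvalues")),
    n_pairs = as.integer(n_pairs), class_order = classes,
    blocks = blocks, cov_norm = cov_norm,
    n_channels = d[2L]
  ), class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters (%d classes x %d pairs x 2), %d channels, cov_norm=%s\n",
              nrow(x$filters), length(x$class_order), x$n_pairs,
              x$n_channels, x$cov_norm))
  invisible(x)
}

#' Apply fitted CSP filters to epochs
#'
#' Projects every epoch onto the spatial filters and computes the classical
#' normalized log-variance features
#' `f_k = log(var(s_k) / sum_j var(s_j))`, which are invariant to overall
#' epoch scale.
#'
#' @param epochs an [epoch_set()] with the channel count the model was
#'   fitted on.
#' @param model a [csp_fit()] result.
#' @return list with `series` (`n_epochs x n_components x n_samples` array
#'   of filtered time courses) and `logvar`
#'   (`n_epochs x n_components` feature matrix).
#' @export
csp_transform <- function(epochs, model) {
  epochs <- validate_epoch_set(epochs)
  d <- dim(epochs$data)
  if (d[2L] != ncol(model$filters))
    stop("channel mismatch: epochs have ", d[2L], ", model expects ",
         ncol(model$filters), call. = FALSE)
  K <- nrow(model$filters)
  series <- array(0, c(d[1L], K, d[3L]))
  logvar <- matrix(0, d[1L], K)
  for (i in seq_len(d[1L])) {
    S <- model$filters %*% matrix(epochs$data[i, , ], d[2L])
    series[i, , ] <- S
    v <- apply(S, 1, stats::var)
    logvar[i, ] <- log(v / sum(v))
  }
  list(series = series, logvar = logvar)
}
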