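test_that("planted diagonal variances recover the closed-form eigenvalues", {
  # class a covariance diag(4, 1), class b diag(1, 1):
  # generalized eigenvalues a_i / (a_i + b_i) = {4/5, 1/2}
  ep <- make_separable_epochs(diag_variance_spec(seed = 7), 200)
  m <- csp_fit(ep, n_pairs = 1, cov_norm = "none")
  expect_lt(abs(m$blocks[[1]]$eigenvalues[1] - 0.8) / 0.8, 0.03)
  expect_lt(abs(m$blocks[[1]]$eigenvalues[2] - 0.5) / 0.5, 0.03)
  # leading filter aligned with the channel-1 axis
  w1 <- m$blocks[[1]]$filters[1, ]
  expect_gt(abs(w1[1]) / sqrt(sum(w1^2)), 0.99)
})

test_that("orthogonal single-source patterns give a top eigenvalue above 0.9", {
  spec <- synthetic_spec(n_eeg_channels = 2, n_eog_channels = 0,
                         classes = c("a", "b"),
                         mixing = list(matrix(c(1, 0), 2), matrix(c(0, 1), 2)),
                         rhythm_bands = list(c(9, 13)), snr_db = 60, seed = 3)
  ep <- make_separable_epochs(spec, 20)
  m <- csp_fit(ep, n_pairs = 1, cov_norm = "none")
  expect_gt(max(m$eigenvalues), 0.9)
})

test_that("identical class covariances give eigenvalues of one half", {
  # distinct mixing matrices with identical covariance A A' = I
  spec <- synthetic_spec(n_eeg_channels = 2, n_eog_channels = 0,
                         classes = c("a", "b"),
                         mixing = list(diag(2), matrix(c(0, 1, 1, 0), 2)),
                         rhythm_bands = list(c(9, 13), c(18, 24)),
                         snr_db = 60, seed = 12)
  ep <- make_separable_epochs(spec, 150)
  m <- csp_fit(ep, n_pairs = 1, cov_norm = "none")
  expect_equal(unname(m$eigenvalues), rep(0.5, 4), tolerance = 0.02)
})

test_that("whitening and the generalized eigen-residual hold on random fits", {
  set.seed(31)
  for (rep in 1:5) {
    nch <- sample(3:6, 1)
    mixing <- list(matrix(rnorm(nch * 2), nch), matrix(rnorm(nch * 2), nch))
    spec <- synthetic_spec(n_eeg_channels = nch, n_eog_channels = 0,
                           classes = c("a", "b"), mixing = mixing,
                           rhythm_bands = list(c(9, 13), c(18, 24)),
                           snr_db = 10, seed = rep)
    ep <- make_separable_epochs(spec, 12)
    m <- csp_fit(ep, n_pairs = 1)
    for (blk in m$blocks) {
      W <- blk$filters
      # whitening invariant: W (Sigma_c + Sigma_rest) W' = I
      expect_lt(max(abs(W %*% blk$composite_cov %*% t(W) - diag(nrow(W)))),
                1e-6)
      expect_true(all(blk$eigenvalues >= 0 & blk$eigenvalues <= 1))
      expect_true(all(diff(blk$eigenvalues) <= 1e-12))  # descending
    }
  }
})

test_that("fitted filters solve the generalized eigenproblem of the sample covariances", {
  # residual check against an independent dense eigensolver on the same
  # average covariances the fit used
  set.seed(77)
  ep <- make_separable_epochs(diag_variance_spec(a = c(3, 1.5),
                                                 b = c(1, 2), seed = 3), 30)
  m <- csp_fit(ep, n_pairs = 1, cov_norm = "none")
  # rebuild the class-average covariances exactly as the model defines them
  covs <- lapply(0:1, function(cl) {
    idx <- which(ep$labels == cl)
    Reduce(`+`, lapply(idx, function(i) {
      X <- matrix(ep$data[i, , ], 2); X <- X - rowMeans(X)
      tcrossprod(X) / ncol(X)
    })) / length(idx)
  })
  for (ci in 1:2) {
    Sc <- covs[[ci]]; Sr <- covs[[3 - ci]]
    blk <- m$blocks[[ci]]
    for (j in seq_along(blk$eigenvalues)) {
      w <- blk$filters[j, ]; lam <- blk$eigenvalues[j]
      expect_lt(max(abs(Sc %*% w - lam * (Sc + Sr) %*% w)), 1e-8)
    }
    # eigenvalues agree with an independent dense solve of inv(Sc+Sr) Sc
    lam_oracle <- sort(Re(eigen(solve(Sc + Sr) %*% Sc)$values),
                       decreasing = TRUE)
    expect_equal(unname(blk$eigenvalues), lam_oracle, tolerance = 1e-10)
  }
})

test_that("csp_transform projects series and scale-invariant log-variances", {
  ep <- make_separable_epochs(diag_variance_spec(), 4)
  m <- csp_fit(ep, n_pairs = 1, cov_norm = "none")
  # identity filters return the input series unchanged
  mi <- m; mi$filters <- diag(2)
  ct <- csp_transform(ep, mi)
  expect_equal(ct$series[1, , ], ep$data[1, , ])
  # scaling an epoch by 10 leaves the normalized log-variances unchanged
  ep10 <- ep; ep10$data <- ep$data * 10
  expect_equal(csp_transform(ep10, m)$logvar, csp_transform(ep, m)$logvar,
               tolerance = 1e-10)
  bad <- make_separable_epochs(small_session_spec(), 2)
  expect_error(csp_transform(bad, m), "channel mismatch")
})

test_that("log-variance features separate planted classes near-perfectly", {
  spec <- diag_variance_spec(a = c(3, 1), b = c(1, 3), snr_db = 60, seed = 21)
  tr <- make_separable_epochs(spec, 40)
  spec$seed <- 22L
  te <- make_separable_epochs(spec, 25)
  m <- csp_fit(tr, n_pairs = 1)
  f_tr <- csp_transform(tr, m)$logvar
  f_te <- csp_transform(te, m)$logvar
  centroids <- rbind(colMeans(f_tr[tr$labels == 0, ]),
                     colMeans(f_tr[tr$labels == 1, ]))
  pred <- apply(f_te, 1, function(v)
    which.min(colSums((t(centroids) - v)^2)) - 1L)
  expect_gte(mean(pred == te$labels), 0.95)
})

test_that("degenerate inputs are rejected or regularized", {
  ep <- make_separable_epochs(diag_variance_spec(), 1)
  expect_error(csp_fit(ep, 1), "at least 2 epochs")
  ep2 <- make_separable_epochs(diag_variance_spec(), 5)
  expect_error(csp_fit(ep2, n_pairs = 2), "n_pairs")
  # rank-deficient: one channel duplicated
  ep3 <- make_separable_epochs(diag_variance_spec(seed = 2), 5)
  ep3$data[, 2, ] <- ep3$data[, 1, ]
  w <- testthat::capture_warnings(m <- csp_fit(ep3, 1))
  expect_true(any(grepl("ridge", w)))   # one warning per rank-deficient block
  expect_true(all(is.finite(m$filters)))
})
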