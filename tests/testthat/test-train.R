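# small, fast feature maps with separable planted classes
separable_maps <- function(n_per_class = 12, seed = 17) {
  spec <- diag_variance_spec(a = c(3, 1), b = c(1, 3), snr_db = 20,
                             seed = seed)
  ep <- make_separable_epochs(spec, n_per_class)
  csp <- csp_fit(ep, n_pairs = 1)
  build_feature_map(ep, csp, wpd_spec(), time_decim = 10)   # 5 x 50 maps
}

tiny_model <- function(shape, seed = 1, dropout = 0.2) {
  build_fusion(fusion_config(
    branches = list(branch_spec(2, 1, n_filters = 3),
                    branch_spec(1, 1, n_filters = 3)),
    dropout = dropout, weight_decay = 1e-4, seed = seed,
    paper_faithful = FALSE), shape)
}

test_that("noise augmentation is seeded, unbiased and sigma-scaled", {
  ep <- make_separable_epochs(diag_variance_spec(seed = 2), 20)
  expect_identical(augment_noise(ep, 0), ep)
  a1 <- augment_noise(ep, 0.1, seed = 5)
  a2 <- augment_noise(ep, 0.1, seed = 5)
  expect_identical(a1, a2)
  expect_error(augment_noise(ep, -1), "non-negative")
  # moment check: the added noise std matches sigma * channel std
  ch_sd <- apply(ep$data, 2, sd)
  diffs <- a1$data - ep$data
  for (ch in 1:2) {
    got <- sd(as.vector(diffs[, ch, ]))          # 2e4 samples per channel
    expect_lt(abs(got - 0.1 * ch_sd[ch]) / (0.1 * ch_sd[ch]), 0.05)
  }
  expect_identical(a1$labels, ep$labels)
})

test_that("training reaches high accuracy on separable planted maps", {
  fm <- separable_maps()
  mdl <- tiny_model(dim(fm$map)[2:3], seed = 3)
  fit <- train(mdl, fm, epochs = 40, lr = 0.005, batch_size = 8, seed = 3)
  expect_gte(tail(fit$history$train_acc, 1), 0.95)
  expect_equal(nrow(fit$history), 40)
})

test_that("training history is fully reproducible under a fixed seed", {
  fm <- separable_maps(6)
  mdl <- tiny_model(dim(fm$map)[2:3], seed = 8)
  f1 <- train(mdl, fm, epochs = 3, lr = 0.002, batch_size = 8, seed = 4)
  f2 <- train(mdl, fm, epochs = 3, lr = 0.002, batch_size = 8, seed = 4)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- train(mdl, fm, epochs = 1, lr = 0.002, batch_size = 8, seed = 4)
  expect_equal(nrow(f3$history), 1)
})

test_that("non-finite losses abort naming the configuration", {
  fm <- separable_maps(4)
  fm$map[1, 1, 1] <- NaN
  mdl <- tiny_model(dim(fm$map)[2:3])
  expect_error(train(mdl, fm, epochs = 1, lr = 0.001, batch_size = 8),
               "diverged.*lr=0.001")
})

test_that("metric formulas match a brute-force counting oracle", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(8:40, 1)
    true <- sample(0:3, n, replace = TRUE)
    pred <- sample(0:3, n, replace = TRUE)
    m <- compute_metrics(true, pred)
    expect_equal(sum(m$confusion), n)             # mass conservation
    cl <- sample(0:3, 1)
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    row <- m$per_class[m$per_class$class == cl, ]
    expect_equal(row$precision, prec)
    expect_equal(row$recall, rec)
    expect_equal(row$f1, f1)
    expect_equal(m$accuracy, mean(true == pred))
  }
})

test_that("evaluation handles perfect, worked-example and degenerate cases", {
  perfect <- compute_metrics(c(0, 1, 2, 3, 0), c(0, 1, 2, 3, 0))
  expect_true(all(diag(perfect$confusion) == c(2, 1, 1, 1)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)

  # class 0 with TP=8, FP=2, FN=2: precision = recall = F1 = 0.8
  true <- c(rep(0, 8), rep(1, 2), rep(0, 2), rep(1, 8))
  pred <- c(rep(0, 8), rep(0, 2), rep(1, 2), rep(1, 8))
  m <- compute_metrics(true, pred, 2)
  expect_equal(m$per_class$precision[1], 0.8)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$f1[1], 0.8)

  # an absent predicted class is flagged, not NaN
  m0 <- compute_metrics(c(0, 0, 1), c(1, 1, 1), 4)
  expect_equal(m0$per_class$precision[1], 0)
  expect_true(m0$per_class$precision_undefined[3])
  expect_error(compute_metrics(integer(), integer()), "empty")
})

test_that("uniform random guessing over 4 balanced classes scores ~0.25", {
  set.seed(7)
  n <- 4000
  true <- rep(0:3, each = n / 4)
  pred <- sample(0:3, n, replace = TRUE)
  m <- compute_metrics(true, pred)
  expect_lt(abs(m$accuracy - 0.25), 0.02)
})

test_that("window voting takes the majority with probability tie-breaks", {
  # three windows voting (A, A, B) -> A
  proba <- rbind(c(0.6, 0.4, 0, 0), c(0.7, 0.3, 0, 0), c(0.2, 0.8, 0, 0))
  pv <- data.frame(trial_id = c(1, 1, 1))
  expect_equal(window_vote(proba, pv)$pred, 0L)
  # tie (A, B): mean probability decides
  proba2 <- rbind(c(0.60, 0.40, 0, 0), c(0.45, 0.55, 0, 0))
  pv2 <- data.frame(trial_id = c(2, 2))
  expect_equal(window_vote(proba2, pv2)$pred, 0L)   # mean 0.525 vs 0.475
  # a single window is its own vote
  expect_equal(window_vote(matrix(c(0.1, 0.2, 0.6, 0.1), 1),
                           data.frame(trial_id = 9))$pred, 2L)
  expect_error(window_vote(proba, data.frame(x = 1:3)), "trial_id")
})
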