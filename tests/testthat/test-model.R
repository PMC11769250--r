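test_that("paper-faithful mode builds exactly the five canonical branches", {
  mdl <- build_fusion(fusion_config(n_filters = 2, seed = 1), c(15, 500))
  expect_length(mdl$branches, 5)
  got <- lapply(mdl$branches, function(b)
    c(b$spec$n_conv_blocks, b$spec$n_dense_blocks))
  expect_equal(got, list(c(6L, 3L), c(4L, 3L), c(3L, 2L), c(2L, 2L), c(2L, 1L)))
  for (b in mdl$branches) {
    expect_equal(b$spec$kernel, c(3L, 3L))
    expect_equal(b$spec$stride, 1L)
    expect_equal(b$spec$dense_width, 32L)
    # graph inspection: the trace lists exactly n_conv_blocks conv layers
    expect_equal(sum(grepl("^conv", b$trace$layer)), b$spec$n_conv_blocks)
    expect_equal(sum(grepl("^dense", b$trace$layer)), b$spec$n_dense_blocks)
    expect_true(all(grepl("^32$", b$trace$output_shape[grepl("^dense",
                                                             b$trace$layer)])))
  }
  expect_equal(mdl$concat_width, 5 * 32)
  # deviating block counts are rejected in paper-faithful mode
  bad <- lapply(list(c(6, 3), c(4, 3), c(3, 2), c(2, 2), c(1, 1)),
                function(d) branch_spec(d[1], d[2]))
  expect_error(fusion_config(branches = bad), "paper-faithful")
})

test_that("shape traces and parameter counts match an independent oracle", {
  for (case in list(list(b = c(2L, 1L), shape = c(15L, 500L), f = 4L),
                    list(b = c(6L, 3L), shape = c(19L, 71L), f = 16L),
                    list(b = c(3L, 2L), shape = c(19L, 100L), f = 8L))) {
    br <- build_branch(branch_spec(case$b[1], case$b[2],
                                   n_filters = case$f), case$shape)
    oracle <- oracle_branch_shapes(case$b[1], case$b[2], case$f, case$shape)
    expect_equal(br$flat_len, oracle$flat)
    expect_equal(br$n_params, oracle$params)
    expect_equal(br$out_width, oracle$out_width)
  }
  # total model parameters = sum of branches + fusion head
  mdl <- build_fusion(fusion_config(n_filters = 4, seed = 2), c(19, 71))
  oracle_total <- sum(vapply(list(c(6, 3), c(4, 3), c(3, 2), c(2, 2), c(2, 1)),
                             function(d) oracle_branch_shapes(d[1], d[2], 4,
                                                              c(19, 71))$params,
                             numeric(1))) + (5 * 32) * 4 + 4
  expect_equal(mdl$n_params, oracle_total)
  expect_equal(mdl$n_params,
               sum(vapply(mdl$params, length, integer(1))))
})

test_that("too-small inputs fail naming the offending block", {
  expect_error(build_branch(branch_spec(6, 1), c(15, 40)), "conv block")
})

test_that("softmax output is row-stochastic and duplication-consistent", {
  mdl <- build_fusion(fusion_config(n_filters = 2, seed = 5), c(8, 64))
  set.seed(1)
  x <- array(rnorm(6 * 8 * 64), c(6, 8, 64))
  p <- predict_proba(mdl, x)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicated inputs give duplicated rows (deterministic inference)
  x2 <- x; x2[4, , ] <- x[1, , ]
  p2 <- predict_proba(mdl, x2)
  expect_equal(p2[4, ], p2[1, ])
  expect_error(predict_proba(mdl, array(0, c(2, 9, 64))), "shape")
})

test_that("initialization is seeded and a zeroed head gives uniform output", {
  cfg <- fusion_config(n_filters = 2, seed = 9)
  m1 <- build_fusion(cfg, c(8, 64))
  m2 <- build_fusion(cfg, c(8, 64))
  expect_identical(m1$params, m2$params)
  m3 <- build_fusion(fusion_config(n_filters = 2, seed = 10), c(8, 64))
  expect_false(identical(m1$params, m3$params))
  m1$params[["head.W"]][] <- 0
  m1$params[["head.b"]][] <- 0
  p <- predict_proba(m1, array(rnorm(3 * 8 * 64), c(3, 8, 64)))
  expect_equal(p, matrix(0.25, 3, 4))
})

test_that("average pooling is available as the per-block policy option", {
  mdl <- build_fusion(fusion_config(n_filters = 2, pooling = "avg", seed = 1),
                      c(8, 64))
  x <- array(rnorm(2 * 8 * 64), c(2, 8, 64))
  p <- predict_proba(mdl, x)
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
})
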