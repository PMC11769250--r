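# The five-branch convolutional fusion network.
#
# Each branch is a stack of convolution blocks (3x3 kernels, stride 1,
# "same" zero padding, tanh activation, pooling) followed by a flatten and a
# stack of 32-unit tanh dense blocks. The five branch outputs are
# concatenated, passed through dropout, and mapped by a single dense layer
# with softmax to the four class probabilities. Pooling halves both
# dimensions (2x2) while both exceed one, then continues along time (1x2)
# so deep branches stay viable on short feature maps.

#' Specification of one convolutional branch
#'
#' @param n_conv_blocks number of convolution blocks (>= 1); each block is
#'   conv(3x3, stride 1, same padding) + tanh + pooling.
#' @param n_dense_blocks number of dense blocks (>= 1), each a 32-unit tanh
#'   layer by default.
#' @param n_filters convolution filters per block (default 16).
#' @param dense_width units per dense block (default 32).
#' @param kernel kernel size, `c(3, 3)`.
#' @param stride convolution stride, 1.
#' @param activation activation name, `"tanh"`.
#' @param pooling `"max"` (default) or `"avg"`.
#' @return An object of class `branch_spec`.
#' @export
branch_spec <- function(n_conv_blocks, n_dense_blocks, n_filters = 16L,
                        dense_width = 32L, kernel = c(3L, 3L), stride = 1L,
                        activation = "tanh", pooling = c("max", "avg")) {
  pooling <- match.arg(pooling)
  if (n_conv_blocks < 1 || n_dense_blocks < 1)
    stop("branches need at least one conv and one dense block", call. = FALSE)
  if (stride != 1L) stop("only stride 1 is supported", call. = FALSE)
  if (activation != "tanh") stop("only tanh activation is supported", call. = FALSE)
  structure(list(n_conv_blocks = as.integer(n_conv_blocks),
                 n_dense_blocks = as.integer(n_dense_blocks),
                 n_filters = as.integer(n_filters),
                 dense_width = as.integer(dense_width),
                 kernel = as.integer(kernel), stride = 1L,
                 activation = "tanh", pooling = pooling),
            class = "branch_spec")
}

# the five canonical (conv, dense) block-count patterns
.canonical_blocks <- list(c(6L, 3L), c(4L, 3L), c(3L, 2L), c(2L, 2L), c(2L, 1L))

#' Configuration of the five-branch fusion network
#'
#' In paper-faithful mode (the default) the five branches have exactly
#' (6,3), (4,3), (3,2), (2,2) and (2,1) convolution/dense blocks.
#'
#' @param branches list of [branch_spec()]s; `NULL` builds the five
#'   canonical branches.
#' @param n_classes number of output classes (default 4).
#' @param dropout dropout rate applied after concatenation, in `[0.3, 0.5]`
#'   by convention (default 0.4).
#' @param weight_decay L2 coefficient on all weights (default 1e-4).
#' @param seed integer seed for weight initialization (default 1).
#' @param n_filters convolution filters per block for the default branches.
#' @param pooling pooling policy for the default branches.
#' @param paper_faithful enforce the five canonical block-count patterns,
#'   3x3 kernels, stride 1 and 32-unit dense blocks (default `TRUE`).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(branches = NULL, n_classes = 4L, dropout = 0.4,
                          weight_decay = 1e-4, seed = 1L, n_filters = 16L,
                          pooling = c("max", "avg"), paper_faithful = TRUE) {
  pooling <- match.arg(pooling)
  if (is.null(branches))
    branches <- lapply(.canonical_blocks, function(bd)
      branch_spec(bd[1], bd[2], n_filters = n_filters, pooling = pooling))
  if (paper_faithful) {
    if (length(branches) != 5L)
      stop("paper-faithful mode requires exactly 5 branches", call. = FALSE)
    for (i in seq_len(5L)) {
      b <- branches[[i]]; want <- .canonical_blocks[[i]]
      if (b$n_conv_blocks != want[1] || b$n_dense_blocks != want[2])
        stop("paper-faithful mode: branch ", i, " must have (",
             want[1], ",", want[2], ") conv/dense blocks", call. = FALSE)
      if (!identical(b$kernel, c(3L, 3L)) || b$stride != 1L ||
          b$dense_width != 32L)
        stop("paper-faithful mode: branch ", i,
             " must use 3x3 kernels, stride 1 and 32-unit dense blocks",
             call. = FALSE)
    }
  }
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must lie in [0, 1)", call. = FALSE)
  structure(list(branches = branches, n_classes = as.integer(n_classes),
                 dropout = dropout, weight_decay = weight_decay,
                 seed = as.integer(seed), paper_faithful = paper_faithful),
            class = "fusion_config")
}

#' Build one branch and emit its layer-by-layer shape trace
#'
#' @param spec a [branch_spec()].
#' @param input_shape `c(rows, cols)` of the 2-D feature map.
#' @return list with `blocks` (per-conv-block output shapes and pooling
#'   windows), `flat_len`, `trace` (data frame of layer, output shape,
#'   parameter count) and `n_params`.
#' @export
build_branch <- function(spec, input_shape) {
  h <- input_shape[1]; w <- input_shape[2]; c <- 1L
  trace <- list(); blocks <- list(); n_par <- 0L
  add <- function(layer, shape, params)
    trace[[length(trace) + 1L]] <<- data.frame(layer = layer,
                                               output_shape = shape,
                                               params = params)
  add("input", sprintf("%dx%dx%d", h, w, c), 0L)
  for (b in seq_len(spec$n_conv_blocks)) {
    np <- prod(spec$kernel) * c * spec$n_filters + spec$n_filters
    c_out <- spec$n_filters
    add(sprintf("conv%d (3x3/1, tanh)", b), sprintf("%dx%dx%d", h, w, c_out), np)
    pool <- if (h > 1L && w > 1L) c(2L, 2L) else c(1L, 2L)
    h2 <- h %/% pool[1]; w2 <- w %/% pool[2]
    if (h2 < 1L || w2 < 1L)
      stop("conv block ", b, ": input ", h, "x", w,
           " too small for the pooling schedule", call. = FALSE)
    blocks[[b]] <- list(in_shape = c(h, w, c), out_shape = c(h2, w2, c_out),
                        pool = pool)
    add(sprintf("%spool%d (%dx%d)", spec$pooling, b, pool[1], pool[2]),
        sprintf("%dx%dx%d", h2, w2, c_out), 0L)
    h <- h2; w <- w2; c <- c_out
    n_par <- n_par + np
  }
  flat <- h * w * c
  add("flatten", as.character(flat), 0L)
  d_in <- flat
  dense <- list()
  for (b in seq_len(spec$n_dense_blocks)) {
    np <- d_in * spec$dense_width + spec$dense_width
    dense[[b]] <- c(d_in, spec$dense_width)
    add(sprintf("dense%d (tanh)", b), as.character(spec$dense_width), np)
    d_in <- spec$dense_width
    n_par <- n_par + np
  }
  list(spec = spec, input_shape = input_shape, blocks = blocks,
       flat_len = flat, dense = dense, out_width = d_in,
       trace = do.call(rbind, trace), n_params = n_par)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Build the five-branch fusion network
#'
#' Constructs all branches, concatenates their final dense activations,
#' applies dropout, and maps through one dense softmax layer. Weights are
#' Glorot-uniform initialized from `config$seed`.
#'
#' @param config a [fusion_config()].
#' @param input_shape `c(rows, cols)` of the feature maps.
#' @return An object of class `fusion_model` with the per-branch shape
#'   traces, the flat parameter list and the total trainable parameter count.
#' @export
build_fusion <- function(config, input_shape) {
  branches <- lapply(config$branches, build_branch, input_shape = input_shape)
  concat_width <- sum(vapply(branches, `[[`, integer(1), "out_width"))
  params <- list()
  with_preserved_rng({
    set.seed(config$seed)
    for (i in seq_along(branches)) {
      br <- branches[[i]]; sp <- br$spec
      for (b in seq_along(br$blocks)) {
        cin <- br$blocks[[b]]$in_shape[3]
        kd <- c(sp$kernel, cin, sp$n_filters)
        params[[sprintf("b%d.conv%d.W", i, b)]] <-
          glorot(kd, prod(sp$kernel) * cin, prod(sp$kernel) * sp$n_filters)
        params[[sprintf("b%d.conv%d.b", i, b)]] <- numeric(sp$n_filters)
      }
      for (b in seq_along(br$dense)) {
        dd <- br$dense[[b]]
        params[[sprintf("b%d.dense%d.W", i, b)]] <-
          matrix(glorot(c(dd[2], dd[1]), dd[1], dd[2]), dd[2], dd[1])
        params[[sprintf("b%d.dense%d.b", i, b)]] <- numeric(dd[2])
      }
    }
    params[["head.W"]] <- matrix(glorot(c(config$n_classes, concat_width),
                                        concat_width, config$n_classes),
                                 config$n_classes, concat_width)
    params[["head.b"]] <- numeric(config$n_classes)
  })
  n_params <- sum(vapply(params, length, integer(1)))
  structure(list(config = config, input_shape = as.integer(input_shape),
                 branches = branches, concat_width = concat_width,
                 params = params, n_params = n_params),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %d branches on %dx%d maps, concat width %d, %d classes, %s parameters\n",
              length(x$branches), x$input_shape[1], x$input_shape[2],
              x$concat_width, x$config$n_classes,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Print the per-layer shape trace of every branch
#'
#' @param model a [build_fusion()] result.
#' @return the combined trace data frame, invisibly.
#' @export
model_describe <- function(model) {
  out <- list()
  for (i in seq_along(model$branches)) {
    tr <- model$branches[[i]]$trace
    tr$branch <- i
    cat(sprintf("branch %d (%d conv, %d dense blocks):\n", i,
                model$branches[[i]]$spec$n_conv_blocks,
                model$branches[[i]]$spec$n_dense_blocks))
    print(tr[, c("layer", "output_shape", "params")], row.names = FALSE)
    out[[i]] <- tr
  }
  cat(sprintf("concat width %d -> dropout -> dense(%d, softmax); total params %d\n",
              model$concat_width, model$config$n_classes, model$n_params))
  invisible(do.call(rbind, out))
}

# ---- forward / backward ----------------------------------------------------

pool_fwd <- function(x, pool, type) {
  if (type == "max") nn_maxpool_fwd(x, pool[1], pool[2])
  else list(out = nn_avgpool_fwd(x, pool[1], pool[2]), idx = NULL)
}

pool_bwd <- function(dout, cache_blk, type) {
  hw <- cache_blk$in_dims
  if (type == "max") nn_maxpool_bwd(dout, cache_blk$idx, hw[1], hw[2])
  else nn_avgpool_bwd(dout, hw[1], hw[2], cache_blk$pool[1], cache_blk$pool[2])
}

branch_forward <- function(model, i, X4, keep_cache = FALSE) {
  br <- model$branches[[i]]; p <- model$params
  type <- br$spec$pooling
  cache <- list(conv = list(), dense = list())
  x <- X4
  for (b in seq_along(br$blocks)) {
    W <- p[[sprintf("b%d.conv%d.W", i, b)]]
    a <- nn_conv2d_fwd(x, W, p[[sprintf("b%d.conv%d.b", i, b)]],
                       tanh_act = TRUE)
    pl <- pool_fwd(a, br$blocks[[b]]$pool, type)
    if (keep_cache)
      cache$conv[[b]] <- list(x = x, a = a, idx = pl$idx,
                              in_dims = dim(a)[1:2], pool = br$blocks[[b]]$pool)
    x <- pl$out
  }
  N <- dim(x)[4]
  h <- matrix(x, nrow = br$flat_len, ncol = N)   # column-major flatten
  if (keep_cache) cache$flat_dims <- dim(x)
  for (b in seq_along(br$dense)) {
    W <- p[[sprintf("b%d.dense%d.W", i, b)]]
    zz <- W %*% h + p[[sprintf("b%d.dense%d.b", i, b)]]
    aa <- tanh(zz)
    if (keep_cache) cache$dense[[b]] <- list(h_in = h, a = aa)
    h <- aa
  }
  list(out = h, cache = cache)
}

branch_backward <- function(model, i, dout, cache, grads) {
  br <- model$branches[[i]]; p <- model$params
  type <- br$spec$pooling
  dh <- dout
  for (b in rev(seq_along(br$dense))) {
    cb <- cache$dense[[b]]
    dz <- dh * (1 - cb$a^2)
    grads[[sprintf("b%d.dense%d.W", i, b)]] <- tcrossprod(dz, cb$h_in)
    grads[[sprintf("b%d.dense%d.b", i, b)]] <- rowSums(dz)
    dh <- crossprod(p[[sprintf("b%d.dense%d.W", i, b)]], dz)
  }
  dx <- array(dh, cache$flat_dims)
  for (b in rev(seq_along(cache$conv))) {
    cb <- cache$conv[[b]]
    da <- pool_bwd(dx, cb, type)
    dz <- da * (1 - cb$a^2)
    g <- nn_conv2d_bwd(cb$x, p[[sprintf("b%d.conv%d.W", i, b)]], dz)
    grads[[sprintf("b%d.conv%d.W", i, b)]] <- g$dk
    grads[[sprintf("b%d.conv%d.b", i, b)]] <- g$db
    dx <- g$dx
  }
  grads
}

# maps: n x rows x cols array -> (rows, cols, 1, n) input tensor
maps_to_tensor <- function(x) {
  d <- dim(x)
  X4 <- aperm(x, c(2, 3, 1))
  dim(X4) <- c(d[2], d[3], 1L, d[1])
  X4
}

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

# full forward pass; returns class probabilities (n_classes x N) and caches
fusion_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  X4 <- maps_to_tensor(x)
  N <- dim(X4)[4]
  outs <- vector("list", length(model$branches))
  caches <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    f <- branch_forward(model, i, X4, keep_cache)
    outs[[i]] <- f$out; caches[[i]] <- f$cache
  }
  Z <- do.call(rbind, outs)
  mask <- NULL
  if (train && model$config$dropout > 0) {
    keep <- 1 - model$config$dropout
    mask <- matrix((stats::runif(length(Z)) < keep) / keep, nrow(Z), ncol(Z))
    Z <- Z * mask
  }
  logits <- model$params[["head.W"]] %*% Z + model$params[["head.b"]]
  list(proba = softmax_cols(logits), Z = Z, mask = mask,
       caches = caches, n = N)
}

# gradients of mean cross-entropy (+ weight decay) given a forward cache
fusion_backward <- function(model, fwd, y01) {
  N <- fwd$n
  dlogits <- (fwd$proba - y01) / N
  grads <- list()
  grads[["head.W"]] <- tcrossprod(dlogits, fwd$Z)
  grads[["head.b"]] <- rowSums(dlogits)
  dZ <- crossprod(model$params[["head.W"]], dlogits)
  if (!is.null(fwd$mask)) dZ <- dZ * fwd$mask
  row0 <- 0L
  for (i in seq_along(model$branches)) {
    w <- model$branches[[i]]$out_width
    grads <- branch_backward(model, i, dZ[row0 + seq_len(w), , drop = FALSE],
                             fwd$caches[[i]], grads)
    row0 <- row0 + w
  }
  wd <- model$config$weight_decay
  if (wd > 0)
    for (nm in names(grads))
      if (endsWith(nm, ".W"))
        grads[[nm]] <- grads[[nm]] + wd * model$params[[nm]]
  grads
}

#' Class probabilities for feature maps
#'
#' @param model a (trained) [build_fusion()] model.
#' @param feature_maps a [build_feature_map()] result, or a bare
#'   `n x rows x cols` array.
#' @param batch_size forward-pass chunk size (default 64).
#' @return row-stochastic `n x n_classes` probability matrix.
#' @export
predict_proba <- function(model, feature_maps, batch_size = 64L) {
  x <- if (is.list(feature_maps)) feature_maps$map else feature_maps
  d <- dim(x)
  if (length(d) != 3L || d[2] != model$input_shape[1] ||
      d[3] != model$input_shape[2])
    stop("feature map shape ", paste(d[-1], collapse = "x"),
         " does not match model input ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  out <- matrix(0, d[1], model$config$n_classes)
  for (s in seq(1L, d[1], by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, d[1])
    fwd <- fusion_forward(model, x[idx, , , drop = FALSE])
    out[idx, ] <- t(fwd$proba)
  }
  out
}

#' Predicted class codes (0-based) for feature maps
#' @inheritParams predict_proba
#' @return integer vector of 0-based class codes.
#' @export
predict_classes <- function(model, feature_maps, batch_size = 64L) {
  max.col(predict_proba(model, feature_maps, batch_size)) - 1L
}
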