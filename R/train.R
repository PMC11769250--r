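# Training loop (Adam + cross-entropy), noise augmentation, grid search and
# the evaluation surfaces: confusion matrix, per-class precision/recall/F1,
# and accuracy/loss histories.

#' Training configuration and hyperparameter grids
#'
#' Defaults instantiate the tuning grids: learning rates spanning
#' 0.001-0.01, batch sizes 16/32/64, dropout 0.3-0.5.
#'
#' @param lr_grid learning-rate candidates (default `c(0.001, 0.005, 0.01)`).
#' @param batch_grid batch-size candidates (default `c(16, 32, 64)`).
#' @param dropout_grid dropout candidates (default `c(0.3, 0.4, 0.5)`).
#' @param epochs training epochs per fit (default 100).
#' @param cv_folds stratified folds for [grid_search()] (default 3, >= 2).
#' @param augment_noise_sigma augmentation noise std in units of per-channel
#'   signal std (default 0.1).
#' @param seed integer seed (default 1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_grid = c(0.001, 0.005, 0.01),
                         batch_grid = c(16L, 32L, 64L),
                         dropout_grid = c(0.3, 0.4, 0.5),
                         epochs = 100L, cv_folds = 3L,
                         augment_noise_sigma = 0.1, seed = 1L) {
  if (length(lr_grid) == 0 || length(batch_grid) == 0 ||
      length(dropout_grid) == 0)
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  if (any(lr_grid <= 0)) stop("learning rates must be positive", call. = FALSE)
  if (cv_folds < 2) stop("`cv_folds` must be >= 2", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (augment_noise_sigma < 0)
    stop("`augment_noise_sigma` must be non-negative", call. = FALSE)
  structure(list(lr_grid = lr_grid, batch_grid = as.integer(batch_grid),
                 dropout_grid = dropout_grid, epochs = as.integer(epochs),
                 cv_folds = as.integer(cv_folds),
                 augment_noise_sigma = augment_noise_sigma,
                 seed = as.integer(seed)), class = "train_config")
}

#' Additive Gaussian noise augmentation
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `sigma * sd(channel)` (per-channel std over the whole set) to every
#' epoch. Labels are untouched. Meant for training folds only.
#'
#' @param epochs an [epoch_set()].
#' @param sigma noise scale (>= 0); 0 returns the input unchanged.
#' @param seed integer seed.
#' @return The perturbed [epoch_set()].
#' @export
augment_noise <- function(epochs, sigma, seed = 1L) {
  epochs <- validate_epoch_set(epochs)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (sigma == 0) return(epochs)
  d <- dim(epochs$data)
  ch_sd <- apply(epochs$data, 2, stats::sd)
  with_preserved_rng({
    set.seed(seed)
    noise <- array(stats::rnorm(prod(d)), d)
    for (ch in seq_len(d[2L]))
      epochs$data[, ch, ] <- epochs$data[, ch, ] +
        sigma * ch_sd[ch] * noise[, ch, ]
  })
  epochs
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

onehot <- function(labels, n_classes) {
  Y <- matrix(0, n_classes, length(labels))
  Y[cbind(labels + 1L, seq_along(labels))] <- 1
  Y
}

eval_loss_acc <- function(model, fmap, batch_size = 64L) {
  p <- predict_proba(model, fmap, batch_size)
  y <- fmap$labels
  loss <- -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
  acc <- mean(max.col(p) - 1L == y)
  c(loss = loss, acc = acc)
}

#' Train a fusion model on feature maps
#'
#' Minimizes mean categorical cross-entropy (plus the model's weight decay)
#' with the Adam optimizer on shuffled mini-batches, recording per-epoch
#' training and validation accuracy and loss. Fully seeded: identical
#' data, configuration and seed reproduce the identical history.
#'
#' @param model a [build_fusion()] model.
#' @param fmap a labelled [build_feature_map()] result.
#' @param epochs training epochs (default 100).
#' @param lr learning rate (default 0.001).
#' @param batch_size mini-batch size (default 32).
#' @param seed integer seed for shuffling and dropout (default 1).
#' @param validation optional held-out `feature_map` scored each epoch.
#' @param verbose print per-epoch progress (default `FALSE`).
#' @return list with the trained `model` and `history` (data frame of epoch,
#'   train/val loss and accuracy).
#' @export
train <- function(model, fmap, epochs = 100L, lr = 0.001, batch_size = 32L,
                  seed = 1L, validation = NULL, verbose = FALSE) {
  x <- fmap$map; y <- fmap$labels
  n <- dim(x)[1]
  if (length(y) != n) stop("feature maps carry no labels", call. = FALSE)
  state <- adam_init(model$params)
  hist <- vector("list", epochs)
  with_preserved_rng({
    set.seed(seed)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (s in seq(1L, n, by = batch_size)) {
        idx <- perm[s:min(s + batch_size - 1L, n)]
        xb <- x[idx, , , drop = FALSE]
        yb <- y[idx]
        fwd <- fusion_forward(model, xb, train = TRUE, keep_cache = TRUE)
        pb <- pmax(fwd$proba[cbind(yb + 1L, seq_along(idx))], 1e-12)
        loss <- -mean(log(pb))
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               " with lr=", lr, ", batch_size=", batch_size, call. = FALSE)
        tot_loss <- tot_loss + loss * length(idx)
        tot_correct <- tot_correct +
          sum(max.col(t(fwd$proba)) - 1L == yb)
        grads <- fusion_backward(model, fwd, onehot(yb, model$config$n_classes))
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params; state <- upd$state
      }
      row <- data.frame(epoch = ep, train_loss = tot_loss / n,
                        train_acc = tot_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(validation)) {
        va <- eval_loss_acc(model, validation)
        row$val_loss <- va["loss"]; row$val_acc <- va["acc"]
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", ep, row$train_loss,
                        row$train_acc,
                        if (!is.null(validation))
                          sprintf("  val_acc %.3f", row$val_acc) else ""))
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' Confusion matrix and per-class precision/recall/F1
#'
#' @param true true class codes (0-based).
#' @param pred predicted class codes (0-based).
#' @param n_classes number of classes (default 4).
#' @return An object of class `mi_metrics`: `confusion` (rows = true,
#'   cols = predicted), `per_class` data frame with precision/recall/F1 and
#'   zero-division flags (metrics defined as 0 when their denominator is 0),
#'   macro averages, `accuracy` and `n`.
#' @export
compute_metrics <- function(true, pred, n_classes = 4L) {
  if (length(true) == 0) stop("empty evaluation set", call. = FALSE)
  if (length(true) != length(pred))
    stop("`true` and `pred` lengths differ", call. = FALSE)
  lv <- seq_len(n_classes) - 1L
  confusion <- table(factor(true, levels = lv), factor(pred, levels = lv))
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(true = lv, pred = lv))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  div0 <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = lv, precision = precision, recall = recall,
                          f1 = f1,
                          precision_undefined = (tp + fp) == 0,
                          recall_undefined = (tp + fn) == 0)
  structure(list(confusion = confusion, per_class = per_class,
                 macro_precision = mean(precision), macro_recall = mean(recall),
                 macro_f1 = mean(f1), accuracy = sum(tp) / length(true),
                 n = length(true)), class = "mi_metrics")
}

#' @export
print.mi_metrics <- function(x, ...) {
  cat(sprintf("<mi_metrics> n=%d  accuracy %.3f  macro P/R/F1 %.3f/%.3f/%.3f\n",
              x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained model on labelled feature maps
#'
#' @param model a trained [build_fusion()] model.
#' @param fmap a labelled [build_feature_map()] result.
#' @return An `mi_metrics` object (see [compute_metrics()]).
#' @export
evaluate <- function(model, fmap) {
  if (dim(fmap$map)[1] == 0) stop("empty evaluation set", call. = FALSE)
  compute_metrics(fmap$labels, predict_classes(model, fmap),
                  model$config$n_classes)
}

#' Majority vote over the windows of each trial
#'
#' @param proba `n_windows x n_classes` probability matrix.
#' @param provenance data frame with a `trial_id` column aligned with the
#'   rows of `proba`.
#' @param true_labels optional per-window true labels, reduced per trial.
#' @return data frame with one row per trial: `trial_id`, `pred` (majority
#'   class, ties broken by mean probability) and `true` if labels given.
#' @export
window_vote <- function(proba, provenance, true_labels = NULL) {
  if (is.null(provenance$trial_id))
    stop("`provenance` must have a `trial_id` column", call. = FALSE)
  if (nrow(proba) != nrow(provenance))
    stop("probability rows do not match provenance rows", call. = FALSE)
  trials <- unique(provenance$trial_id)
  pred <- integer(length(trials)); tru <- integer(length(trials))
  for (k in seq_along(trials)) {
    idx <- which(provenance$trial_id == trials[k])
    votes <- tabulate(max.col(proba[idx, , drop = FALSE]), ncol(proba))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      mp <- colMeans(proba[idx, top, drop = FALSE])
      top <- top[which.max(mp)]
    }
    pred[k] <- top - 1L
    if (!is.null(true_labels)) tru[k] <- true_labels[idx[1L]]
  }
  out <- data.frame(trial_id = trials, pred = pred)
  if (!is.null(true_labels)) out$true <- tru
  out
}

# stratified fold assignment at the trial level: every window of a trial
# lands in the same fold, folds are class-balanced
trial_folds <- function(epochs, k, seed) {
  pv <- epochs$provenance
  trials <- unique(pv$trial_id)
  t_label <- epochs$labels[match(trials, pv$trial_id)]
  fold_of <- integer(length(trials))
  with_preserved_rng({
    set.seed(seed)
    for (cl in unique(t_label)) {
      idx <- sample(which(t_label == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_of[match(pv$trial_id, trials)]
}

#' Grid search over learning rate, batch size and dropout
#'
#' Stratified k-fold cross-validation over the full Cartesian grid. Folds
#' are assigned per TRIAL so windows of one trial never straddle a split;
#' CSP and the feature scaler are fitted on each fold's training part only.
#' Ties in mean validation accuracy are broken toward smaller learning
#' rate, then smaller batch, then larger dropout.
#'
#' @param data an [epoch_set()] of windows (preprocessed, EEG only).
#' @param config a [train_config()] carrying the grids, `cv_folds` and the
#'   per-candidate epoch budget.
#' @param model_config a [fusion_config()] template; its dropout is
#'   overridden by each candidate.
#' @param csp_pairs CSP filter pairs per class (default 2).
#' @param wpd a [wpd_spec()] or `NULL` (default [wpd_spec()]).
#' @param time_decim feature-map time decimation (default 1).
#' @return list with `best` (named list lr/batch_size/dropout), `table`
#'   (full CV table with mean validation accuracy) and `cv_folds`.
#' @export
grid_search <- function(data, config, model_config = fusion_config(),
                        csp_pairs = 2L, wpd = wpd_spec(), time_decim = 1L) {
  data <- validate_epoch_set(data)
  k <- config$cv_folds
  counts <- table(data$labels[!duplicated(data$provenance$trial_id)])
  if (any(counts < k))
    stop("every class needs at least `cv_folds` trials", call. = FALSE)
  folds <- trial_folds(data, k, config$seed)
  grid <- expand.grid(lr = config$lr_grid, batch_size = config$batch_grid,
                      dropout = config$dropout_grid,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- matrix(0, nrow(grid), k)
  for (f in seq_len(k)) {
    tr <- epoch_subset(data, which(folds != f))
    va <- epoch_subset(data, which(folds == f))
    csp <- csp_fit(tr, n_pairs = csp_pairs)
    fm_tr <- build_feature_map(tr, csp, wpd, time_decim)
    fm_va <- build_feature_map(va, csp, wpd, time_decim,
                               scaler = fm_tr$scaler)
    shape <- dim(fm_tr$map)[2:3]
    for (g in seq_len(nrow(grid))) {
      mc <- model_config
      mc$dropout <- grid$dropout[g]
      mdl <- build_fusion(mc, shape)
      fit <- train(mdl, fm_tr, epochs = config$epochs, lr = grid$lr[g],
                   batch_size = grid$batch_size[g], seed = config$seed + f)
      acc[g, f] <- eval_loss_acc(fit$model, fm_va)["acc"]
    }
  }
  grid$mean_val_acc <- rowMeans(acc)
  list(best = pick_best_candidate(grid), table = grid, cv_folds = k)
}

# argmax mean validation accuracy; ties broken toward smaller lr, then
# smaller batch, then larger dropout
pick_best_candidate <- function(grid) {
  ord <- order(-grid$mean_val_acc, grid$lr, grid$batch_size, -grid$dropout)
  best <- grid[ord[1L], ]
  list(lr = best$lr, batch_size = best$batch_size, dropout = best$dropout)
}
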