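## Per-trial classifiers: a 3-feature multilayer perceptron and a small
## 2-channel CNN, trained with Adam on softmax cross-entropy, a
## participant-level 8:2 train/validation split, and early stopping on the
## validation loss (best-epoch weights restored).

#' Architecture configuration
#'
#' `"baseline"` is an MLP with three hidden layers of 5 units on the three
#' trial features (fixation-sample total, saccade count, scan-path length).
#' `"cnn"` is two 3x3 convolution layers (8 then 16 filters), each followed
#' by ReLU and 2x2 max pooling, and a fully connected 2-logit output, on
#' the 2-channel square model input.
#'
#' @param kind `"baseline"` or `"cnn"`.
#' @param input_side side of the square CNN input (default 34).
#' @param in_channels,f1,f2 CNN channel/filter counts.
#' @return An `arch_config` list.
#' @export
arch_config <- function(kind = c("baseline", "cnn"), input_side = 34L,
                        in_channels = 2L, f1 = 8L, f2 = 16L) {
  kind <- match.arg(kind)
  if (kind == "baseline") {
    return(structure(list(kind = kind, widths = c(3L, 5L, 5L, 5L, 2L)),
                     class = "arch_config"))
  }
  H1 <- input_side - 2L
  P1 <- H1 %/% 2L
  H2 <- P1 - 2L
  P2 <- H2 %/% 2L
  stopifnot(P2 >= 1)
  structure(list(kind = kind, C0 = in_channels, S0 = as.integer(input_side),
                 F1 = as.integer(f1), F2 = as.integer(f2), K = 3L,
                 H1 = H1, P1 = P1, H2 = H2, P2 = P2,
                 fc_in = as.integer(f2) * P2 * P2),
            class = "arch_config")
}

#' Training protocol configuration
#'
#' @param max_epochs maximum training epochs (default 300).
#' @param early_stop_patience stop when the validation loss has not improved
#'   for this many epochs (default 15); the best-epoch weights are restored.
#' @param lr_grid candidate Adam learning rates for nested selection.
#' @param val_fraction fraction of *participants* held out for validation
#'   (default 0.2, stratified by group).
#' @param batch_size Adam minibatch size.
#' @param seed RNG seed; training is reproducible given the seed.
#' @param inner_fold_cap maximum number of inner leave-one-participant-out
#'   folds used for learning-rate selection (`Inf` = all).
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 300L, early_stop_patience = 15L,
                         lr_grid = c(1e-2, 1e-3, 1e-4), val_fraction = 0.2,
                         batch_size = 64L, seed = 1L, inner_fold_cap = Inf) {
  stopifnot(early_stop_patience < max_epochs, length(lr_grid) >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_grid = sort(lr_grid), val_fraction = val_fraction,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 inner_fold_cap = inner_fold_cap),
            class = "train_config")
}

## ---- parameter init ----

.he_mat <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

.init_params <- function(arch) {
  if (arch$kind == "baseline") {
    w <- arch$widths
    p <- list()
    for (i in seq_len(length(w) - 1)) {
      p[[paste0("W", i)]] <- .he_mat(w[i + 1], w[i])
      p[[paste0("b", i)]] <- numeric(w[i + 1])
    }
    return(p)
  }
  list(W1 = .he_mat(arch$F1, arch$C0 * arch$K^2), b1 = numeric(arch$F1),
       W2 = .he_mat(arch$F2, arch$F1 * arch$K^2), b2 = numeric(arch$F2),
       W3 = .he_mat(2, arch$fc_in), b3 = numeric(2))
}

## ---- forward / backward ----

.fw_baseline <- function(params, X) {
  nl <- length(params) / 2
  A <- X
  cache <- list(A0 = X)
  for (i in seq_len(nl)) {
    Z <- params[[paste0("W", i)]] %*% A + params[[paste0("b", i)]]
    if (i < nl) {
      A <- pmax(Z, 0)
      cache[[paste0("Z", i)]] <- Z
      cache[[paste0("A", i)]] <- A
    } else {
      cache$logits <- Z
    }
  }
  cache
}

.bw_baseline <- function(params, cache, dZ) {
  nl <- length(params) / 2
  g <- list()
  for (i in nl:1) {
    A_prev <- if (i == 1) cache$A0 else cache[[paste0("A", i - 1)]]
    g[[paste0("W", i)]] <- dZ %*% t(A_prev)
    g[[paste0("b", i)]] <- rowSums(dZ)
    if (i > 1) {
      dA <- t(params[[paste0("W", i)]]) %*% dZ
      dZ <- dA * (cache[[paste0("Z", i - 1)]] > 0)
    }
  }
  g
}

## slice the precomputed layer-1 im2col matrix down to samples `idx`
## (each sample owns P contiguous columns)
.slice_cols1 <- function(cols1, idx, P) {
  cpp_slice_cols(cols1, as.integer(idx), as.integer(P))
}

.fw_cnn <- function(params, X, arch, keep_cache = TRUE, cols1 = NULL) {
  a <- arch
  if (is.null(cols1)) cols1 <- cpp_im2col(X, a$C0, a$S0, a$S0, a$K, a$K)
  n <- ncol(cols1) / a$H1^2
  Z1 <- cpp_gemm_nn_bias(params$W1, cols1, params$b1)
  A1 <- cpp_relu(Z1)
  dim(A1) <- c(a$F1 * a$H1^2, n)
  p1 <- cpp_maxpool(A1, a$F1, a$H1, a$H1)
  cols2 <- cpp_im2col(p1$out, a$F1, a$P1, a$P1, a$K, a$K)
  Z2 <- cpp_gemm_nn_bias(params$W2, cols2, params$b2)
  A2 <- cpp_relu(Z2)
  dim(A2) <- c(a$F2 * a$H2^2, n)
  p2 <- cpp_maxpool(A2, a$F2, a$H2, a$H2)
  logits <- params$W3 %*% p2$out + params$b3
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, cols1 = cols1, Z1 = Z1, p1 = p1,
       cols2 = cols2, Z2 = Z2, p2 = p2, n = n)
}

.bw_cnn <- function(params, cache, dZ, arch) {
  a <- arch
  n <- cache$n
  g <- list()
  g$W3 <- tcrossprod(dZ, cache$p2$out)
  g$b3 <- rowSums(dZ)
  dP2 <- crossprod(params$W3, dZ)
  dA2 <- cpp_maxpool_bw(dP2, cache$p2$argmax, a$F2, a$H2, a$H2)
  dZ2 <- cpp_relu_bw(dA2, cache$Z2)  # same element order; modifies dA2
  dim(dZ2) <- c(a$F2, n * a$H2^2)
  g$W2 <- cpp_gemm_nt(dZ2, cache$cols2)
  g$b2 <- cpp_row_sums(dZ2)
  dP1 <- cpp_col2im(cpp_gemm_nn_bias(t(params$W2), dZ2, numeric(ncol(params$W2))),
                    a$F1, a$P1, a$P1, a$K, a$K, n)
  dA1 <- cpp_maxpool_bw(dP1, cache$p1$argmax, a$F1, a$H1, a$H1)
  dZ1 <- cpp_relu_bw(dA1, cache$Z1)
  dim(dZ1) <- c(a$F1, n * a$H1^2)
  g$W1 <- cpp_gemm_nt(dZ1, cache$cols1)
  g$b1 <- cpp_row_sums(dZ1)
  g
}

.net_forward <- function(model, X, keep_cache = FALSE, cols1 = NULL) {
  if (model$arch$kind == "baseline") {
    .fw_baseline(model$params, X)
  } else {
    .fw_cnn(model$params, X, model$arch, keep_cache = keep_cache,
            cols1 = cols1)
  }
}

## softmax cross-entropy; y in {0,1}; optional per-class weights
## (inverse class frequency) so imbalanced LOPO folds do not teach the
## model the class prior
.softmax_ce <- function(logits, y, class_w = c(1, 1)) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  n <- ncol(logits)
  idx <- cbind(y + 1L, seq_len(n))
  w <- class_w[y + 1L]
  sw <- sum(w)
  loss <- -sum(w * log(pmax(p[idx], 1e-12))) / sw
  dZ <- p
  dZ[idx] <- dZ[idx] - 1
  dZ <- sweep(dZ, 2, w / sw, "*")
  list(loss = loss, dZ = dZ, prob = p)
}

.forward_loss <- function(model, X, y, chunk = 512L, cols1 = NULL,
                          class_w = c(1, 1)) {
  n <- if (is.null(X)) length(y) else ncol(X)
  P <- if (model$arch$kind == "cnn") model$arch$H1^2 else 0L
  total <- 0
  wtot <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    cb <- if (!is.null(cols1)) .slice_cols1(cols1, s:e, P)
    xb <- if (!is.null(X)) X[, s:e, drop = FALSE]
    logits <- .net_forward(model, xb, cols1 = cb)$logits
    wb <- sum(class_w[y[s:e] + 1L])
    total <- total + .softmax_ce(logits, y[s:e], class_w)$loss * wb
    wtot <- wtot + wb
  }
  total / wtot
}

## ---- Adam ----

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mh <- state$m[[k]] / (1 - beta1^state$t)
    vh <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

## participant-level stratified 8:2 split; returns validation participant ids
.val_participants <- function(participant_id, y) {
  plab <- tapply(y, participant_id, function(v) v[1])
  val <- character(0)
  for (cl in unique(plab)) {
    ids <- names(plab)[plab == cl]
    n_val <- max(1L, round(0.2 * length(ids)))
    if (n_val >= length(ids)) n_val <- length(ids) - 1L
    if (n_val >= 1) val <- c(val, sample(ids, n_val))
  }
  val
}

#' Train a per-trial classifier
#'
#' Adam on softmax cross-entropy with a participant-level stratified 8:2
#' train/validation split, at most `max_epochs` epochs and early stopping
#' after `early_stop_patience` epochs without validation-loss improvement;
#' the best-validation weights are restored. Deterministic under
#' `cfg$seed`.
#'
#' @param x `d x n` matrix of model inputs (columns = trials).
#' @param y integer 0/1 labels per trial (1 = disorder).
#' @param participant_id participant of each trial.
#' @param arch an [arch_config()].
#' @param cfg a [train_config()].
#' @param lr Adam learning rate; if `NULL`, selected by
#'   [select_learning_rate()].
#' @return A `trial_model` list with `params`, `arch`, `lr` and a per-epoch
#'   `log` data frame (`epoch, train_loss, val_loss`).
#' @export
train_trial_model <- function(x, y, participant_id, arch, cfg = train_config(),
                              lr = NULL, cols1 = NULL) {
  y <- as.integer(y)
  stopifnot(ncol(x) == length(y), length(participant_id) == length(y))
  if (length(unique(y)) < 2) stop("training data contains a single class")
  if (length(unique(participant_id)) < 2) stop("need >= 2 training participants")
  if (is.null(lr)) {
    lr <- if (length(cfg$lr_grid) == 1) cfg$lr_grid else
      select_learning_rate(x, y, participant_id, arch, cfg, cols1 = cols1)
  }
  is_cnn <- arch$kind == "cnn"
  if (is_cnn && is.null(cols1)) {
    cols1 <- cpp_im2col(x, arch$C0, arch$S0, arch$S0, arch$K, arch$K)
  }
  set.seed(cfg$seed)
  val_ids <- .val_participants(participant_id, y)
  is_val <- participant_id %in% val_ids
  tr_idx <- which(!is_val)
  va_idx <- which(is_val)
  if (!length(va_idx)) {  # degenerate pool: validate on the training set
    tr_idx <- seq_along(y)
    va_idx <- seq_along(y)
  }
  Xtr <- x[, tr_idx, drop = FALSE]; ytr <- y[tr_idx]
  Xva <- x[, va_idx, drop = FALSE]; yva <- y[va_idx]
  if (is_cnn) {
    P <- arch$H1^2
    Ctr <- .slice_cols1(cols1, tr_idx, P)
    Cva <- .slice_cols1(cols1, va_idx, P)
  }

  params <- .init_params(arch)
  state <- list(t = 0, m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  model <- list(params = params, arch = arch)
  best <- list(loss = Inf, params = params)
  stall <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  ntr <- ncol(Xtr)
  ## inverse-class-frequency loss weights: LOPO folds are mildly imbalanced
  ## and unweighted training would teach the net the class prior
  cw <- as.numeric(ntr / (2 * pmax(tabulate(ytr + 1L, 2L), 1L)))
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(ntr)
    batch_losses <- numeric(0)
    for (s in seq(1, ntr, by = cfg$batch_size)) {
      bi <- ord[s:min(ntr, s + cfg$batch_size - 1L)]
      if (arch$kind == "baseline") {
        cache <- .fw_baseline(model$params, Xtr[, bi, drop = FALSE])
        ce <- .softmax_ce(cache$logits, ytr[bi], cw)
        grads <- .bw_baseline(model$params, cache, ce$dZ)
      } else {
        cache <- .fw_cnn(model$params, NULL, arch,
                         cols1 = .slice_cols1(Ctr, bi, P))
        ce <- .softmax_ce(cache$logits, ytr[bi], cw)
        grads <- .bw_cnn(model$params, cache, ce$dZ, arch)
      }
      batch_losses <- c(batch_losses, ce$loss)
      upd <- .adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
    }
    ## train loss is the running minibatch mean; validation loss is exact
    tr_loss <- mean(batch_losses)
    va_loss <- if (is_cnn) .forward_loss(model, NULL, yva, cols1 = Cva,
                                         class_w = cw)
               else .forward_loss(model, Xva, yva, class_w = cw)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                 val_loss = va_loss))
    if (va_loss < best$loss - 1e-9) {
      best <- list(loss = va_loss, params = model$params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  structure(list(params = best$params, arch = arch, lr = lr,
                 best_val_loss = best$loss, log = log,
                 val_participants = val_ids),
            class = "trial_model")
}

#' Nested learning-rate selection
#'
#' Inner leave-one-participant-out cross-validation over the training
#' participants for each candidate rate; the rate with the best mean inner
#' accuracy wins, ties going to the smallest rate. A grid of one returns
#' immediately. `cfg$inner_fold_cap` limits the number of inner folds.
#'
#' @inheritParams train_trial_model
#' @return The chosen learning rate, with the per-candidate mean accuracies
#'   in attribute `"scores"`.
#' @export
select_learning_rate <- function(x, y, participant_id, arch,
                                 cfg = train_config(), cols1 = NULL) {
  grid <- cfg$lr_grid
  if (length(grid) == 1) return(grid)
  set.seed(cfg$seed + 1L)
  pids <- unique(participant_id)
  if (is.finite(cfg$inner_fold_cap) && cfg$inner_fold_cap < length(pids)) {
    pids <- sample(pids, cfg$inner_fold_cap)
  }
  P <- if (arch$kind == "cnn") arch$H1^2 else 0L
  scores <- vapply(grid, function(lr) {
    acc <- vapply(pids, function(p) {
      tr <- participant_id != p
      if (length(unique(y[tr])) < 2) return(NA_real_)
      ctr <- if (!is.null(cols1)) .slice_cols1(cols1, which(tr), P)
      m <- train_trial_model(x[, tr, drop = FALSE], y[tr], participant_id[tr],
                             arch, cfg, lr = lr, cols1 = ctr)
      cte <- if (!is.null(cols1)) .slice_cols1(cols1, which(!tr), P)
      mean(predict_trials(m, x[, !tr, drop = FALSE], cols1 = cte) == y[!tr])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }, numeric(1))
  best <- grid[which.max(scores)]  # which.max takes the first (smallest) on ties
  attr(best, "scores") <- stats::setNames(scores, grid)
  best
}

#' Predict binary trial labels
#'
#' Argmax over the two logits; deterministic.
#'
#' @param model a `trial_model`.
#' @param x `d x n` input matrix.
#' @return Integer 0/1 vector of length `ncol(x)`.
#' @export
predict_trials <- function(model, x, chunk = 512L, cols1 = NULL) {
  if (model$arch$kind == "baseline") {
    if (nrow(x) != model$arch$widths[1]) stop("input dimension mismatch")
  } else if (nrow(x) != model$arch$C0 * model$arch$S0^2) {
    stop("input dimension mismatch")
  }
  n <- ncol(x)
  P <- if (model$arch$kind == "cnn") model$arch$H1^2 else 0L
  out <- integer(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    cb <- if (!is.null(cols1)) .slice_cols1(cols1, s:e, P)
    logits <- .net_forward(model, x[, s:e, drop = FALSE], cols1 = cb)$logits
    out[s:e] <- max.col(t(logits)) - 1L
  }
  out
}

## ---- baseline featurization ----

#' Fit a z-score scaler on training-trial features
#'
#' @param features data frame of *kept* training trials with columns
#'   `fix_total, n_saccades, scan_path_length`.
#' @return A `feature_scaler` with per-feature means and SDs; zero-variance
#'   features are flagged so they map to 0.
#' @export
fit_feature_scaler <- function(features) {
  m <- as.matrix(features[, c("fix_total", "n_saccades", "scan_path_length")])
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  structure(list(mean = mu, sd = sdv, constant = sdv == 0),
            class = "feature_scaler")
}

#' Baseline feature vectors for trials
#'
#' Returns the 3-vector (total fixation-sample count, saccade count,
#' scan-path length) per trial, z-scored with *training* statistics; a
#' feature that was constant in training maps to 0.
#'
#' @param features trial feature data frame (must have passed
#'   [filter_trials()]: all rows `kept`).
#' @param scaler a [fit_feature_scaler()] result.
#' @return `3 x n` matrix.
#' @export
featurize_baseline <- function(features, scaler) {
  if (!is.null(features$kept) && !all(features$kept)) {
    stop("featurize_baseline expects filtered (kept) trials only")
  }
  m <- as.matrix(features[, c("fix_total", "n_saccades", "scan_path_length")])
  z <- sweep(sweep(m, 2, scaler$mean), 2, ifelse(scaler$constant, 1, scaler$sd), "/")
  z[, scaler$constant] <- 0
  t(z)
}
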