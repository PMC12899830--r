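#' Losses, augmentation and the training loop
#'
#' Binary focal loss and cross-entropy (both from logits for numerical
#' stability), MixUp batch augmentation, Adam optimization with
#' cosine-decay-with-restarts or reduce-on-plateau learning-rate schedules,
#' and model checkpointing on validation ROC AUC. All stochastic steps use
#' R's RNG, so CPU runs with equal seeds are bit-identical.
#'
#' @name training
NULL

#' Binary focal loss
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for positives and
#' `1 - p` for negatives, averaged over the batch. `gamma = 0`,
#' `alpha = 0.5` reduces to half the binary cross-entropy.
#'
#' @param y Labels in `[0, 1]` (soft labels allowed).
#' @param p Predicted probabilities.
#' @param alpha Positive-class weight.
#' @param gamma Focusing exponent.
#' @param eps Probability clipping bound.
#' @return Mean loss (non-negative scalar).
#' @export
focal_loss <- function(y, p, alpha = 0.25, gamma = 2.0, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(y * (-alpha * (1 - p)^gamma * log(p)) +
         (1 - y) * (-(1 - alpha) * p^gamma * log(1 - p)))
}

# loss value + d(loss)/d(logit) for the two supported losses
loss_grad <- function(y, z, loss = "focal", alpha = 0.25, gamma = 2.0,
                      eps = 1e-7) {
  p <- pmin(pmax(sigmoid(z), eps), 1 - eps)
  n <- length(y)
  if (loss == "bce") {
    val <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    return(list(value = val, dz = (p - y) / n))
  }
  val <- focal_loss(y, p, alpha, gamma, eps)
  dldp <- y * alpha * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p) +
    (1 - y) * (1 - alpha) * (-gamma * p^(gamma - 1) * log(1 - p) +
                               p^gamma / (1 - p))
  list(value = val, dz = dldp * p * (1 - p) / n)
}

#' MixUp augmentation of one training batch
#'
#' Draws a single mixing weight `lambda ~ Beta(alpha, alpha)` and forms
#' convex combinations of the batch with a random permutation of itself;
#' labels are mixed identically (and so become soft).
#'
#' @param X Input array (first dimension = batch) or named list of such
#'   arrays (all mixed with the same permutation and lambda).
#' @param y Label vector.
#' @param alpha Beta-distribution parameter; `alpha <= 0` disables mixing.
#' @return list with `X`, `y` and the drawn `lambda`.
#' @export
mixup_batch <- function(X, y, alpha = 0.2) {
  n <- length(y)
  if (n < 2L) eeg_stop("config", "mixup needs a batch of at least 2")
  if (alpha <= 0) return(list(X = X, y = y, lambda = 1))
  lam <- stats::rbeta(1, alpha, alpha)
  perm <- sample.int(n)
  mix1 <- function(a) {
    if (is.null(dim(a))) return(lam * a + (1 - lam) * a[perm])
    if (length(dim(a)) == 3L) lam * a + (1 - lam) * a[perm, , , drop = FALSE]
    else lam * a + (1 - lam) * a[perm, , drop = FALSE]
  }
  Xm <- if (is.list(X)) lapply(X, mix1) else mix1(X)
  list(X = Xm, y = lam * y + (1 - lam) * y[perm], lambda = lam)
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size Windows per mini-batch (64 cross-subject, 128 OSW).
#' @param epochs Training epochs (150 in the full configuration; reducible).
#' @param schedule `"cosine_restarts"`, `"plateau"` (on validation AUC) or
#'   `"constant"`.
#' @param loss `"focal"` or `"bce"`.
#' @param focal_alpha,focal_gamma Focal-loss parameters.
#' @param mixup_alpha MixUp Beta parameter; 0 disables MixUp.
#' @param checkpoint Restore the weights of the best validation-AUC epoch
#'   (otherwise the final weights are kept, as in the OSW protocol).
#' @param cosine_t0,cosine_mult First restart period (epochs) and period
#'   multiplier.
#' @param plateau_factor,plateau_patience Reduce-on-plateau settings.
#' @param seed RNG seed for shuffling, MixUp and noise.
#' @export
train_config <- function(lr = 1e-3, batch_size = 64L, epochs = 10L,
                         schedule = c("cosine_restarts", "plateau",
                                      "constant"),
                         loss = c("focal", "bce"),
                         focal_alpha = 0.25, focal_gamma = 2.0,
                         mixup_alpha = 0.2, checkpoint = TRUE,
                         cosine_t0 = 10L, cosine_mult = 2L,
                         plateau_factor = 0.5, plateau_patience = 5L,
                         seed = 42L) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 schedule = match.arg(schedule), loss = match.arg(loss),
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 mixup_alpha = mixup_alpha, checkpoint = isTRUE(checkpoint),
                 cosine_t0 = as.integer(cosine_t0),
                 cosine_mult = as.integer(cosine_mult),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_state <- function(layers) {
  lapply(layers, function(l)
    list(m = lapply(l$par, function(p) p * 0),
         v = lapply(l$par, function(p) p * 0)))
}

adam_step <- function(layers, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (n in names(l$par)) {
      g <- l$gr[[n]]
      state[[i]]$m[[n]] <- beta1 * state[[i]]$m[[n]] + (1 - beta1) * g
      state[[i]]$v[[n]] <- beta2 * state[[i]]$v[[n]] + (1 - beta2) * g^2
      l$par[[n]] <- l$par[[n]] - lr * (state[[i]]$m[[n]] / bc1) /
        (sqrt(state[[i]]$v[[n]] / bc2) + eps)
    }
  }
  state
}

slice_inputs <- function(inputs, idx) {
  lapply(inputs, function(a)
    if (length(dim(a)) == 3L) a[idx, , , drop = FALSE]
    else a[idx, , drop = FALSE])
}

# rank-based AUC; NA if only one class present
auc_safe <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a model
#'
#' Mini-batch Adam with the configured loss, schedule and augmentations
#' (Gaussian input noise lives inside the model and, like MixUp, applies to
#' training batches only). Validation ROC AUC is computed each epoch; with
#' `checkpoint = TRUE` the returned model carries the weights of the best
#' validation epoch.
#'
#' @param model An `nn_model` handle from [build_resnet_se()] or
#'   [build_res_tcn_se_attention()].
#' @param inputs Named list of training input arrays (`raw` and, for the
#'   hybrid model, `dwt` and `feats`), first dimension = windows.
#' @param y Binary training labels.
#' @param val_inputs,val_y Validation windows (disjoint from training).
#' @param config A [train_config()].
#' @return list with `model`, `history` (one row per epoch: lr, train loss
#'   and accuracy, validation AUC and accuracy), `best_epoch`,
#'   `best_val_auc`.
#' @export
train_model <- function(model, inputs, y, val_inputs, val_y,
                        config = train_config()) {
  if (!is.list(inputs)) inputs <- list(raw = inputs)
  if (!is.list(val_inputs)) val_inputs <- list(raw = val_inputs)
  n <- length(y)
  if (n == 0L) eeg_stop("data", "empty training set")
  set.seed(config$seed)
  state <- adam_state(model$layers)
  lr <- config$lr
  cos_tcur <- 0L; cos_ti <- config$cosine_t0
  plateau_best <- -Inf; plateau_wait <- 0L
  hist <- data.frame()
  best_auc <- -Inf; best_epoch <- NA_integer_; best_snap <- NULL
  tstep <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr_epoch <- switch(config$schedule,
      constant = lr,
      plateau = lr,
      cosine_restarts = config$lr * 0.5 * (1 + cos(pi * cos_tcur / cos_ti)))
    idx_all <- sample.int(n)
    tl <- 0; tn <- 0L; tcorrect <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- idx_all[s:min(n, s + config$batch_size - 1L)]
      if (length(idx) < 2L) next
      xb <- slice_inputs(inputs, idx)
      yb <- y[idx]
      if (config$mixup_alpha > 0) {
        mb <- mixup_batch(xb, yb, config$mixup_alpha)
        xb <- mb$X; ybm <- mb$y
      } else ybm <- yb
      z <- model$forward(xb, train = TRUE)
      lg <- loss_grad(ybm, z, config$loss, config$focal_alpha,
                      config$focal_gamma)
      zero_grads(model$layers)
      model$backward(lg$dz)
      tstep <- tstep + 1L
      state <- adam_step(model$layers, state, lr_epoch, tstep)
      tl <- tl + lg$value * length(idx); tn <- tn + length(idx)
      tcorrect <- tcorrect + sum((sigmoid(z) > 0.5) == (yb > 0.5))
    }
    val_p <- predict_prob(model, val_inputs)
    val_auc <- auc_safe(val_y, val_p)
    val_acc <- mean((val_p > 0.5) == (val_y > 0.5))
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr_epoch, train_loss = tl / max(tn, 1L),
      train_acc = tcorrect / max(tn, 1L), val_auc = val_auc,
      val_acc = val_acc))
    score <- if (is.na(val_auc)) val_acc else val_auc
    if (score > best_auc) {
      best_auc <- score; best_epoch <- epoch
      if (config$checkpoint) best_snap <- snapshot_params(model)
    }
    if (config$schedule == "cosine_restarts") {
      cos_tcur <- cos_tcur + 1L
      if (cos_tcur >= cos_ti) { cos_tcur <- 0L; cos_ti <- cos_ti * config$cosine_mult }
    } else if (config$schedule == "plateau") {
      if (score > plateau_best + 1e-12) {
        plateau_best <- score; plateau_wait <- 0L
      } else {
        plateau_wait <- plateau_wait + 1L
        if (plateau_wait >= config$plateau_patience) {
          lr <- lr * config$plateau_factor
          plateau_wait <- 0L
        }
      }
    }
  }
  if (config$checkpoint && !is.null(best_snap)) restore_params(model, best_snap)
  list(model = model, history = hist, best_epoch = best_epoch,
       best_val_auc = best_auc)
}
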