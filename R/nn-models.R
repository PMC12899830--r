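#' Model architectures
#'
#' Two compact 1-D CNNs: a residual squeeze-and-excitation network for the
#' subject-independent protocol (raw windows only) and a residual temporal
#' convolutional network with SE and attention pooling that fuses raw
#' windows with the DWT and FEATS descriptor branches for the
#' subject-dependent protocol. Controlled ablation variants (SE and/or
#' attention removed structurally) mirror the published ablation harness.
#'
#' @name models
NULL

#' ResNet-SE architecture specification
#'
#' Three stages of two residual blocks each with increasing width and
#' decreasing kernel size; the first block of each stage halves the time
#' axis. The default configuration has about 0.93 M trainable parameters.
#'
#' @param stage_filters,stage_kernels,stage_dilations Per-stage settings.
#' @param blocks_per_stage Residual blocks per stage.
#' @param head_units Width of the dense classifier head.
#' @param noise_std Gaussian input-noise SD (z-score units), training only.
#' @param dropout Dense-head dropout rate.
#' @param use_se Keep squeeze-and-excitation gating.
#' @export
resnet_se_spec <- function(stage_filters = c(64L, 96L, 128L),
                           stage_kernels = c(11L, 9L, 7L),
                           stage_dilations = c(1L, 2L, 4L),
                           blocks_per_stage = 2L, head_units = 128L,
                           noise_std = 0.01, dropout = 0.3, use_se = TRUE) {
  stopifnot(length(stage_filters) == 3L, length(stage_kernels) == 3L,
            length(stage_dilations) == 3L)
  structure(list(stage_filters = as.integer(stage_filters),
                 stage_kernels = as.integer(stage_kernels),
                 stage_dilations = as.integer(stage_dilations),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 head_units = as.integer(head_units),
                 noise_std = noise_std, dropout = dropout,
                 use_se = isTRUE(use_se)),
            class = "resnet_se_spec")
}

#' Res-TCN-SE-Attention architecture specification
#'
#' @param stem_filters,stem_kernel Initial convolution.
#' @param block_filters,dilations Five depthwise-separable residual blocks;
#'   the first four end with a factor-2 max-pool.
#' @param block_kernel Separable-convolution kernel size.
#' @param raw_head_units Dense units after attention pooling.
#' @param dwt_units,feats_units Two-layer MLP widths of the feature branches.
#' @param fusion_units Dense units of the fusion head.
#' @param attention_units Width of the attention scoring head.
#' @param noise_std,spatial_dropout,dropout Regularization settings.
#' @param use_se,use_attention Structural ablation switches (attention off
#'   replaces attention pooling with global average pooling).
#' @export
res_tcn_spec <- function(stem_filters = 64L, stem_kernel = 5L,
                         block_filters = c(64L, 96L, 128L, 192L, 256L),
                         block_kernel = 5L,
                         dilations = c(1L, 2L, 4L, 8L, 12L),
                         raw_head_units = 192L,
                         dwt_units = c(256L, 128L),
                         feats_units = c(192L, 128L),
                         fusion_units = 160L, attention_units = 64L,
                         noise_std = 0.01, spatial_dropout = 0.1,
                         dropout = 0.3, use_se = TRUE, use_attention = TRUE) {
  stopifnot(length(block_filters) == 5L, length(dilations) == 5L)
  structure(list(stem_filters = as.integer(stem_filters),
                 stem_kernel = as.integer(stem_kernel),
                 block_filters = as.integer(block_filters),
                 block_kernel = as.integer(block_kernel),
                 dilations = as.integer(dilations),
                 raw_head_units = as.integer(raw_head_units),
                 dwt_units = as.integer(dwt_units),
                 feats_units = as.integer(feats_units),
                 fusion_units = as.integer(fusion_units),
                 attention_units = as.integer(attention_units),
                 noise_std = noise_std, spatial_dropout = spatial_dropout,
                 dropout = dropout, use_se = isTRUE(use_se),
                 use_attention = isTRUE(use_attention)),
            class = "res_tcn_spec")
}

# Residual block of the ResNet-SE: conv-BN-ReLU twice, SE gate, projected
# shortcut on channel change, optional factor-2 max-pool.
resnet_block <- function(cin, cout, k, dil, use_se, pool) {
  main <- list(layer_conv1d(cin, cout, k, dil), layer_batchnorm(cout),
               layer_relu(), layer_conv1d(cout, cout, k, dil),
               layer_batchnorm(cout), layer_relu())
  se <- if (use_se) layer_se(cout) else NULL
  proj <- if (cin != cout) layer_conv1d(cin, cout, 1L) else NULL
  pooler <- if (pool) layer_maxpool2() else NULL
  b <- new.env(parent = emptyenv())
  b$layers <- c(main, list(se), list(proj), list(pooler))
  b$layers <- b$layers[!vapply(b$layers, is.null, TRUE)]
  b$fwd <- function(x, train = FALSE) {
    h <- seq_forward(main, x, train)
    if (!is.null(se)) h <- se$fwd(h, train)
    s <- if (is.null(proj)) x else proj$fwd(x, train)
    y <- h + s
    if (!is.null(pooler)) y <- pooler$fwd(y, train)
    y
  }
  b$bwd <- function(dy) {
    if (!is.null(pooler)) dy <- pooler$bwd(dy)
    dh <- dy
    if (!is.null(se)) dh <- se$bwd(dh)
    dx <- seq_backward(main, dh)
    dx + (if (is.null(proj)) dy else proj$bwd(dy))
  }
  b
}

# Depthwise-separable residual block of the Res-TCN: two separable convs
# with BN/ReLU/spatial dropout, residual add (1x1 projection on channel
# change), ReLU, SE gate on the block output, optional max-pool.
res_tcn_block <- function(cin, cout, k, dil, use_se, pool, sdrop) {
  main <- list(layer_sepconv1d(cin, cout, k, dil), layer_batchnorm(cout),
               layer_relu(), layer_spatial_dropout(sdrop),
               layer_sepconv1d(cout, cout, k, dil), layer_batchnorm(cout),
               layer_spatial_dropout(sdrop))
  se <- if (use_se) layer_se(cout) else NULL
  proj <- if (cin != cout) layer_conv1d(cin, cout, 1L) else NULL
  outact <- layer_relu()
  pooler <- if (pool) layer_maxpool2() else NULL
  b <- new.env(parent = emptyenv())
  b$layers <- c(main, list(se), list(proj), list(outact), list(pooler))
  b$layers <- b$layers[!vapply(b$layers, is.null, TRUE)]
  b$fwd <- function(x, train = FALSE) {
    h <- seq_forward(main, x, train)
    s <- if (is.null(proj)) x else proj$fwd(x, train)
    y <- outact$fwd(h + s, train)
    if (!is.null(se)) y <- se$fwd(y, train)
    if (!is.null(pooler)) y <- pooler$fwd(y, train)
    y
  }
  b$bwd <- function(dy) {
    if (!is.null(pooler)) dy <- pooler$bwd(dy)
    if (!is.null(se)) dy <- se$bwd(dy)
    dy <- outact$bwd(dy)
    dx <- seq_backward(main, dy)
    dx + (if (is.null(proj)) dy else proj$bwd(dy))
  }
  b
}

collect_layers <- function(parts) {
  out <- list()
  for (p in parts) {
    if (is.null(p)) next
    if (is.environment(p) && !is.null(p$layers)) out <- c(out, p$layers)
    else out <- c(out, list(p))
  }
  out
}

#' Build the subject-independent ResNet-SE model
#'
#' Maps a `win_samples x n_channels` z-scored raw window to a deception
#' probability. `win_samples` must be divisible by 8 (three pooling stages).
#'
#' @param win_samples Window length in samples.
#' @param n_channels Number of EEG channels.
#' @param spec A [resnet_se_spec()].
#' @return An `nn_model` handle (forward/backward/predict, parameter count).
#' @export
build_resnet_se <- function(win_samples, n_channels, spec = resnet_se_spec()) {
  if (win_samples %% 8L != 0L)
    eeg_stop("config", "win_samples must be divisible by 8")
  noise <- layer_gaussian_noise(spec$noise_std)
  blocks <- list()
  cin <- n_channels
  for (st in 1:3) {
    f <- spec$stage_filters[st]
    for (bl in seq_len(spec$blocks_per_stage)) {
      blocks[[length(blocks) + 1L]] <-
        resnet_block(cin, f, spec$stage_kernels[st], spec$stage_dilations[st],
                     spec$use_se, pool = (bl == 1L))
      cin <- f
    }
  }
  gap <- layer_gap()
  drop1 <- layer_dropout(spec$dropout)
  densem <- layer_dense(cin, spec$head_units)
  actm <- layer_relu()
  drop2 <- layer_dropout(spec$dropout)
  head <- layer_dense(spec$head_units, 1L)
  m <- new.env(parent = emptyenv())
  m$kind <- "resnet_se"
  m$inputs <- "raw"
  m$win_samples <- win_samples
  m$layers <- collect_layers(c(list(noise), blocks,
                               list(gap, drop1, densem, actm, drop2, head)))
  m$forward <- function(inputs, train = FALSE) {
    x <- if (is.list(inputs)) inputs$raw else inputs
    x <- noise$fwd(x, train)
    for (b in blocks) x <- b$fwd(x, train)
    h <- gap$fwd(x, train)
    h <- drop2$fwd(actm$fwd(densem$fwd(drop1$fwd(h, train), train), train), train)
    drop(head$fwd(h, train))
  }
  m$backward <- function(dlogit) {
    dy <- head$bwd(matrix(dlogit, ncol = 1L))
    dy <- drop1$bwd(densem$bwd(actm$bwd(drop2$bwd(dy))))
    dy <- gap$bwd(dy)
    for (b in rev(blocks)) dy <- b$bwd(dy)
    invisible(NULL)
  }
  m$n_params <- n_params(m$layers)
  m
}

#' Build the hybrid Res-TCN-SE-Attention model
#'
#' Three branches: the raw branch (stem convolution, five separable residual
#' SE blocks with dilations 1/2/4/8/12, attention pooling, dense embedding),
#' and two feature branches (layer-normalized DWT and FEATS vectors through
#' two-layer MLPs). Embeddings are concatenated into a dense fusion head.
#' `win_samples` must be divisible by 16 (four pooling blocks).
#'
#' @param win_samples Raw window length in samples.
#' @param n_channels Number of EEG channels.
#' @param dwt_dim,feats_dim Feature-branch input dimensions.
#' @param spec A [res_tcn_spec()].
#' @return An `nn_model` handle.
#' @export
build_res_tcn_se_attention <- function(win_samples, n_channels,
                                       dwt_dim = 175L, feats_dim = 167L,
                                       spec = res_tcn_spec()) {
  if (win_samples %% 16L != 0L)
    eeg_stop("config", "win_samples must be divisible by 16")
  noise <- layer_gaussian_noise(spec$noise_std)
  stem <- layer_conv1d(n_channels, spec$stem_filters, spec$stem_kernel)
  blocks <- list()
  cin <- spec$stem_filters
  for (i in 1:5) {
    blocks[[i]] <- res_tcn_block(cin, spec$block_filters[i], spec$block_kernel,
                                 spec$dilations[i], spec$use_se,
                                 pool = (i <= 4L), sdrop = spec$spatial_dropout)
    cin <- spec$block_filters[i]
  }
  pool_layer <- if (spec$use_attention)
    layer_attention_pool(cin, spec$attention_units) else layer_gap()
  rdrop1 <- layer_dropout(spec$dropout)
  rdense <- layer_dense(cin, spec$raw_head_units)
  ract <- layer_relu()
  rdrop2 <- layer_dropout(spec$dropout)
  dwt_branch <- list(layer_layernorm(dwt_dim),
                     layer_dense(dwt_dim, spec$dwt_units[1]), layer_relu(),
                     layer_dropout(spec$dropout),
                     layer_dense(spec$dwt_units[1], spec$dwt_units[2]),
                     layer_relu())
  feats_branch <- list(layer_layernorm(feats_dim),
                       layer_dense(feats_dim, spec$feats_units[1]),
                       layer_relu(), layer_dropout(spec$dropout),
                       layer_dense(spec$feats_units[1], spec$feats_units[2]),
                       layer_relu())
  fused_dim <- spec$raw_head_units + spec$dwt_units[2] + spec$feats_units[2]
  fdense <- layer_dense(fused_dim, spec$fusion_units)
  fact <- layer_relu()
  fdrop <- layer_dropout(spec$dropout)
  head <- layer_dense(spec$fusion_units, 1L)
  m <- new.env(parent = emptyenv())
  m$kind <- "res_tcn_se_attention"
  m$inputs <- c("raw", "dwt", "feats")
  m$win_samples <- win_samples
  m$layers <- collect_layers(c(list(noise, stem), blocks,
                               list(pool_layer, rdrop1, rdense, ract, rdrop2),
                               dwt_branch, feats_branch,
                               list(fdense, fact, fdrop, head)))
  m$dims <- c(raw = spec$raw_head_units, dwt = spec$dwt_units[2],
              feats = spec$feats_units[2])
  m$forward <- function(inputs, train = FALSE) {
    x <- stem$fwd(noise$fwd(inputs$raw, train), train)
    for (b in blocks) x <- b$fwd(x, train)
    e_raw <- rdrop2$fwd(ract$fwd(rdense$fwd(rdrop1$fwd(
      pool_layer$fwd(x, train), train), train), train), train)
    e_dwt <- seq_forward(dwt_branch, inputs$dwt, train)
    e_feats <- seq_forward(feats_branch, inputs$feats, train)
    h <- cbind(e_raw, e_dwt, e_feats)
    drop(head$fwd(fdrop$fwd(fact$fwd(fdense$fwd(h, train), train), train),
                  train))
  }
  m$backward <- function(dlogit) {
    dh <- fdense$bwd(fact$bwd(fdrop$bwd(head$bwd(matrix(dlogit, ncol = 1L)))))
    d1 <- m$dims["raw"]; d2 <- m$dims["dwt"]
    d_raw <- dh[, seq_len(d1), drop = FALSE]
    d_dwt <- dh[, d1 + seq_len(d2), drop = FALSE]
    d_feats <- dh[, (d1 + d2 + 1L):ncol(dh), drop = FALSE]
    seq_backward(dwt_branch, d_dwt)
    seq_backward(feats_branch, d_feats)
    dy <- pool_layer$bwd(rdrop1$bwd(rdense$bwd(ract$bwd(rdrop2$bwd(d_raw)))))
    for (b in rev(blocks)) dy <- b$bwd(dy)
    stem$bwd(dy)
    invisible(NULL)
  }
  m$n_params <- n_params(m$layers)
  m
}

#' Build a Res-TCN ablation variant
#'
#' Structural removal of SE gating and/or attention pooling (replaced by
#' global average pooling), mirroring the published ablation harness:
#' `"full"`, `"no_se"`, `"no_attention"`, `"neither"`.
#'
#' @param variant One of the four variant names.
#' @inheritParams build_res_tcn_se_attention
#' @export
build_res_tcn_variant <- function(variant = c("full", "no_se", "no_attention",
                                              "neither"),
                                  win_samples, n_channels,
                                  dwt_dim = 175L, feats_dim = 167L,
                                  spec = res_tcn_spec()) {
  variant <- match.arg(variant)
  spec$use_se <- variant %in% c("full", "no_attention")
  spec$use_attention <- variant %in% c("full", "no_se")
  m <- build_res_tcn_se_attention(win_samples, n_channels, dwt_dim,
                                  feats_dim, spec)
  m$variant <- variant
  m
}

#' Predicted probabilities for a batch of inputs
#'
#' Runs the model in inference mode (no dropout/noise, batch-norm running
#' statistics) in chunks.
#'
#' @param model An `nn_model` handle.
#' @param inputs Named list of input arrays (or a raw array for raw-only
#'   models); first dimension indexes windows.
#' @param batch_size Chunk size.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, inputs, batch_size = 256L) {
  if (!is.list(inputs)) inputs <- list(raw = inputs)
  n <- dim(inputs[[1]])[1]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    chunk <- lapply(inputs, function(a)
      if (length(dim(a)) == 3L) a[idx, , , drop = FALSE]
      else a[idx, , drop = FALSE])
    out[idx] <- sigmoid(model$forward(chunk, train = FALSE))
  }
  out
}

snapshot_params <- function(model) {
  lapply(model$layers, function(l) {
    s <- list(par = l$par)
    if (identical(l$type, "batchnorm")) {
      s$run_mean <- l$run_mean
      s$run_var <- l$run_var
      s$run_n <- l$run_n
    }
    s
  })
}

restore_params <- function(model, snap) {
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    l$par <- snap[[i]]$par
    if (identical(l$type, "batchnorm")) {
      l$run_mean <- snap[[i]]$run_mean
      l$run_var <- snap[[i]]$run_var
      l$run_n <- snap[[i]]$run_n
    }
  }
  invisible(model)
}
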