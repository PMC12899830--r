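#' End-to-end experiment drivers
#'
#' The two evaluation pipelines: the subject-dependent session-disjoint
#' overlapping sliding-window (OSW) experiment and the subject-independent
#' grouped cross-validation experiment with session-level aggregation and a
#' single global Youden-J threshold, plus the OSW ablation harness and the
#' descriptive-statistics driver.
#'
#' @name drivers
NULL

# Stack a window list into model input arrays (+ metadata); hybrid models
# additionally get the per-window DWT and FEATS vectors.
windows_to_arrays <- function(windows, with_features = FALSE, fs = 128) {
  n <- length(windows)
  W <- nrow(windows[[1]]$data); C <- ncol(windows[[1]]$data)
  raw <- array(0, c(n, W, C))
  dwt <- if (with_features) matrix(0, n, 175L) else NULL
  feats <- if (with_features) matrix(0, n, 167L) else NULL
  for (i in seq_len(n)) {
    raw[i, , ] <- windows[[i]]$data
    if (with_features) {
      dwt[i, ] <- dwt_features(windows[[i]])
      feats[i, ] <- feats_vector(windows[[i]], fs)
    }
  }
  meta <- data.frame(
    subject_id = vapply(windows, function(w) w$subject_id, ""),
    session_id = vapply(windows, function(w) w$session_id, ""),
    label = vapply(windows, function(w) w$label, 0L))
  inputs <- if (with_features) list(raw = raw, dwt = dwt, feats = feats)
  else list(raw = raw)
  list(inputs = inputs, meta = meta)
}

build_model_for <- function(arch, win_samples, n_channels, model_spec) {
  switch(arch,
    resnet_se = build_resnet_se(win_samples, n_channels,
                                model_spec %||% resnet_se_spec()),
    res_tcn = build_res_tcn_se_attention(win_samples, n_channels,
                                         spec = model_spec %||% res_tcn_spec()),
    eeg_stop("config", "unknown architecture '%s'", arch))
}

#' Subject-dependent OSW experiment
#'
#' Stratified 80/10/10 split over sessions; 2.0 s / 0.25 s z-scored windows
#' inherit their session's subset; the model is trained on the training
#' windows, a single decision threshold is calibrated on the validation
#' windows with Youden's J, and both window-level and session-level metrics
#' are computed on the held-out test sessions with that fixed threshold.
#'
#' @param records Preprocessed [session_record()]s.
#' @param arch `"res_tcn"` (hybrid RAW+DWT+FEATS, the OSW default) or
#'   `"resnet_se"` (raw-only).
#' @param model_spec Architecture spec (reduced specs keep runs desk-scale).
#' @param tconfig A [train_config()].
#' @param win_s,hop_s Windowing (defaults 2.0 / 0.25).
#' @param split_seed Seed of the session split (fixed and reused across
#'   subject-dependent experiments).
#' @return list: `window_report`, `session_report`, `operating_point`,
#'   `history`, `split`, `window_probs` (test windows), `session_scores`.
#' @export
run_subject_dependent <- function(records, arch = "res_tcn",
                                  model_spec = NULL,
                                  tconfig = train_config(batch_size = 128L,
                                                         loss = "bce",
                                                         mixup_alpha = 0,
                                                         checkpoint = FALSE),
                                  win_s = 2.0, hop_s = 0.25,
                                  split_seed = 42L) {
  sessions <- data.frame(
    session_id = vapply(records, function(r) r$session_id, ""),
    label = vapply(records, function(r) r$label, 0L))
  split <- osw_split(sessions, seed = split_seed)
  windows <- segment_dataset(records, win_s, hop_s, zscore = TRUE)
  wa <- windows_to_arrays(windows, with_features = (arch == "res_tcn"),
                          fs = records[[1]]$fs)
  subset_of <- function(ids) which(wa$meta$session_id %in% ids)
  tr <- subset_of(split$train); va <- subset_of(split$val)
  te <- subset_of(split$test)
  W <- dim(wa$inputs$raw)[2]; C <- dim(wa$inputs$raw)[3]
  set.seed(tconfig$seed)
  model <- build_model_for(arch, W, C, model_spec)
  fit <- train_model(model, slice_inputs(wa$inputs, tr), wa$meta$label[tr],
                     slice_inputs(wa$inputs, va), wa$meta$label[va], tconfig)
  val_p <- predict_prob(fit$model, slice_inputs(wa$inputs, va))
  op <- if (length(unique(wa$meta$label[va])) < 2L) {
    # degenerate tiny split: validation sessions carry one class only
    warning("single-class validation subset; using the default 0.5 cutpoint")
    structure(list(threshold = 0.5, J = NA_real_, source = "default_0.5"),
              class = "operating_point")
  } else {
    youden_threshold(val_p, wa$meta$label[va], source = "validation_windows")
  }
  test_p <- predict_prob(fit$model, slice_inputs(wa$inputs, te))
  pred <- as.integer(test_p >= op$threshold)
  window_report <- classification_report(pred, wa$meta$label[te], test_p)
  ss <- aggregate_session_scores(test_p, wa$meta$session_id[te],
                                 wa$meta$subject_id[te], wa$meta$label[te])
  session_report <- classification_report(
    as.integer(ss$score >= op$threshold), ss$label, ss$score)
  list(window_report = window_report, session_report = session_report,
       operating_point = op, history = fit$history, split = split,
       window_probs = test_p, session_scores = ss)
}

#' OSW ablation harness
#'
#' Retrains the four structural variants (full, no SE, no attention,
#' neither) across the given seeds on one fixed session split and reports
#' window/session accuracy as mean and SD across seeds.
#'
#' @inheritParams run_subject_dependent
#' @param seeds Training seeds (the split stays fixed).
#' @param variants Subset of the four variant names.
#' @return list with `runs` (per variant x seed) and `summary` data.frame.
#' @export
run_osw_ablation <- function(records, model_spec = NULL,
                             tconfig = train_config(batch_size = 128L,
                                                    loss = "bce",
                                                    mixup_alpha = 0,
                                                    checkpoint = FALSE),
                             seeds = 0:2,
                             variants = c("full", "no_se", "no_attention",
                                          "neither"),
                             win_s = 2.0, hop_s = 0.25, split_seed = 42L) {
  runs <- list()
  for (v in variants) {
    for (s in seeds) {
      spec <- model_spec %||% res_tcn_spec()
      spec$use_se <- v %in% c("full", "no_attention")
      spec$use_attention <- v %in% c("full", "no_se")
      tc <- tconfig; tc$seed <- as.integer(s)
      res <- run_subject_dependent(records, arch = "res_tcn",
                                   model_spec = spec, tconfig = tc,
                                   win_s = win_s, hop_s = hop_s,
                                   split_seed = split_seed)
      runs[[paste(v, s, sep = "_")]] <- list(
        variant = v, seed = s,
        window_acc = res$window_report$accuracy,
        session_acc = res$session_report$accuracy,
        sessions_correct = sum(res$session_report$counts[c("TN", "TP")]),
        sessions_total = res$session_report$n)
    }
  }
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(variant = r$variant, seed = r$seed,
               window_acc = r$window_acc, session_acc = r$session_acc,
               sessions_correct = r$sessions_correct,
               sessions_total = r$sessions_total)))
  summary <- do.call(rbind, lapply(split(df, df$variant), function(d)
    data.frame(variant = d$variant[1],
               window_acc_mean = mean(d$window_acc),
               window_acc_sd = stats::sd(d$window_acc),
               session_acc_mean = mean(d$session_acc),
               session_acc_sd = stats::sd(d$session_acc),
               min_sessions_correct = min(d$sessions_correct))))
  list(runs = df, summary = summary)
}

#' Subject-independent grouped cross-validation experiment
#'
#' Five-fold grouped CV with subject as the grouping variable on 3.0 s /
#' 0.25 s z-scored raw windows. In each fold a fresh model is trained on
#' the non-test windows (about 10% of which form the inner validation set,
#' used for checkpointing on validation AUC), out-of-fold window
#' probabilities are collected, averaged per session, and one global
#' decision threshold is calibrated on the pooled out-of-fold session
#' scores with Youden's J. Threshold calibration therefore only ever sees
#' scores produced by models that never saw the scored subject.
#'
#' @param records Preprocessed [session_record()]s.
#' @param arch Architecture (default `"resnet_se"`, raw windows only).
#' @param model_spec Architecture spec.
#' @param tconfig A [train_config()] (focal loss, MixUp and plateau
#'   scheduling by default).
#' @param K Number of folds.
#' @param win_s,hop_s Windowing (defaults 3.0 / 0.25).
#' @param seed Seed for fold assignment and per-fold training.
#' @return list: `session_report` (pooled, at the global threshold),
#'   `operating_point`, `session_scores`, `fold_stats` (per-fold session
#'   and window AUC), `fold_auc_mean`, `fold_auc_sd`, `binomial_p`,
#'   `window_auc` (pooled out-of-fold), `folds`.
#' @export
run_cross_subject <- function(records, arch = "resnet_se",
                              model_spec = NULL,
                              tconfig = train_config(batch_size = 64L,
                                                     loss = "focal",
                                                     schedule = "plateau",
                                                     mixup_alpha = 0.2,
                                                     checkpoint = TRUE),
                              K = 5L, win_s = 3.0, hop_s = 0.25,
                              seed = 42L) {
  windows <- segment_dataset(records, win_s, hop_s, zscore = TRUE)
  wa <- windows_to_arrays(windows, with_features = (arch == "res_tcn"),
                          fs = records[[1]]$fs)
  folds <- grouped_folds(wa$meta$subject_id, K = K, seed = seed)
  oof <- rep(NA_real_, nrow(wa$meta))
  fold_stats <- list()
  W <- dim(wa$inputs$raw)[2]; C <- dim(wa$inputs$raw)[3]
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    tc <- tconfig; tc$seed <- derive_seed(seed, 3L, k)
    set.seed(tc$seed)
    model <- build_model_for(arch, W, C, model_spec)
    fit <- train_model(model, slice_inputs(wa$inputs, f$train_idx),
                       wa$meta$label[f$train_idx],
                       slice_inputs(wa$inputs, f$val_idx),
                       wa$meta$label[f$val_idx], tc)
    p <- predict_prob(fit$model, slice_inputs(wa$inputs, f$test_idx))
    oof[f$test_idx] <- p
    ssf <- aggregate_session_scores(p, wa$meta$session_id[f$test_idx],
                                    wa$meta$subject_id[f$test_idx],
                                    wa$meta$label[f$test_idx])
    fold_stats[[k]] <- data.frame(
      fold = k,
      n_test_subjects = length(f$test_subjects),
      window_auc = auc_safe(wa$meta$label[f$test_idx], p),
      window_acc = mean((p > 0.5) == (wa$meta$label[f$test_idx] > 0.5)),
      session_auc = auc_safe(ssf$label, ssf$score),
      best_val_auc = fit$best_val_auc)
  }
  stopifnot(!anyNA(oof))
  ss <- aggregate_session_scores(oof, wa$meta$session_id, wa$meta$subject_id,
                                 wa$meta$label)
  op <- youden_threshold(ss$score, ss$label, source = "pooled_oof_sessions")
  pred <- as.integer(ss$score >= op$threshold)
  session_report <- classification_report(pred, ss$label, ss$score)
  fold_stats <- do.call(rbind, fold_stats)
  list(session_report = session_report, operating_point = op,
       session_scores = ss, fold_stats = fold_stats,
       fold_auc_mean = mean(fold_stats$session_auc, na.rm = TRUE),
       fold_auc_sd = stats::sd(fold_stats$session_auc),
       binomial_p = exact_binomial_test(
         sum(pred == ss$label), nrow(ss), 0.5),
       window_auc = roc_auc(oof, wa$meta$label),
       folds = folds, window_meta = wa$meta)
}

#' Descriptive statistics driver
#'
#' Computes the DESC table on the 2.0 s / 1.0 s descriptive stream and the
#' class-wise quartile/IQR summary plus Cliff's delta effect sizes of the
#' cross-channel mean band powers.
#'
#' @param records Preprocessed [session_record()]s.
#' @return list: `desc` (window table), `band_summary`, `effect_sizes`.
#' @export
describe_dataset <- function(records) {
  desc <- desc_table(records)
  list(desc = desc, band_summary = band_power_summary(desc),
       effect_sizes = band_effect_sizes(desc))
}
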