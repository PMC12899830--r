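#' Evaluation protocols
#'
#' Session-level stratified 80/10/10 splitting (subject-dependent OSW),
#' subject-grouped K-fold cross-validation, session-score aggregation,
#' ROC analysis with Youden-J threshold calibration, the metrics report,
#' Wilson intervals and the exact binomial test.
#'
#' @name protocol
NULL

# largest-remainder allocation of `total` items across strata of sizes n_c
allocate_counts <- function(n_c, total) {
  quota <- total * n_c / sum(n_c)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, n_c, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Stratified session-level 80/10/10 split
#'
#' Sessions (not windows) are assigned to train/validation/test, stratified
#' by the session label; every window later inherits its session's subset.
#' For 54 sessions the sizes are 43/5/6.
#'
#' @param sessions data.frame with columns `session_id` and `label`.
#' @param ratios Train/validation/test fractions.
#' @param seed RNG seed.
#' @return list of class `split_plan` with character vectors `train`,
#'   `val`, `test`.
#' @export
osw_split <- function(sessions, ratios = c(0.8, 0.1, 0.1), seed = 42L) {
  n <- nrow(sessions)
  if (n < 10L) eeg_stop("data", "need at least 10 sessions for an 80/10/10 split")
  if (anyDuplicated(sessions$session_id))
    eeg_stop("data", "duplicate session ids")
  n_val <- max(1L, floor(n * ratios[2]))
  n_test <- max(1L, ceiling(n * ratios[3]))
  if (n - n_val - n_test < 1L) eeg_stop("data", "train subset would be empty")
  classes <- sort(unique(sessions$label))
  n_c <- vapply(classes, function(cl) sum(sessions$label == cl), 0L)
  test_c <- allocate_counts(n_c, n_test)
  val_c <- allocate_counts(n_c - test_c, n_val)
  set.seed(seed)
  train <- val <- test <- character(0)
  for (i in seq_along(classes)) {
    ids <- sessions$session_id[sessions$label == classes[i]]
    ids <- sample(ids)
    test <- c(test, ids[seq_len(test_c[i])])
    val <- c(val, ids[test_c[i] + seq_len(val_c[i])])
    train <- c(train, ids[-(seq_len(test_c[i] + val_c[i]))])
  }
  structure(list(train = train, val = val, test = test), class = "split_plan")
}

#' Subject-grouped K-fold plan
#'
#' Partitions subjects into K folds of near-equal size (sizes differ by at
#' most one); each subject is a test subject in exactly one fold. Inner
#' validation indices are drawn at random from the non-test windows
#' (approximately `val_frac` of them).
#'
#' @param subject_ids Per-window subject identifier vector.
#' @param K Number of folds.
#' @param seed RNG seed.
#' @param val_frac Fraction of non-test windows used for inner validation.
#' @return list of class `fold_plan`; per fold: `test_subjects`,
#'   `train_idx`, `val_idx`, `test_idx` (window indices).
#' @export
grouped_folds <- function(subject_ids, K = 5L, seed = 42L, val_frac = 0.1) {
  subjects <- unique(subject_ids)
  if (K > length(subjects))
    eeg_stop("config", "K = %d exceeds the %d available subjects",
             K, length(subjects))
  set.seed(seed)
  subjects <- sample(subjects)
  sizes <- rep(length(subjects) %/% K, K)
  extra <- length(subjects) %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- list()
  at <- 0L
  for (k in seq_len(K)) {
    test_subjects <- subjects[at + seq_len(sizes[k])]
    at <- at + sizes[k]
    test_idx <- which(subject_ids %in% test_subjects)
    pool <- setdiff(seq_along(subject_ids), test_idx)
    n_val <- max(1L, round(val_frac * length(pool)))
    val_idx <- sort(sample(pool, n_val))
    folds[[k]] <- list(test_subjects = test_subjects,
                       train_idx = setdiff(pool, val_idx),
                       val_idx = val_idx, test_idx = test_idx)
  }
  structure(folds, class = "fold_plan")
}

#' Aggregate window probabilities to session scores
#'
#' Arithmetic mean of the window probabilities within each
#' (subject, session) pair — the operational decision unit.
#'
#' @param window_probs Window probabilities.
#' @param session_ids,subject_ids,labels Per-window metadata.
#' @return data.frame: subject_id, session_id, label, score, n_windows.
#' @export
aggregate_session_scores <- function(window_probs, session_ids, subject_ids,
                                     labels) {
  if (length(window_probs) != length(session_ids))
    eeg_stop("data", "every window needs a session key")
  keys <- unique(session_ids)
  rows <- lapply(keys, function(k) {
    sel <- session_ids == k
    data.frame(subject_id = subject_ids[sel][1], session_id = k,
               label = labels[sel][1], score = mean(window_probs[sel]),
               n_windows = sum(sel))
  })
  do.call(rbind, rows)
}

#' ROC curve points
#'
#' Thresholds are the descending unique scores with a `+Inf` sentinel;
#' the decision rule is positive iff `score >= threshold`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    eeg_stop("data", "ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nn, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Youden-J operating point
#'
#' Maximizes `J = TPR - FPR` over the ROC thresholds; ties are broken
#' toward the smallest maximizing threshold (favouring sensitivity).
#'
#' @inheritParams roc_points
#' @param source Provenance tag stored in the result (e.g.
#'   `"validation_windows"` or `"pooled_oof_sessions"`).
#' @return list of class `operating_point`: `threshold`, `J`, `source`.
#' @export
youden_threshold <- function(scores, labels, source = "validation_windows") {
  rp <- roc_points(scores, labels)
  J <- rp$tpr - rp$fpr
  best <- max(J)
  cand <- rp$threshold[J >= best - 1e-12]
  thr <- min(cand[is.finite(cand)] %||% cand)
  if (!is.finite(thr)) thr <- max(scores)
  structure(list(threshold = thr, J = best, source = source),
            class = "operating_point")
}

#' ROC AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (rank formulation of the Mann-Whitney statistic).
#'
#' @inheritParams roc_points
#' @return Value in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    eeg_stop("data", "AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# average-precision PR AUC (step-wise interpolation)
pr_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y == 1)
  sum(diff(c(0, rec)) * prec)
}

#' Wilson score interval
#'
#' @param k Successes.
#' @param n Trials (>= 1).
#' @param confidence Confidence level.
#' @return Named vector `(lo, hi)` in percent.
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (n < 1) eeg_stop("data", "wilson_interval needs n >= 1")
  if (k < 0 || k > n) eeg_stop("data", "k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = 100 * (centre - half) / den, hi = 100 * (centre + half) / den)
}

#' Exact two-sided binomial test
#'
#' Minimum-likelihood two-sided p-value: the sum of `P(X = x)` over all
#' outcomes at most as likely as the observed count under
#' `Binomial(n, p0)` (the convention of `stats::binom.test`).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @return p-value.
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5) {
  if (k < 0 || k > n) eeg_stop("data", "k must lie in [0, n]")
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

guard0 <- function(num, den) if (den <= 0) 0 else num / den

#' Classification metrics report
#'
#' Confusion counts with TRUTH (label 1) as the positive class, accuracy,
#' balanced accuracy, per-class precision/recall/F1 with macro and
#' support-weighted averages, MCC, Wilson 95% intervals for accuracy and
#' the per-class recalls, and (when scores are supplied) ROC AUC and PR
#' AUC. Zero-denominator rates are reported as 0 and flagged.
#'
#' @param predictions Binary predictions.
#' @param labels Binary reference labels.
#' @param scores Optional continuous scores for the AUCs.
#' @return list of class `metrics_report`.
#' @export
classification_report <- function(predictions, labels, scores = NULL) {
  tp <- sum(predictions == 1 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  n <- tp + tn + fp + fn
  prec1 <- guard0(tp, tp + fp); rec1 <- guard0(tp, tp + fn)
  prec0 <- guard0(tn, tn + fn); rec0 <- guard0(tn, tn + fp)
  f1 <- function(p, r) guard0(2 * p * r, p + r)
  f11 <- f1(prec1, rec1); f10 <- f1(prec0, rec0)
  sup1 <- tp + fn; sup0 <- tn + fp
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den <= 0) 0 else (tp * tn - fp * fn) / mcc_den
  degenerate <- (tp + fp == 0) || (tn + fn == 0) || (sup1 == 0) || (sup0 == 0)
  rep <- list(
    counts = c(TN = tn, FP = fp, FN = fn, TP = tp),
    n = n,
    accuracy = guard0(tp + tn, n),
    balanced_accuracy = (rec0 + rec1) / 2,
    per_class = data.frame(
      class = c(0L, 1L),
      precision = c(prec0, prec1), recall = c(rec0, rec1),
      f1 = c(f10, f11), support = c(sup0, sup1)),
    macro = c(precision = (prec0 + prec1) / 2, recall = (rec0 + rec1) / 2,
              f1 = (f10 + f11) / 2),
    weighted = c(
      precision = guard0(sup0 * prec0 + sup1 * prec1, n),
      recall = guard0(sup0 * rec0 + sup1 * rec1, n),
      f1 = guard0(sup0 * f10 + sup1 * f11, n)),
    mcc = mcc,
    wilson_accuracy = wilson_interval(tp + tn, n),
    wilson_recall_lie = if (sup0 > 0) wilson_interval(tn, sup0) else c(lo = 0, hi = 0),
    wilson_recall_truth = if (sup1 > 0) wilson_interval(tp, sup1) else c(lo = 0, hi = 0),
    degenerate = degenerate)
  if (!is.null(scores)) {
    rep$roc_auc <- roc_auc(scores, labels)
    rep$pr_auc <- pr_auc(scores, labels)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f (balanced %.4f, MCC %.4f), n = %d\n",
              x$accuracy, x$balanced_accuracy, x$mcc, x$n))
  cat(sprintf("counts TN=%d FP=%d FN=%d TP=%d\n",
              x$counts["TN"], x$counts["FP"], x$counts["FN"], x$counts["TP"]))
  print(x$per_class, row.names = FALSE)
  if (!is.null(x$roc_auc))
    cat(sprintf("ROC AUC %.4f, PR AUC %.4f\n", x$roc_auc, x$pr_auc))
  invisible(x)
}
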