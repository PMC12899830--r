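fake_sessions <- function(n_subjects = 27L) {
  data.frame(
    session_id = c(sprintf("S%02d_lie", 1:n_subjects),
                   sprintf("S%02d_truth", 1:n_subjects)),
    label = rep(0:1, each = n_subjects))
}

test_that("osw_split is stratified, disjoint, and sized 43/5/6 at n = 54", {
  sp <- osw_split(fake_sessions(), seed = 1L)
  expect_length(sp$train, 43L)
  expect_length(sp$val, 5L)
  expect_length(sp$test, 6L)
  all_ids <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_ids), sort(fake_sessions()$session_id))
  expect_equal(anyDuplicated(all_ids), 0L)
  # labels balanced within +/- 1 in every subset
  lab <- function(ids) sum(grepl("truth", ids))
  for (s in sp) expect_lte(abs(lab(s) - (length(s) - lab(s))), 1L)
  # deterministic for a seed, different across seeds
  expect_identical(sp, osw_split(fake_sessions(), seed = 1L))
  expect_false(identical(sp$test, osw_split(fake_sessions(), seed = 2L)$test))
  expect_error(osw_split(fake_sessions(3L)), class = "eegdecept_data_error")
})

test_that("grouped folds partition subjects 6/6/5/5/5 with inner validation", {
  subj <- rep(sprintf("S%02d", 1:27), each = 40L)
  fp <- grouped_folds(subj, K = 5L, seed = 3L)
  sizes <- sort(vapply(fp, function(f) length(f$test_subjects), 0L),
                decreasing = TRUE)
  expect_equal(sizes, c(6L, 6L, 5L, 5L, 5L))
  # each subject tested in exactly one fold
  tested <- unlist(lapply(fp, function(f) f$test_subjects))
  expect_equal(sort(tested), sort(unique(subj)))
  for (f in fp) {
    expect_length(intersect(subj[f$train_idx], f$test_subjects), 0L)
    expect_length(intersect(subj[f$val_idx], f$test_subjects), 0L)
    expect_length(intersect(f$train_idx, f$val_idx), 0L)
    pool <- length(f$train_idx) + length(f$val_idx)
    expect_lt(abs(length(f$val_idx) / pool - 0.1), 0.02)
  }
  expect_error(grouped_folds(subj, K = 30L),
               class = "eegdecept_config_error")
})

test_that("session aggregation averages probabilities per session", {
  ss <- aggregate_session_scores(rep(0.7, 6), rep(c("a", "b"), each = 3),
                                 rep("s1", 6), rep(c(0L, 1L), each = 3))
  expect_equal(ss$score, c(0.7, 0.7))
  ss2 <- aggregate_session_scores(c(0.2, 0.4, 0.9), rep("a", 3), rep("s", 3),
                                  rep(1L, 3))
  expect_equal(ss2$score, 0.5)
  expect_equal(ss2$n_windows, 3L)
  keys <- sample(letters[1:5], 40, replace = TRUE)
  ss3 <- aggregate_session_scores(runif(40), keys, keys, rep(0L, 40))
  expect_equal(nrow(ss3), length(unique(keys)))
})

test_that("roc_points matches an exhaustive threshold sweep", {
  scores <- c(0.9, 0.8, 0.2, 0.1); labels <- c(1, 1, 0, 0)
  rp <- roc_points(scores, labels)
  expect_true(any(rp$fpr == 0 & rp$tpr == 1))      # passes through (0, 1)
  rp_tied <- roc_points(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(nrow(rp_tied), 2L)
  expect_equal(rp_tied$fpr, c(0, 1))
  expect_equal(rp_tied$tpr, c(0, 1))
  set.seed(20)
  s <- round(runif(20), 2); y <- rbinom(20, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  rp <- roc_points(s, y)
  for (i in seq_len(nrow(rp))) {
    t <- rp$threshold[i]
    expect_equal(rp$tpr[i], sum(s >= t & y == 1) / sum(y == 1))
    expect_equal(rp$fpr[i], sum(s >= t & y == 0) / sum(y == 0))
  }
  expect_error(roc_points(1:5, rep(1, 5)), class = "eegdecept_data_error")
})

test_that("youden_threshold maximizes J with the smallest-threshold tie rule", {
  op <- youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(op$J, 1)
  expect_equal(op$threshold, 0.8)
  # brute-force sweep oracle on overlapping scores
  set.seed(21)
  s <- round(runif(30), 1); y <- rep(0:1, 15)
  op <- youden_threshold(s, y)
  sweep_J <- function(t) sum(s >= t & y == 1) / sum(y == 1) -
    sum(s >= t & y == 0) / sum(y == 0)
  cand <- sort(unique(s))
  best <- max(vapply(c(cand, Inf), sweep_J, 0))
  expect_equal(op$J, best)
  expect_equal(sweep_J(op$threshold), best)
  # smallest maximizing threshold
  expect_true(all(vapply(cand[cand < op$threshold], sweep_J, 0) < best))
  # degenerate identical scores
  opd <- youden_threshold(rep(0.4, 6), rep(0:1, 3))
  expect_equal(opd$threshold, 0.4)
  expect_equal(opd$J, 0)
})

test_that("roc_auc equals pair counting and links to Cliff's delta", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5)), 0.5)
  set.seed(22)
  s <- round(rnorm(30), 1); y <- rbinom(30, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y), auc_pair_oracle(s, y))
  # cross-module identity Delta = 2 AUC - 1 on any two-sample input
  for (rep in 1:3) {
    a <- round(rnorm(20), 1); b <- round(rnorm(25, 0.4), 1)
    auc <- roc_auc(c(a, b), c(rep(1, 20), rep(0, 25)))
    expect_equal(cliffs_delta(a, b), 2 * auc - 1, tolerance = 1e-12)
  }
})

test_that("classification_report reproduces the worked confusion matrix", {
  # TN=20 FP=7 FN=11 TP=16 with TRUTH (1) positive
  labels <- c(rep(0, 27), rep(1, 27))
  preds <- c(rep(0, 20), rep(1, 7), rep(0, 11), rep(1, 16))
  rep_ <- classification_report(preds, labels)
  expect_equal(unname(rep_$counts), c(20L, 7L, 11L, 16L))
  expect_equal(rep_$per_class$recall[1], 20 / 27)
  expect_equal(rep_$per_class$recall[2], 16 / 27)
  expect_equal(round(100 * rep_$per_class$recall, 1), c(74.1, 59.3))
  expect_equal(round(100 * rep_$accuracy, 1), 66.7)
  expect_equal(round(100 * rep_$per_class$precision, 1), c(64.5, 69.6))
  # all rates recomputable from the stored counts
  cts <- rep_$counts
  expect_equal(rep_$accuracy,
               unname((cts["TN"] + cts["TP"]) / sum(cts)))
  expect_equal(rep_$balanced_accuracy,
               unname((cts["TN"] / (cts["TN"] + cts["FP"]) +
                         cts["TP"] / (cts["TP"] + cts["FN"])) / 2))
  # degenerate cases
  perfect <- classification_report(labels, labels)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  onecls <- classification_report(rep(1, 54), labels)
  expect_equal(onecls$mcc, 0)
  expect_true(onecls$degenerate)
})

test_that("wilson_interval reproduces the published intervals", {
  expect_equal(round(wilson_interval(36, 54), 1),
               c(lo = 53.4, hi = 77.8))
  expect_equal(round(wilson_interval(20, 27), 1),
               c(lo = 55.3, hi = 86.8))
  expect_equal(round(wilson_interval(16, 27), 1),
               c(lo = 40.7, hi = 75.5))
  expect_equal(unname(wilson_interval(10, 10)["hi"]), 100)
  expect_equal(unname(wilson_interval(0, 10)["lo"]), 0)
  expect_error(wilson_interval(5, 0), class = "eegdecept_data_error")
})

test_that("exact binomial test matches enumeration and the published p", {
  expect_equal(round(exact_binomial_test(36, 54), 3), 0.020)
  expect_equal(exact_binomial_test(27, 54), 1)
  # full enumeration oracle at n = 8: walk all 2^8 outcome sequences
  outcomes <- as.matrix(expand.grid(rep(list(0:1), 8)))
  ks <- rowSums(outcomes)
  count_prob <- vapply(0:8, function(x) mean(ks == x), 0)
  for (k in 0:8) {
    oracle_p <- sum(count_prob[count_prob <= count_prob[k + 1] + 1e-12])
    expect_equal(exact_binomial_test(k, 8), oracle_p, tolerance = 1e-9,
                 info = paste("k =", k))
  }
  # agrees with the minimum-likelihood convention of stats::binom.test
  for (kn in list(c(36, 54), c(5, 20), c(13, 17))) {
    expect_equal(exact_binomial_test(kn[1], kn[2]),
                 stats::binom.test(kn[1], kn[2], 0.5)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("report serialization round-trips through JSON", {
  labels <- rep(0:1, each = 10)
  preds <- c(rep(0, 8), rep(1, 2), rep(0, 3), rep(1, 7))
  rp <- classification_report(preds, labels, scores = seq(0, 1, length.out = 20))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(rp)[c("counts", "accuracy", "mcc", "roc_auc")],
                       f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(back$counts), unname(rp$counts),
               ignore_attr = TRUE)
  expect_equal(back$accuracy, rp$accuracy)
  expect_equal(back$roc_auc, rp$roc_auc)
})
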