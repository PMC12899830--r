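# End-to-end driver smoke tests on reduced configurations: full protocol
# code, tiny model capacity and session durations to stay desk-scale.

test_that("subject-dependent driver honours the session-disjoint contract", {
  ds <- tiny_dataset(n_subjects = 10L, duration_s = 10, class_effect = 0.9,
                     subject_sd = 0, seed = 5L, preprocess = TRUE)
  r <- run_subject_dependent(
    ds$records, model_spec = tiny_tcn_spec(),
    tconfig = train_config(epochs = 2L, batch_size = 128L, loss = "bce",
                           mixup_alpha = 0, checkpoint = FALSE, seed = 1L))
  # no test window's session appears in train or validation
  expect_length(intersect(r$split$test, c(r$split$train, r$split$val)), 0L)
  expect_equal(sort(unique(r$session_scores$session_id)), sort(r$split$test))
  expect_equal(r$operating_point$source, "validation_windows")
  expect_true(all(r$window_probs > 0 & r$window_probs < 1))
  expect_equal(r$session_report$n, length(r$split$test))
  expect_equal(nrow(r$history), 2L)
})

test_that("cross-subject driver is subject-disjoint with one global threshold", {
  ds <- tiny_dataset(n_subjects = 6L, duration_s = 10, class_effect = 0.5,
                     seed = 9L, preprocess = TRUE)
  r <- run_cross_subject(
    ds$records, model_spec = tiny_resnet_spec(),
    tconfig = train_config(epochs = 2L, batch_size = 64L, loss = "focal",
                           schedule = "plateau", mixup_alpha = 0.2,
                           checkpoint = TRUE, seed = 2L),
    K = 3L)
  # every session scored exactly once, all 12 sessions present
  expect_equal(nrow(r$session_scores), 12L)
  expect_equal(r$session_report$n, 12L)
  # single global threshold calibrated on pooled out-of-fold session scores
  expect_length(r$operating_point$threshold, 1L)
  expect_equal(r$operating_point$source, "pooled_oof_sessions")
  # subject-disjointness inside every fold
  for (f in r$folds) {
    pool_subjects <- r$window_meta$subject_id[c(f$train_idx, f$val_idx)]
    expect_length(intersect(f$test_subjects, pool_subjects), 0L)
    test_subjects <- unique(r$window_meta$subject_id[f$test_idx])
    expect_setequal(test_subjects, f$test_subjects)
  }
  expect_equal(nrow(r$fold_stats), 3L)
  expect_true(r$binomial_p >= 0 && r$binomial_p <= 1)
  # decisions recomputable from scores and the stored threshold
  expect_equal(unname(r$session_report$counts["TP"]),
               sum(r$session_scores$score >= r$operating_point$threshold &
                     r$session_scores$label == 1L))
})

test_that("describe driver emits the quartile and effect-size tables", {
  ds <- tiny_dataset(n_subjects = 3L, duration_s = 10, seed = 4L,
                     preprocess = TRUE)
  d <- describe_dataset(ds$records)
  expect_equal(ncol(d$desc), 65L)
  expect_equal(nrow(d$band_summary), 5L)
  expect_equal(d$band_summary$iqr_truth,
               d$band_summary$q3_truth - d$band_summary$q1_truth)
  expect_equal(nrow(d$effect_sizes), 5L)
  expect_true(all(abs(d$effect_sizes$cliffs_delta) <= 1))
})

test_that("CLI simulates byte-identical datasets and returns exit codes", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  code <- run_cli(c("simulate", "--out", out1, "--seed", "11",
                    "--subjects", "2", "--duration", "5"))
  expect_equal(code, 0L)
  expect_length(list.files(out1, pattern = "\\.csv$"), 5L)  # 4 sessions + manifest
  run_cli(c("simulate", "--out", out2, "--seed", "11",
            "--subjects", "2", "--duration", "5"))
  for (f in list.files(out1, pattern = "\\.csv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  # usage errors
  expect_equal(run_cli(character(0)), 2L)
  expect_equal(run_cli(c("frobnicate")), 2L)
  expect_equal(run_cli(c("osw", "--config")), 2L)
  # config round trip: echoed config reloads to the same values
  cfg <- jsonlite::read_json(file.path(out1, "run_config.json"),
                             simplifyVector = TRUE)
  expect_equal(cfg$seed, 11L)
  expect_equal(cfg$synth$n_subjects, 2L)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 99L, synth = list(n_subjects = 3L)), f,
                       auto_unbox = TRUE)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$seed, 99L)
  expect_equal(cfg2$synth$n_subjects, 3L)
  expect_equal(cfg2$preprocess$bp_high, 45)  # defaults merged in
})

test_that("CLI describe command writes its reports", {
  out <- withr::local_tempdir()
  code <- run_cli(c("describe", "--out", out, "--seed", "3",
                    "--subjects", "2", "--duration", "5"))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "band_summary.csv")))
  expect_true(file.exists(file.path(out, "effect_sizes.csv")))
  expect_true(file.exists(file.path(out, "run_config.json")))
  bs <- utils::read.csv(file.path(out, "band_summary.csv"))
  expect_equal(nrow(bs), 5L)
})
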