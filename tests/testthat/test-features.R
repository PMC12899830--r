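fs <- 128

test_that("welch_psd has the documented resolution and satisfies Parseval", {
  x <- sin(2 * pi * 10 * (0:255) / fs)
  ps <- welch_psd(x, fs)
  expect_equal(ps$freqs[2] - ps$freqs[1], 0.5)       # 0.5 Hz bins at N >= 256
  expect_equal(ps$freqs[which.max(ps$psd)], 10)
  expect_equal(welch_psd(numeric(64), fs)$psd, numeric(33))
  set.seed(10)
  for (n in c(256L, 1000L)) {
    w <- rnorm(n)
    ps <- welch_psd(w, fs)
    expect_equal(trapz(ps$freqs, ps$psd), mean((w - mean(w))^2),
                 tolerance = 0.1)
  }
})

test_that("band powers integrate correctly and tile the pass band", {
  ps <- list(freqs = seq(0, 64, 0.5), psd = numeric(129))
  expect_equal(band_power(ps$freqs, ps$psd, 8, 13), 0)
  expect_warning(band_power(ps$freqs, ps$psd, 70, 80), "empty")
  x <- sin(2 * pi * 10 * (0:255) / fs)
  ps <- welch_psd(x, fs)
  alpha <- band_power(ps$freqs, ps$psd, 8, 13)
  total <- band_power(ps$freqs, ps$psd, 1, 45)
  expect_gt(alpha / total, 0.9)
  set.seed(11)
  w <- rnorm(512)
  ps <- welch_psd(w, fs)
  parts <- sum(vapply(seq_len(5), function(b)
    band_power(ps$freqs, ps$psd, CANONICAL_BANDS$lo[b],
               CANONICAL_BANDS$hi[b]), 0))
  expect_equal(parts, band_power(ps$freqs, ps$psd, 1, 45), tolerance = 0.01)
})

test_that("hjorth parameters match guards and the sinusoid closed form", {
  expect_equal(hjorth_params(rep(2, 100)),
               c(activity = 0, mobility = 0, complexity = 0))
  for (f in c(5, 10, 20)) {
    x <- sin(2 * pi * f * (0:2047) / fs)
    h <- hjorth_params(x)
    expect_equal(unname(h["mobility"]), 2 * sin(pi * f / fs),
                 tolerance = 1e-3)
  }
  set.seed(12)
  comp <- replicate(100, hjorth_params(rnorm(256))["complexity"])
  expect_true(all(comp > 1))
})

test_that("DESC has 65 columns with consistent aggregates", {
  r <- tiny_session()
  w <- segment_session(r, 2.0, 1.0)[[1]]
  d <- desc_features(w, 0L, fs)
  expect_equal(ncol(d), 65L)
  expect_equal(sum(!vapply(d, is.numeric, TRUE)), 2L)  # subject + session ids
  meta <- c("subject_id", "session_id", "label", "window_index",
            "start_time_s")
  expect_equal(ncol(d) - length(meta), DESC_NUMERIC_DIM)
  # aggregates equal mean/sd of the per-channel band powers by definition
  per_ch <- vapply(EEG_CHANNELS, function(ch) d[[paste0(ch, "_alpha")]], 0)
  expect_equal(d$bandmean_alpha, mean(per_ch))
  expect_equal(d$bandsd_alpha, sqrt(mean((per_ch - mean(per_ch))^2)))
  # identical channels collapse the SD aggregates to zero
  wi <- w; wi$data <- matrix(w$data[, 1], nrow(w$data), 5,
                             dimnames = list(NULL, EEG_CHANNELS))
  di <- desc_features(wi, 0L, fs)
  expect_equal(di$bandsd_delta, 0)
  expect_equal(di$bandsd_gamma, 0)
})

test_that("DWT vector has 175 values, conserves energy, guards zeros", {
  r <- tiny_session()
  w <- zscore_window(segment_session(r, 2.0, 0.25)[[3]])
  v <- dwt_features(w)
  expect_length(v, 175L)
  expect_true(all(is.finite(v)))
  # relative energies per channel sum to 1
  for (ch in EEG_CHANNELS) {
    rel <- v[grepl(paste0("^", ch, "_.*_relenergy$"), names(v))]
    expect_equal(sum(rel), 1, tolerance = 1e-10)
  }
  # orthogonal transform: sub-band energies sum to the signal energy
  x <- w$data[, 1]
  cf <- dwt_db4(x, 4L)
  expect_equal(sum(vapply(cf, function(c) sum(c^2), 0)), sum(x^2),
               tolerance = 1e-8)
  # zero window: all statistics and energies are zero by guard
  wz <- w; wz$data[] <- 0
  expect_equal(unname(dwt_features(wz)), rep(0, 175L))
  # too-short windows are refused
  ws <- w; ws$data <- w$data[1:32, ]
  expect_error(dwt_features(ws), class = "eegdecept_data_error")
})

test_that("spectral and differential entropies match closed forms", {
  expect_equal(spectral_entropy(c(0, 5, 0, 0)), 0)
  expect_equal(spectral_entropy(rep(2, 64)), 1)
  expect_equal(spectral_entropy(numeric(10)), 0)
  set.seed(13)
  se <- replicate(20, spectral_entropy(welch_psd(rnorm(256), fs)$psd))
  expect_true(all(se >= 0.8))
  expect_equal(differential_entropy_band(1 / (2 * pi * exp(1))), 0)
  expect_equal(differential_entropy_band(1), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  expect_equal(differential_entropy_band(1), 1.41894, tolerance = 1e-5)
  p <- sort(runif(10, 0.001, 10))
  expect_true(all(diff(differential_entropy_band(p)) > 0))
})

test_that("FEATS vector has 167 values with antisymmetric frontal indices", {
  r <- tiny_session()
  w <- zscore_window(segment_session(r, 2.0, 0.25)[[2]])
  v <- feats_vector(w, fs)
  expect_length(v, 167L)
  expect_true(all(is.finite(v)))
  for (ch in EEG_CHANNELS) {
    rel <- v[grepl(paste0("^", ch, "_rel_"), names(v))]
    expect_length(rel, 11L)
    expect_equal(sum(rel), 1, tolerance = 1e-10)
  }
  # swapping AF3 and AF4 negates both asymmetry terms
  ws <- w
  ws$data[, c("AF3", "AF4")] <- w$data[, c("AF4", "AF3")]
  vs <- feats_vector(ws, fs)
  expect_equal(unname(vs["frontal_asym_alpha"]),
               -unname(v["frontal_asym_alpha"]), tolerance = 1e-10)
  expect_equal(unname(vs["frontal_asym_beta"]),
               -unname(v["frontal_asym_beta"]), tolerance = 1e-10)
  # zero window stays finite through every guard
  wz <- w; wz$data[] <- 0
  expect_true(all(is.finite(feats_vector(wz, fs))))
})

test_that("cliffs_delta equals the O(n^2) pair oracle", {
  expect_equal(cliffs_delta(c(1, 1, 1), c(1, 1)), 0)
  expect_equal(cliffs_delta(c(5, 6, 7), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 2), c(5, 6, 7)), -1)
  set.seed(14)
  for (rep in 1:3) {
    a <- round(rnorm(50), 1)  # rounding forces ties
    b <- round(rnorm(50, 0.3), 1)
    expect_equal(cliffs_delta(a, b), cliffs_delta_oracle(a, b))
  }
  expect_error(cliffs_delta(numeric(0), 1), class = "eegdecept_data_error")
})

test_that("band_power_summary reproduces sort-based order statistics", {
  # type-7 quantile oracle written out explicitly
  q7 <- function(v, p) {
    v <- sort(v); n <- length(v)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  set.seed(15)
  desc <- data.frame(label = rep(0:1, each = 500))
  for (b in CANONICAL_BANDS$name)
    desc[[paste0("bandmean_", b)]] <- rlnorm(1000, meanlog = 2)
  s <- band_power_summary(desc)
  expect_equal(nrow(s), 5L)
  for (i in seq_len(5)) {
    v1 <- desc[[paste0("bandmean_", s$band[i])]][desc$label == 1L]
    expect_equal(s$q1_truth[i], q7(v1, 0.25))
    expect_equal(s$median_truth[i], q7(v1, 0.5))
    expect_equal(s$q3_truth[i], q7(v1, 0.75))
  }
  expect_equal(s$iqr_truth, s$q3_truth - s$q1_truth)
  expect_equal(s$iqr_lie, s$q3_lie - s$q1_lie)
  expect_equal(s$delta_median, s$median_truth - s$median_lie)
  # single row per class: quartiles collapse
  d1 <- desc[c(1, 501), ]
  s1 <- band_power_summary(d1)
  expect_equal(s1$q1_truth, s1$median_truth)
  expect_equal(s1$median_truth, s1$q3_truth)
  expect_equal(s1$iqr_truth, rep(0, 5))
})
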