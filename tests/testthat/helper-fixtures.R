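# Shared fixtures: all built in code, cached per test run because
# generation + preprocessing is the expensive part.

tiny_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_subjects = 2L, duration_s = 10, class_effect = 0.5,
           subject_sd = 0.3, seed = 7L, preprocess = FALSE) {
    key <- paste(n_subjects, duration_s, class_effect, subject_sd, seed,
                 preprocess, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- synth_config(n_subjects = n_subjects, duration_s = duration_s,
                        class_effect = class_effect, subject_sd = subject_sd,
                        seed = seed)
    ds <- generate_dataset(cfg)
    if (preprocess) ds$records <- preprocess_dataset(ds$records)
    cache[[key]] <- ds
    ds
  }
})

# one preprocessed session reused by windowing/feature tests
tiny_session <- function() {
  tiny_dataset(n_subjects = 1L, duration_s = 10, seed = 7L,
               preprocess = TRUE)$records[[1]]
}

# reduced model specs: full protocol code, desk-scale capacity
tiny_resnet_spec <- function() {
  resnet_se_spec(stage_filters = c(8L, 12L, 16L), head_units = 16L)
}

tiny_tcn_spec <- function(...) {
  res_tcn_spec(stem_filters = 8L, block_filters = c(8L, 12L, 16L, 20L, 24L),
               raw_head_units = 24L, dwt_units = c(32L, 16L),
               feats_units = c(32L, 16L), fusion_units = 24L,
               attention_units = 8L, ...)
}

# brute-force O(n^2) oracles
cliffs_delta_oracle <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + sign(x - y)
  s / (length(a) * length(b))
}

auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

rms <- function(x) sqrt(mean(x^2))
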