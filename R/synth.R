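#' Synthetic five-channel EEG with known ground truth
#'
#' Generates wearable-EEG-like datasets: 27 subjects x 2 sessions (one LIE, one
#' TRUTH), ~75 s at 128 Hz on the AF3/T7/Pz/T8/AF4 montage. Each channel is
#' a sum of band-limited Gaussian components in the five canonical bands,
#' a 1/f background, a 50 Hz mains sinusoid, and sparse one-sided
#' exponential-decay transients. Class separation enters as a multiplicative
#' gain on the band components (delta/theta up for LIE, beta/gamma up for
#' TRUTH, matching the direction of the reported descriptive statistics);
#' between-subject heterogeneity as log-normal per-subject, per-band gain
#' multipliers.
#'
#' @name synth_eeg
NULL

#' Canonical EEG frequency bands (Hz)
#' @export
CANONICAL_BANDS <- data.frame(
  name = c("delta", "theta", "alpha", "beta", "gamma"),
  lo = c(1, 4, 8, 13, 30),
  hi = c(4, 8, 13, 30, 45)
)

#' Synthetic dataset configuration
#'
#' Defaults state the emulated world: 27 subjects, two ~75 s sessions each,
#' 128 Hz, five channels. Band gains are the per-band component standard
#' deviations in microvolts, chosen so pooled cross-channel mean band powers
#' land on the scale of the descriptive statistics reported for the real
#' recordings (delta by far the largest, gamma the smallest).
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject Sessions per subject (2: one per label).
#' @param duration_s Session duration in seconds.
#' @param fs Sampling rate, Hz.
#' @param channel_names Five channel labels.
#' @param band_gains Named per-band baseline SD (uV) for delta..gamma.
#' @param class_effect Fraction in `[0,1]` scaling the LIE-vs-TRUTH band-gain
#'   shift; 0 makes both classes identically distributed.
#' @param subject_sd Between-subject log-gain standard deviation.
#' @param mains_amp Amplitude (uV) of the 50 Hz mains component.
#' @param artifact_rate Transient artifact rate, events per second.
#' @param artifact_amp_mult Artifact amplitude as a multiple of the channel SD.
#' @param seed Integer master seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 27L, sessions_per_subject = 2L,
                         duration_s = 75, fs = 128,
                         channel_names = EEG_CHANNELS,
                         band_gains = c(delta = 17, theta = 8, alpha = 5.5,
                                        beta = 6.5, gamma = 4),
                         class_effect = 0.5, subject_sd = 0.3,
                         mains_amp = 2, artifact_rate = 0.1,
                         artifact_amp_mult = 8, seed = 42L) {
  if (duration_s <= 0 || fs <= 0)
    eeg_stop("config", "duration_s and fs must be positive")
  if (round(duration_s * fs) < 1)
    eeg_stop("config", "duration_s * fs must be at least 1 sample")
  if (class_effect < 0 || class_effect > 1)
    eeg_stop("config", "class_effect must lie in [0, 1]")
  if (sessions_per_subject != 2L)
    eeg_stop("config", "sessions_per_subject must be 2 (one session per label)")
  stopifnot(length(channel_names) == 5L,
            identical(sort(names(band_gains)), sort(CANONICAL_BANDS$name)))
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = 2L,
                 duration_s = duration_s, fs = fs,
                 channel_names = channel_names,
                 band_gains = band_gains[CANONICAL_BANDS$name],
                 class_effect = class_effect, subject_sd = subject_sd,
                 mains_amp = mains_amp, artifact_rate = artifact_rate,
                 artifact_amp_mult = artifact_amp_mult,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Per-subject log-normal band-gain multipliers; drawn from the subject's own
# seed so the draw is independent of how many subjects the dataset has.
subject_band_gains <- function(config, subject_index) {
  set.seed(derive_seed(config$seed, 1L, subject_index))
  mult <- exp(stats::rnorm(5, mean = 0, sd = config$subject_sd))
  g <- config$band_gains * mult
  names(g) <- CANONICAL_BANDS$name
  g
}

# Class gain multiplier per band: (1 +/- 0.3 * class_effect); delta/theta up
# for LIE (label 0), beta/gamma up for TRUTH (label 1), alpha unchanged.
class_band_mult <- function(class_effect, label) {
  shift <- 0.3 * class_effect
  if (label == 0L) {
    c(delta = 1 + shift, theta = 1 + shift, alpha = 1,
      beta = 1 - shift, gamma = 1 - shift)
  } else {
    c(delta = 1 - shift, theta = 1 - shift, alpha = 1,
      beta = 1 + shift, gamma = 1 + shift)
  }
}

# 1/f-amplitude background noise via FFT shaping, unit SD then scaled.
one_over_f_noise <- function(n, scale) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))          # avoid division by zero at DC
  shape <- 1 / sqrt(pmin(f, n - f + 1))
  shape[1] <- 0                       # remove DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / sd_pop(x) * scale
}

#' Generate one synthetic session
#'
#' @param config A [synth_config()].
#' @param subject Subject index (1-based) used for identity and seeding.
#' @param label 0 = LIE, 1 = TRUTH.
#' @param session_index Index used only for seed derivation (default
#'   `label + 1`).
#' @return A [session_record()].
#' @export
generate_session <- function(config, subject, label,
                             session_index = label + 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (!label %in% c(0L, 1L)) eeg_stop("config", "label must be 0 or 1")
  n <- round(config$duration_s * config$fs)
  fs <- config$fs
  gains <- subject_band_gains(config, subject) *
    class_band_mult(config$class_effect, label)
  set.seed(derive_seed(config$seed, 2L, subject, session_index))
  nch <- length(config$channel_names)
  X <- matrix(0, n, nch)
  for (ch in seq_len(nch)) {
    sig <- one_over_f_noise(n, scale = 3)
    for (b in seq_len(nrow(CANONICAL_BANDS))) {
      comp <- stats::rnorm(n)
      comp <- bandpass_filter(comp, fs, filter_spec(
        bp_low = CANONICAL_BANDS$lo[b], bp_high = CANONICAL_BANDS$hi[b]))
      sig <- sig + comp / sd_pop(comp) * gains[b]
    }
    phi <- stats::runif(1, 0, 2 * pi)
    sig <- sig + config$mains_amp * sin(2 * pi * 50 * (0:(n - 1)) / fs + phi)
    # sparse one-sided exponential transients (tau = 50 ms)
    n_events <- stats::rpois(1, config$artifact_rate * config$duration_s)
    if (n_events > 0) {
      base_sd <- sd_pop(sig)
      tau <- 0.05 * fs
      kern_len <- ceiling(6 * tau)
      kern <- exp(-(0:(kern_len - 1)) / tau)
      starts <- sample.int(n, n_events, replace = TRUE)
      signs <- sample(c(-1, 1), n_events, replace = TRUE)
      for (e in seq_len(n_events)) {
        idx <- starts[e]:min(n, starts[e] + kern_len - 1L)
        sig[idx] <- sig[idx] +
          signs[e] * config$artifact_amp_mult * base_sd *
          kern[seq_along(idx)]
      }
    }
    X[, ch] <- sig
  }
  session_record(subject_id = sprintf("S%02d", subject),
                 session_id = sprintf("S%02d_%s", subject,
                                      if (label == 1L) "truth" else "lie"),
                 label = label, fs = fs, samples = X,
                 channel_names = config$channel_names)
}

#' Generate a full synthetic dataset
#'
#' One LIE and one TRUTH session per subject, so labels are exactly balanced
#' for any number of subjects.
#'
#' @param config A [synth_config()].
#' @return list with `records` (list of [session_record()]) and `manifest`
#'   (data.frame: subject_id, session_id, label, file).
#' @export
generate_dataset <- function(config = synth_config()) {
  records <- list()
  for (s in seq_len(config$n_subjects)) {
    for (label in c(0L, 1L)) {
      records[[length(records) + 1L]] <- generate_session(config, s, label)
    }
  }
  manifest <- data.frame(
    subject_id = vapply(records, function(r) r$subject_id, ""),
    session_id = vapply(records, function(r) r$session_id, ""),
    label = vapply(records, function(r) r$label, 0L),
    file = paste0(vapply(records, function(r) r$session_id, ""), ".csv")
  )
  list(records = records, manifest = manifest)
}

#' Write a generated dataset to disk
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest file.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(dataset$records)) {
    write_session_csv(dataset$records[[i]],
                      file.path(dir, dataset$manifest$file[i]))
  }
  write_manifest_csv(dataset$manifest, file.path(dir, "manifest.csv"))
}
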