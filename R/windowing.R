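#' Sliding-window segmentation
#'
#' Fixed-length overlapping windows with session-label inheritance; partial
#' segments at the recording end are discarded. Indexing is 0-based,
#' left-closed right-open. The three standard configurations are
#' 2.0 s / 0.25 s (subject-dependent OSW), 3.0 s / 0.25 s (cross-subject)
#' and 2.0 s / 1.0 s (descriptive features, not z-scored).
#'
#' @name windowing
NULL

#' Number of full windows in a recording
#'
#' @param n_samples Recording length in samples.
#' @param win_samples Window length in samples.
#' @param hop_samples Hop in samples.
#' @return `max(0, floor((n_samples - win_samples) / hop_samples) + 1)`.
#' @export
count_windows <- function(n_samples, win_samples, hop_samples) {
  if (win_samples <= 0 || hop_samples <= 0)
    eeg_stop("config", "win_samples and hop_samples must be positive")
  max(0L, floor((n_samples - win_samples) / hop_samples) + 1L)
}

# Seconds -> samples with a tolerance for floating-point nuisance.
to_samples <- function(seconds, fs) {
  v <- seconds * fs
  if (abs(v - round(v)) > 1e-6)
    eeg_stop("config", "%g s is not an integer number of samples at %g Hz",
             seconds, fs)
  as.integer(round(v))
}

#' Segment one session into windows
#'
#' @param record A preprocessed [session_record()].
#' @param win_s Window length, seconds.
#' @param hop_s Hop, seconds.
#' @return List of `window` objects: `data` (win x channels matrix),
#'   `subject_id`, `session_id`, `label`, `start_sample` (0-based),
#'   `start_time_s`, `zscored` flag.
#' @export
segment_session <- function(record, win_s = 2.0, hop_s = 0.25) {
  stopifnot(inherits(record, "session_record"))
  W <- to_samples(win_s, record$fs)
  H <- to_samples(hop_s, record$fs)
  n <- nrow(record$samples)
  k <- count_windows(n, W, H)
  lapply(seq_len(k), function(i) {
    s0 <- (i - 1L) * H              # 0-based start
    structure(list(data = record$samples[(s0 + 1L):(s0 + W), , drop = FALSE],
                   subject_id = record$subject_id,
                   session_id = record$session_id,
                   label = record$label,
                   start_sample = s0,
                   start_time_s = s0 / record$fs,
                   zscored = FALSE),
              class = "eeg_window")
  })
}

#' Per-channel window z-scoring
#'
#' Population standard deviation (no Bessel correction) with an epsilon
#' guard: a constant channel becomes all zeros.
#'
#' @param window An `eeg_window`.
#' @param epsilon Lower bound on the standard deviation.
#' @return The window with standardized columns and `zscored = TRUE`.
#' @export
zscore_window <- function(window, epsilon = 1e-8) {
  X <- window$data
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)
  sdv <- pmax(sdv, epsilon)
  window$data <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  window$zscored <- TRUE
  window
}

#' Segment a dataset
#'
#' @param records List of preprocessed [session_record()]s.
#' @param win_s,hop_s Window length and hop, seconds.
#' @param zscore Whether to z-score each window per channel.
#' @return Flat list of windows.
#' @export
segment_dataset <- function(records, win_s = 2.0, hop_s = 0.25,
                            zscore = TRUE) {
  out <- unlist(lapply(records, segment_session, win_s = win_s,
                       hop_s = hop_s), recursive = FALSE)
  if (zscore) out <- lapply(out, zscore_window)
  out
}
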