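#' Hand-crafted window descriptors
#'
#' Three feature families computed from preprocessed windows: a 60-number
#' interpretable descriptor (DESC: canonical band powers, Hjorth parameters,
#' band ratios and cross-channel aggregates, plus 5 metadata columns = 65
#' columns), 175 db4 DWT sub-band statistics, and a 167-number extended
#' spectral-statistical vector (FEATS) with differential entropies and
#' frontal asymmetry indices. Plus the descriptive statistics used to
#' summarize class differences (quartiles/IQR, Cliff's delta).
#'
#' @name features
NULL

#' Extended FEATS band edges (Hz), clipped to Nyquist at use time
#' @export
FEATS_BANDS <- data.frame(
  name = c("delta", "theta", "alpha", "alpha_low", "alpha_high",
           "beta", "beta_low", "beta_high", "gamma", "gamma_low",
           "gamma_mid"),
  lo = c(0.5, 4, 8, 8, 10, 13, 13, 20, 30, 30, 45),
  hi = c(4, 8, 13, 10, 13, 30, 20, 30, 65, 45, 65)
)

#' Welch power spectral density
#'
#' Hann window (periodic), constant detrending per segment, segment length
#' `min(256, N)` with 50% overlap for longer signals; one-sided density so
#' that the integral over frequency approximates the signal variance.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @return list with `freqs` and `psd` (uV^2/Hz for uV input).
#' @export
welch_psd <- function(x, fs) {
  N <- length(x)
  if (N < 2L) eeg_stop("data", "welch_psd needs at least 2 samples")
  nper <- min(256L, N)
  step <- if (N > nper) nper %/% 2L else nper
  starts <- seq(1L, N - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1L)) / nper)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 * scale
    P <- P[seq_len(nfreq)]
    P[2:(nfreq - 1L)] <- 2 * P[2:(nfreq - 1L)]  # one-sided doubling
    acc <- acc + P
  }
  list(freqs = (seq_len(nfreq) - 1L) * fs / nper, psd = acc / length(starts))
}

#' Band power by trapezoidal integration of the PSD
#'
#' @param freqs,psd As returned by [welch_psd()].
#' @param lo,hi Band edges in Hz; clipped to the available frequency range.
#' @return Integrated power; 0 (with a warning) if no bins fall in the band.
#' @export
band_power <- function(freqs, psd, lo, hi) {
  lo <- max(lo, freqs[1]); hi <- min(hi, freqs[length(freqs)])
  sel <- which(freqs >= lo & freqs <= hi)
  if (length(sel) < 2L) {
    warning("empty frequency-bin range for band [", lo, ", ", hi, "] Hz")
    return(0)
  }
  trapz(freqs[sel], psd[sel])
}

#' Hjorth parameters
#'
#' Activity = variance; mobility = sqrt(var(diff(x))/var(x)); complexity =
#' mobility(diff(x))/mobility(x). First differences, no sampling-rate
#' scaling; zero-variance inputs return 0 by guard.
#'
#' @param x Numeric signal of length >= 3.
#' @return Named vector `(activity, mobility, complexity)`.
#' @export
hjorth_params <- function(x) {
  if (length(x) < 3L) eeg_stop("data", "hjorth_params needs >= 3 samples")
  v0 <- stats::var(x)
  if (v0 < .Machine$double.eps)
    return(c(activity = 0, mobility = 0, complexity = 0))
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 < .Machine$double.eps)
    return(c(activity = v0, mobility = mob, complexity = 0))
  comp <- sqrt(stats::var(d2) / v1) / mob
  c(activity = v0, mobility = mob, complexity = comp)
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the PSD normalized to a probability vector, divided by
#' `log(number of bins)`, so the value lies in `[0, 1]`; an all-zero PSD
#' returns 0.
#'
#' @param psd Non-negative PSD values.
#' @return Value in `[0, 1]`.
#' @export
spectral_entropy <- function(psd) {
  tot <- sum(psd)
  if (tot <= 0) return(0)
  p <- psd / tot
  p <- p[p > 0]
  if (length(p) <= 1L) return(0)
  -sum(p * log(p)) / log(length(psd))
}

#' Band-limited differential entropy
#'
#' `0.5 * log(2 * pi * e * max(P, eps))` with `eps = 1e-12`, the closed form
#' for a Gaussian of variance `P`.
#'
#' @param band_power_value Band power (>= 0).
#' @export
differential_entropy_band <- function(band_power_value) {
  0.5 * log(2 * pi * exp(1) * pmax(band_power_value, 1e-12))
}

guarded_ratio <- function(num, den) if (den <= 0) 0 else num / den

#' DESC descriptor for one window (65 columns)
#'
#' Per channel: the five canonical band powers, Hjorth activity/mobility/
#' complexity, beta/alpha and theta/alpha ratios (10 x 5 = 50); plus
#' cross-channel mean and SD of each band power (10); plus 5 metadata
#' columns (subject_id, session_id, label, window_index, start_time_s).
#' Windows come from the 2.0 s / 1.0 s descriptive stream and are not
#' z-scored.
#'
#' @param window An `eeg_window` (not z-scored).
#' @param window_index Running index within the session.
#' @param fs Sampling rate, Hz.
#' @return One-row data.frame with 65 columns (60 numeric + 5 metadata).
#' @export
desc_features <- function(window, window_index = 0L, fs = 128) {
  X <- window$data
  chn <- colnames(X)
  bp <- matrix(0, length(chn), 5, dimnames = list(chn, CANONICAL_BANDS$name))
  per_ch <- numeric(0)
  for (ch in seq_along(chn)) {
    ps <- welch_psd(X[, ch], fs)
    for (b in seq_len(5))
      bp[ch, b] <- band_power(ps$freqs, ps$psd,
                              CANONICAL_BANDS$lo[b], CANONICAL_BANDS$hi[b])
    hj <- hjorth_params(X[, ch])
    vals <- c(bp[ch, ], hj,
              beta_alpha = guarded_ratio(bp[ch, "beta"], bp[ch, "alpha"]),
              theta_alpha = guarded_ratio(bp[ch, "theta"], bp[ch, "alpha"]))
    names(vals) <- paste0(chn[ch], "_",
                          c(CANONICAL_BANDS$name, "activity", "mobility",
                            "complexity", "beta_alpha", "theta_alpha"))
    per_ch <- c(per_ch, vals)
  }
  agg <- c(colMeans(bp), apply(bp, 2, sd_pop))
  names(agg) <- c(paste0("bandmean_", CANONICAL_BANDS$name),
                  paste0("bandsd_", CANONICAL_BANDS$name))
  out <- as.data.frame(as.list(c(per_ch, agg)), check.names = FALSE)
  out$subject_id <- window$subject_id
  out$session_id <- window$session_id
  out$label <- window$label
  out$window_index <- as.integer(window_index)
  out$start_time_s <- window$start_time_s
  out
}

#' DESC table for a dataset
#'
#' Segments each record with the descriptive 2.0 s / 1.0 s stream (no
#' z-scoring) and stacks the per-window DESC rows.
#'
#' @param records List of preprocessed [session_record()]s.
#' @param win_s,hop_s Descriptive windowing (defaults 2.0 / 1.0).
#' @return data.frame, one row per window, 65 columns.
#' @export
desc_table <- function(records, win_s = 2.0, hop_s = 1.0) {
  rows <- list()
  for (r in records) {
    wins <- segment_session(r, win_s, hop_s)
    for (i in seq_along(wins))
      rows[[length(rows) + 1L]] <- desc_features(wins[[i]], i - 1L, r$fs)
  }
  do.call(rbind, rows)
}

#' Number of numeric (non-metadata) DESC columns
#' @export
DESC_NUMERIC_DIM <- 60L

#' DWT descriptor for one window (175 values)
#'
#' 4-level db4 DWT per channel; from each of the five sub-bands (A4, D4,
#' D3, D2, D1): min, max, median, mean, SD, variance and relative energy
#' (sub-band energy over the total across the five sub-bands), giving
#' 7 x 5 = 35 values per channel and 175 across the montage. Channel-major
#' ordering.
#'
#' @param window A z-scored `eeg_window` (length divisible by 16).
#' @return Named numeric vector of length 175.
#' @export
dwt_features <- function(window) {
  X <- window$data
  chn <- colnames(X)
  out <- numeric(0)
  for (ch in seq_along(chn)) {
    x <- X[, ch]
    zero <- all(x == 0)
    cf <- dwt_db4(x, level = 4L)
    energies <- vapply(cf, function(c) sum(c^2), 0)
    etot <- sum(energies)
    for (sb in seq_along(cf)) {
      c <- cf[[sb]]
      if (zero) {
        stats <- c(0, 0, 0, 0, 0, 0, 0)
      } else {
        stats <- c(min(c), max(c), stats::median(c), mean(c), sd_pop(c),
                   sd_pop(c)^2, if (etot > 0) energies[sb] / etot else 0)
      }
      names(stats) <- paste0(chn[ch], "_", names(cf)[sb], "_",
                             c("min", "max", "median", "mean", "std",
                               "var", "relenergy"))
      out <- c(out, stats)
    }
  }
  out
}

#' FEATS descriptor for one window (167 values)
#'
#' Per channel (33 values): 11 extended band powers, 11 relative powers
#' (each power over the sum of all 11, so they sum to 1), theta/beta and
#' (theta+alpha)/beta ratios, spectral entropy, Hjorth activity/mobility/
#' complexity, and differential entropies of the delta/theta/alpha/beta/
#' gamma extended bands; plus two frontal asymmetry indices,
#' `log alpha(AF4) - log alpha(AF3)` and the same for beta (eps-guarded
#' logs). Channel-major ordering, asymmetries last.
#'
#' @param window A z-scored `eeg_window`.
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector of length 167.
#' @export
feats_vector <- function(window, fs = 128) {
  X <- window$data
  chn <- colnames(X)
  if (!all(c("AF3", "AF4") %in% chn))
    eeg_stop("config", "FEATS requires AF3 and AF4 channels")
  nb <- nrow(FEATS_BANDS)
  out <- numeric(0)
  alpha_p <- beta_p <- stats::setNames(numeric(length(chn)), chn)
  for (ch in seq_along(chn)) {
    x <- X[, ch]
    ps <- welch_psd(x, fs)
    powers <- vapply(seq_len(nb), function(b)
      band_power(ps$freqs, ps$psd, FEATS_BANDS$lo[b],
                 min(FEATS_BANDS$hi[b], fs / 2)), 0)
    names(powers) <- paste0(chn[ch], "_pow_", FEATS_BANDS$name)
    tot <- sum(powers)
    rel <- if (tot > 0) powers / tot else powers * 0
    names(rel) <- paste0(chn[ch], "_rel_", FEATS_BANDS$name)
    th <- powers[paste0(chn[ch], "_pow_theta")]
    al <- powers[paste0(chn[ch], "_pow_alpha")]
    be <- powers[paste0(chn[ch], "_pow_beta")]
    ratios <- c(guarded_ratio(th, be), guarded_ratio(th + al, be))
    names(ratios) <- paste0(chn[ch], "_", c("theta_beta", "thetaalpha_beta"))
    se <- stats::setNames(spectral_entropy(ps$psd),
                          paste0(chn[ch], "_spec_entropy"))
    hj <- hjorth_params(x)
    names(hj) <- paste0(chn[ch], "_", c("activity", "mobility", "complexity"))
    de <- differential_entropy_band(
      powers[paste0(chn[ch], "_pow_",
                    c("delta", "theta", "alpha", "beta", "gamma"))])
    names(de) <- paste0(chn[ch], "_de_",
                        c("delta", "theta", "alpha", "beta", "gamma"))
    alpha_p[chn[ch]] <- al
    beta_p[chn[ch]] <- be
    out <- c(out, powers, rel, ratios, se, hj, de)
  }
  eps <- 1e-12
  asym <- c(frontal_asym_alpha = log(max(alpha_p["AF4"], eps)) -
              log(max(alpha_p["AF3"], eps)),
            frontal_asym_beta = log(max(beta_p["AF4"], eps)) -
              log(max(beta_p["AF3"], eps)))
  c(out, asym)
}

#' Cliff's delta effect size
#'
#' `(#\{a > b\} - #\{a < b\}) / (n_a * n_b)` over all cross-group pairs,
#' computed via mid-ranks (equivalent to the pair count, ties contributing
#' zero).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return Value in `[-1, 1]`.
#' @export
cliffs_delta <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na == 0L || nb == 0L) eeg_stop("data", "both samples must be non-empty")
  r <- rank(c(sample_a, sample_b))
  # rank-sum identity: sum of a-ranks = #{a>b} + 0.5*#{a==b} + na(na+1)/2
  wins <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  (2 * wins - na * nb) / (na * nb)
}

#' Quartile summary of cross-channel mean band power by class
#'
#' One row per band: Q1/median/Q3/IQR per class plus the difference in
#' medians (TRUTH - LIE).
#'
#' @param desc DESC table from [desc_table()].
#' @return data.frame with one row per canonical band.
#' @export
band_power_summary <- function(desc) {
  if (nrow(desc) == 0L) eeg_stop("data", "empty DESC table")
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- lapply(CANONICAL_BANDS$name, function(b) {
    v <- desc[[paste0("bandmean_", b)]]
    qt <- qs(v[desc$label == 1L]); ql <- qs(v[desc$label == 0L])
    data.frame(band = b,
               q1_truth = qt[1], q1_lie = ql[1],
               median_truth = qt[2], median_lie = ql[2],
               q3_truth = qt[3], q3_lie = ql[3],
               iqr_truth = qt[3] - qt[1], iqr_lie = ql[3] - ql[1],
               delta_median = qt[2] - ql[2])
  })
  do.call(rbind, rows)
}

#' Cliff's delta of cross-channel mean band power per band (TRUTH - LIE)
#'
#' @param desc DESC table from [desc_table()].
#' @return data.frame with columns `band` and `cliffs_delta`.
#' @export
band_effect_sizes <- function(desc) {
  rows <- lapply(CANONICAL_BANDS$name, function(b) {
    v <- desc[[paste0("bandmean_", b)]]
    data.frame(band = b,
               cliffs_delta = cliffs_delta(v[desc$label == 1L],
                                           v[desc$label == 0L]))
  })
  do.call(rbind, rows)
}
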