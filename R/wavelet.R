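#' Daubechies-4 wavelet machinery
#'
#' Periodized orthonormal DWT and full wavelet-packet decomposition with the
#' db4 mother wavelet, used by the DWT feature extractor and by the
#' wavelet-packet soft-threshold artifact-reduction step. The transform is
#' implemented as an exactly orthogonal map (analysis rows are even circular
#' shifts of the decomposition filters), so synthesis is the transpose and
#' reconstruction is exact to machine precision whenever every intermediate
#' length is even and at least `2 * (filter length - 1)` samples long; the
#' decomposition depth is capped accordingly.
#'
#' @name wavelet
NULL

# db4 scaling (reconstruction low-pass) filter, orthonormal, sum = sqrt(2).
# Computed by spectral factorization of the degree-3 Daubechies polynomial.
DB4_REC_LO <- c(0.23037781330885523, 0.71484657055254153,
                0.63088076792959036, -0.02798376941698385,
                -0.18703481171888114, 0.03084138183598697,
                0.03288301166698295, -0.01059740178499728)

db4_filters <- function() {
  rec_lo <- DB4_REC_LO
  L <- length(rec_lo)
  dec_lo <- rev(rec_lo)
  # quadrature mirror: g[n] = (-1)^n h[L-1-n] with h the analysis low-pass
  dec_hi <- (-1)^(seq_len(L) - 1) * rec_lo
  rec_hi <- rev(dec_hi)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi)
}

wavelet_filters <- function(wavelet) {
  if (!identical(tolower(wavelet), "db4"))
    eeg_stop("config", "unknown wavelet '%s' (only db4 is provided)", wavelet)
  db4_filters()
}

# One analysis step: circular convolution with the decomposition filters,
# downsampled by 2. Returns approximation and detail, each length N/2.
wt_split <- function(x, flt) {
  N <- length(x)
  L <- length(flt$dec_lo)
  starts <- seq(1L, N, by = 2L)
  idx <- (outer(starts - 1L, 0:(L - 1L), "+")) %% N + 1L
  M <- matrix(x[idx], nrow = length(starts))
  list(a = drop(M %*% flt$dec_lo), d = drop(M %*% flt$dec_hi))
}

# One synthesis step: the transpose of wt_split (exact inverse when the
# analysis rows are orthonormal, i.e. length(a) + length(d) >= 2*(L-1)).
wt_merge <- function(a, d, flt) {
  N <- 2L * length(a)
  L <- length(flt$dec_lo)
  starts <- seq(1L, N, by = 2L)
  idx <- (outer(starts - 1L, 0:(L - 1L), "+")) %% N + 1L
  contrib <- outer(a, flt$dec_lo) + outer(d, flt$dec_hi)
  x <- numeric(N)
  for (j in seq_len(L)) {
    tgt <- idx[, j]
    x[tgt] <- x[tgt] + contrib[, j]
  }
  x
}

#' Multi-level periodized db4 DWT
#'
#' @param x Numeric signal whose length is divisible by `2^level`.
#' @param level Decomposition depth.
#' @param wavelet Mother wavelet name (only `"db4"`).
#' @return Named list of coefficient vectors, deepest approximation first:
#'   e.g. `A4, D4, D3, D2, D1` for `level = 4`.
#' @export
dwt_db4 <- function(x, level = 4L, wavelet = "db4") {
  flt <- wavelet_filters(wavelet)
  Lf <- length(flt$dec_lo)
  N <- length(x)
  if (N %% 2^level != 0L || N / 2^level < 1L)
    eeg_stop("data", "signal length %d not divisible by 2^%d", N, level)
  # exact-orthogonality condition at every split
  if (N / 2^(level - 1L) < 2L * (Lf - 1L))
    eeg_stop("data",
             "signal length %d too short for a %d-level db4 transform", N, level)
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- wt_split(a, flt)
    a <- s$a
    details[[l]] <- s$d
  }
  out <- c(list(a), rev(details))
  names(out) <- c(paste0("A", level), paste0("D", seq(level, 1L)))
  out
}

#' Inverse of [dwt_db4()]
#' @param coeffs List as returned by [dwt_db4()].
#' @inheritParams dwt_db4
#' @return Reconstructed signal.
#' @export
idwt_db4 <- function(coeffs, wavelet = "db4") {
  flt <- wavelet_filters(wavelet)
  a <- coeffs[[1]]
  for (k in seq(2L, length(coeffs))) a <- wt_merge(a, coeffs[[k]], flt)
  a
}

# Deepest wavelet-packet level at which the periodized transform remains
# exactly orthogonal: every split must see >= 2*(L-1) samples.
wp_max_level <- function(n, filter_len = 8L) {
  max(1L, floor(log2(n / (2 * (filter_len - 1)))))
}

# Full wavelet-packet decomposition to `level`; returns list of terminal
# node coefficient vectors (natural / tree order, which is irrelevant for
# per-packet thresholding).
wp_decompose <- function(x, level, flt) {
  nodes <- list(x)
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      s <- wt_split(nodes[[i]], flt)
      nxt[[2L * i - 1L]] <- s$a
      nxt[[2L * i]] <- s$d
    }
    nodes <- nxt
  }
  nodes
}

wp_reconstruct <- function(nodes, flt) {
  while (length(nodes) > 1L) {
    nxt <- vector("list", length(nodes) / 2L)
    for (i in seq_along(nxt))
      nxt[[i]] <- wt_merge(nodes[[2L * i - 1L]], nodes[[2L * i]], flt)
    nodes <- nxt
  }
  nodes[[1]]
}

#' ATAR specification
#'
#' Wavelet-packet soft-threshold artifact reduction: each channel is
#' decomposed to the deepest permitted packet level, every terminal packet is
#' soft-thresholded at `rel_threshold` times its own maximum absolute
#' coefficient, and the signal is reconstructed.
#'
#' @param wavelet Mother wavelet (only `"db4"`).
#' @param rel_threshold Fraction of the per-packet max |coefficient| in
#'   `[0, 1]` used as the soft threshold.
#' @export
atar_spec <- function(wavelet = "db4", rel_threshold = 0.1) {
  if (rel_threshold < 0 || rel_threshold > 1)
    eeg_stop("config", "rel_threshold must lie in [0, 1]")
  wavelet_filters(wavelet)  # validates the name
  structure(list(wavelet = wavelet, rel_threshold = rel_threshold),
            class = "atar_spec")
}

#' Wavelet-packet soft-threshold artifact reduction (one channel)
#'
#' @param x Numeric signal (one EEG channel).
#' @param spec An [atar_spec()].
#' @return Denoised signal of the same length as `x`.
#' @export
atar_denoise <- function(x, spec = atar_spec()) {
  flt <- wavelet_filters(spec$wavelet)
  Lf <- length(flt$dec_lo)
  n <- length(x)
  if (n < Lf) eeg_stop("data", "signal shorter than one wavelet support")
  level <- wp_max_level(n, Lf)
  block <- 2^level
  n_pad <- ceiling(n / block) * block
  xp <- if (n_pad > n) {
    # symmetric reflection of the tail to reach a block multiple
    pad <- n_pad - n
    c(x, x[seq(n, by = -1L, length.out = pad)])
  } else x
  nodes <- wp_decompose(xp, level, flt)
  thr_frac <- spec$rel_threshold
  nodes <- lapply(nodes, function(cf) {
    thr <- thr_frac * max(abs(cf))
    sign(cf) * pmax(abs(cf) - thr, 0)
  })
  y <- wp_reconstruct(nodes, flt)
  y[seq_len(n)]
}
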