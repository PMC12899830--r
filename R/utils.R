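# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Classed error helper
#'
#' All package errors carry a subclass so callers (and the CLI) can map them
#' to exit codes: `eegdecept_config_error`, `eegdecept_format_error`,
#' `eegdecept_io_error`, `eegdecept_data_error`.
#' @noRd
eeg_stop <- function(subclass, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c(paste0("eegdecept_", subclass, "_error"), "eegdecept_error",
              "error", "condition")
  ))
}

#' Derive a child RNG seed from a parent seed and integer tags
#'
#' Splitting is hierarchical (dataset -> subject -> session) so that adding
#' subjects to a configuration does not perturb the draws of earlier
#' subjects. Simple integer mixing keeps the result in [0, 2^31 - 2].
#' @noRd
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (t in tags) {
    # 48271 is a classic Lehmer multiplier; exact in double precision here
    h <- (h * 48271 + as.double(t) * 9973 + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Population standard deviation (no Bessel correction)
#' @noRd
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
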