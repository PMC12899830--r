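#' Session records and per-session CSV input/output
#'
#' A session is one ~75 s five-channel recording with a single LIE/TRUTH
#' label; it is the operational decision unit of the whole pipeline.
#'
#' @name dataset_io
NULL

#' Canonical wearable montage
#' @export
EEG_CHANNELS <- c("AF3", "T7", "Pz", "T8", "AF4")

#' Construct a session record
#'
#' @param subject_id,session_id Identifier strings.
#' @param label Integer class label: 0 = LIE, 1 = TRUTH.
#' @param fs Sampling rate, Hz.
#' @param samples Numeric matrix, time x channels, in microvolts.
#' @param channel_names Ordered channel names (defaults to the canonical
#'   AF3, T7, Pz, T8, AF4 montage).
#' @param preprocessed Logical flag set by [preprocess_session()].
#' @return Object of class `session_record`.
#' @export
session_record <- function(subject_id, session_id, label, fs, samples,
                           channel_names = EEG_CHANNELS,
                           preprocessed = FALSE) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples))
    eeg_stop("format", "sample matrix must be numeric with no missing values")
  if (ncol(samples) != length(channel_names))
    eeg_stop("format", "sample matrix has %d columns for %d channels",
             ncol(samples), length(channel_names))
  if (!(fs > 0)) eeg_stop("config", "fs must be positive")
  if (!label %in% c(0L, 1L)) eeg_stop("format", "label must be 0 (LIE) or 1 (TRUTH)")
  colnames(samples) <- channel_names
  structure(list(subject_id = as.character(subject_id),
                 session_id = as.character(session_id),
                 label = as.integer(label), fs = fs,
                 channel_names = channel_names, samples = samples,
                 preprocessed = isTRUE(preprocessed)),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session %s | subject %s | %s | %d x %d @ %g Hz%s>\n",
              x$session_id, x$subject_id,
              if (x$label == 1L) "TRUTH" else "LIE",
              nrow(x$samples), ncol(x$samples), x$fs,
              if (x$preprocessed) " | preprocessed" else ""))
  invisible(x)
}

#' Write one session to CSV
#'
#' Header row of channel names, one row per sample, '.' decimal point,
#' comma separator, values in microvolts with 6 significant digits.
#'
#' @param record A [session_record()].
#' @param destination File path.
#' @export
write_session_csv <- function(record, destination) {
  stopifnot(inherits(record, "session_record"))
  dir <- dirname(destination)
  if (!dir.exists(dir))
    eeg_stop("io", "destination directory does not exist: %s", dir)
  m <- record$samples
  txt <- apply(m, 2, function(col) formatC(col, format = "g", digits = 6))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(m))
  lines <- c(paste(record$channel_names, collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  ok <- tryCatch({ writeLines(lines, destination); TRUE },
                 error = function(e) FALSE)
  if (!ok) eeg_stop("io", "cannot write %s", destination)
  invisible(destination)
}

#' Read one session from CSV
#'
#' The reader canonicalises channel order to AF3, T7, Pz, T8, AF4 regardless
#' of the column layout of the file; `column_map` names the five channel
#' columns either by header name or by 1-based position.
#'
#' @param source File path.
#' @param column_map Named list/vector mapping canonical channel names to
#'   source columns (header names or integer positions). Default: identity
#'   mapping by header name.
#' @param fs Sampling rate, Hz.
#' @param label Session label, 0/1.
#' @param subject_id,session_id Identifiers.
#' @param sep Field separator (default comma).
#' @return A [session_record()].
#' @export
read_session_csv <- function(source, column_map = NULL, fs = 128,
                             label, subject_id, session_id, sep = ",") {
  if (!file.exists(source)) eeg_stop("io", "no such file: %s", source)
  df <- tryCatch(
    utils::read.table(source, header = TRUE, sep = sep, dec = ".",
                      check.names = FALSE, colClasses = NA),
    error = function(e) eeg_stop("format", "cannot parse %s: %s",
                                 source, conditionMessage(e)))
  if (nrow(df) == 0L) eeg_stop("format", "%s contains a header but no samples", source)
  if (is.null(column_map)) column_map <- stats::setNames(as.list(EEG_CHANNELS), EEG_CHANNELS)
  cols <- lapply(EEG_CHANNELS, function(ch) {
    key <- column_map[[ch]]
    if (is.null(key))
      eeg_stop("format", "column_map is missing channel %s", ch)
    col <- if (is.numeric(key)) {
      if (key < 1 || key > ncol(df))
        eeg_stop("format", "column index %d out of range for %s", key, ch)
      df[[key]]
    } else {
      if (!key %in% names(df))
        eeg_stop("format", "missing channel column '%s' in %s", key, source)
      df[[key]]
    }
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v))
      eeg_stop("format", "non-numeric value for channel %s at row %d of %s",
               ch, which(is.na(v))[1], source)
    v
  })
  session_record(subject_id, session_id, label, fs,
                 do.call(cbind, cols), EEG_CHANNELS)
}

#' Write a dataset manifest
#' @param manifest data.frame with columns subject_id, session_id, label, file.
#' @param destination File path.
#' @export
write_manifest_csv <- function(manifest, destination) {
  utils::write.csv(manifest, destination, row.names = FALSE, quote = FALSE)
  invisible(destination)
}

#' Read a dataset manifest
#' @param source File path.
#' @export
read_manifest_csv <- function(source) {
  if (!file.exists(source)) eeg_stop("io", "no such file: %s", source)
  utils::read.csv(source, stringsAsFactors = FALSE)
}

#' Dataset bookkeeping diagnostics
#'
#' @param records List of [session_record()]s.
#' @return A list with subject/session counts, per-class label counts and a
#'   per-session duration table.
#' @export
dataset_diagnostics <- function(records) {
  if (length(records) == 0L)
    return(list(n_subjects = 0L, n_sessions = 0L, n_lie = 0L, n_truth = 0L,
                sessions = data.frame(subject_id = character(),
                                      session_id = character(),
                                      label = integer(),
                                      duration_s = numeric())))
  tab <- data.frame(
    subject_id = vapply(records, function(r) r$subject_id, ""),
    session_id = vapply(records, function(r) r$session_id, ""),
    label = vapply(records, function(r) r$label, 0L),
    duration_s = vapply(records, function(r) nrow(r$samples) / r$fs, 0)
  )
  list(n_subjects = length(unique(tab$subject_id)),
       n_sessions = nrow(tab),
       n_lie = sum(tab$label == 0L),
       n_truth = sum(tab$label == 1L),
       sessions = tab)
}
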