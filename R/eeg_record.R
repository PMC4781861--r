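#' Multichannel EEG record
#'
#' Container for a sampled multichannel EEG segment. Data are stored
#' channel-major (one row per channel) in microvolts. Times are seconds from
#' record start, sample indices are 0-based, and all intervals are half-open
#' `[start, end)`.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (CHB-MIT style recordings use 256).
#' @param channel_labels character vector, one label per channel.
#' @param annotations list of [seizure_annotation()] objects.
#' @param patient_id,record_id identifier strings.
#' @param start_time offset of the first sample in seconds (0 at record start).
#'
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_labels = NULL, annotations = list(),
                       patient_id = "unknown", record_id = "record",
                       start_time = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("eeg_record: need one channel label per data row", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("eeg_record: fs must be a single positive number", call. = FALSE)
  }
  dur <- ncol(data) / fs
  for (a in annotations) {
    stopifnot(inherits(a, "seizure_annotation"))
    if (a$onset_s < 0 || a$end_s > dur) {
      stop("eeg_record: annotation outside [0, duration)", call. = FALSE)
    }
  }
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         annotations = annotations, patient_id = patient_id,
         record_id = record_id, start_time = start_time),
    class = "eeg_record"
  )
}

#' Seizure annotation
#'
#' Ground-truth seizure interval, seconds from record start, half-open
#' `[onset_s, end_s)`.
#'
#' @param onset_s seizure onset in seconds.
#' @param end_s seizure end in seconds; must exceed `onset_s`.
#' @return An object of class `seizure_annotation`.
#' @export
seizure_annotation <- function(onset_s, end_s) {
  if (!(is.numeric(onset_s) && is.numeric(end_s)) ||
      onset_s < 0 || end_s <= onset_s) {
    stop("seizure_annotation: need 0 <= onset_s < end_s", call. = FALSE)
  }
  structure(list(onset_s = as.numeric(onset_s), end_s = as.numeric(end_s)),
            class = "seizure_annotation")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s/%s: %d channel(s) x %d samples @ %g Hz (%.1f s), %d seizure annotation(s)\n",
              x$patient_id, x$record_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, length(x$annotations)))
  invisible(x)
}

#' Record duration in seconds
#' @param record an [eeg_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(record) ncol(record$data) / record$fs

#' Total annotated ictal time of a record, in seconds
#' @param record an [eeg_record()].
#' @return summed seizure duration in seconds.
#' @export
ictal_seconds <- function(record) {
  if (length(record$annotations) == 0L) return(0)
  sum(vapply(record$annotations, function(a) a$end_s - a$onset_s, numeric(1)))
}

#' Subset an EEG record to selected channels
#' @param record an [eeg_record()].
#' @param labels channel labels to keep, in the requested order.
#' @return an [eeg_record()] with the selected channels.
#' @export
subset_channels <- function(record, labels) {
  idx <- match(labels, record$channel_labels)
  if (anyNA(idx)) {
    stop("subset_channels: unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  record$data <- record$data[idx, , drop = FALSE]
  record$channel_labels <- record$channel_labels[idx]
  record
}
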