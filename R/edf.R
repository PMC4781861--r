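# EDF (European Data Format) reader/writer.
#
# EDF stores a fixed 256-byte ASCII header, one 256-byte ASCII block per
# signal, then data records of 16-bit little-endian integers. Samples are
# mapped to physical units linearly between (digital min, digital max) and
# (physical min, physical max).

EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

# Default physical range: +/- 3276.8 uV, so one 16-bit step is exactly 0.1 uV.
EDF_PHYS_MIN_DEFAULT <- -3276.8
EDF_PHYS_MAX_DEFAULT <- 3276.7

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Read an EDF file
#'
#' Reads a European Data Format file into an [eeg_record()]. All signals must
#' share one sampling rate; data are returned channel-major with no
#' resampling. Seizure annotations are not stored in plain EDF; attach them
#' from a summary file with [parse_summary()].
#'
#' @param path path to an EDF file.
#' @param patient_id optional patient identifier; defaults to the EDF local
#'   patient field (trimmed).
#' @return an [eeg_record()].
#' @seealso [write_edf()], [parse_summary()]
#' @export
read_edf <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("read_edf: no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("read_edf: truncated EDF header", call. = FALSE)
  field <- function(raw, from, len) {
    trimws(rawToChar(raw[from:(from + len - 1L)]))
  }
  patient_field <- field(hdr, 9L, 80L)
  n_records <- suppressWarnings(as.integer(field(hdr, 237L, 8L)))
  rec_dur <- suppressWarnings(as.numeric(field(hdr, 245L, 8L)))
  ns <- suppressWarnings(as.integer(field(hdr, 253L, 4L)))
  if (is.na(ns) || ns <= 0L || is.na(n_records) || is.na(rec_dur) ||
      rec_dur <= 0) {
    stop("read_edf: corrupt EDF header (record/signal counts)", call. = FALSE)
  }

  sig_hdr <- readBin(con, "raw", 256L * ns)
  if (length(sig_hdr) < 256L * ns) {
    stop("read_edf: truncated EDF signal header", call. = FALSE)
  }
  sfield <- function(from, len) {
    vapply(seq_len(ns) - 1L, function(k) {
      off <- from + k * len
      trimws(rawToChar(sig_hdr[off:(off + len - 1L)]))
    }, character(1))
  }
  # signal header layout: 16 label, 80 transducer, 8 dim, 8 phys min,
  # 8 phys max, 8 dig min, 8 dig max, 80 prefilter, ns*8 samples-per-record
  labels <- sfield(1L, 16L)
  phys_min <- as.numeric(sfield(ns * 104L + 1L, 8L))
  phys_max <- as.numeric(sfield(ns * 112L + 1L, 8L))
  dig_min <- as.numeric(sfield(ns * 120L + 1L, 8L))
  dig_max <- as.numeric(sfield(ns * 128L + 1L, 8L))
  spr <- as.integer(sfield(ns * 216L + 1L, 8L))
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    stop("read_edf: corrupt EDF signal header fields", call. = FALSE)
  }
  if (length(unique(spr)) != 1L) {
    stop("read_edf: signals with differing sampling rates are not supported",
         call. = FALSE)
  }
  fs <- spr[1L] / rec_dur

  n_vals <- n_records * sum(spr)
  vals <- readBin(con, "integer", n = n_vals, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(vals) < n_vals) {
    stop("read_edf: truncated EDF data section", call. = FALSE)
  }
  # records are blocks of (spr samples for signal 1, spr for signal 2, ...)
  dim(vals) <- c(spr[1L], ns, n_records)
  data <- matrix(0, nrow = ns, ncol = spr[1L] * n_records)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns)) {
    data[s, ] <- phys_min[s] + (as.vector(vals[, s, ]) - dig_min[s]) * scale[s]
  }
  eeg_record(data, fs = fs, channel_labels = labels,
             patient_id = if (is.null(patient_id)) patient_field else patient_id,
             record_id = sub("\\.edf$", "", basename(path), ignore.case = TRUE))
}

#' Write an EDF file
#'
#' Writes an [eeg_record()] as 16-bit EDF with a default physical range of
#' +/- 3276.8 uV, i.e. a quantization step of 0.1 uV. Data records are one
#' second long; a final partial second is zero-padded (documented rule), so
#' re-read records may be longer by up to `fs - 1` samples unless the
#' duration is a whole number of seconds.
#'
#' @param record an [eeg_record()]; `fs` must be a positive integer.
#' @param path output path.
#' @param phys_min,phys_max physical range in microvolts mapped onto the
#'   16-bit digital range; samples outside are clipped.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path,
                      phys_min = EDF_PHYS_MIN_DEFAULT,
                      phys_max = EDF_PHYS_MAX_DEFAULT) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (fs != round(fs)) {
    stop("write_edf: non-integer sampling rates are not supported",
         call. = FALSE)
  }
  ns <- nrow(record$data)
  n_samp <- ncol(record$data)
  n_records <- ceiling(n_samp / fs)
  if (n_records < 1L) stop("write_edf: empty record", call. = FALSE)

  data <- record$data
  pad <- n_records * fs - n_samp
  if (pad > 0L) data <- cbind(data, matrix(0, nrow = ns, ncol = pad))

  step <- (phys_max - phys_min) / (EDF_DIG_MAX - EDF_DIG_MIN)
  dig <- round((data - phys_min) / step) + EDF_DIG_MIN
  dig[dig < EDF_DIG_MIN] <- EDF_DIG_MIN
  dig[dig > EDF_DIG_MAX] <- EDF_DIG_MAX
  storage.mode(dig) <- "integer"

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("write_edf: cannot open ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_ascii(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8L)                               # version
  wr(record$patient_id, 80L)                # local patient id
  wr(record$record_id, 80L)                 # local recording id
  wr("01.01.00", 8L); wr("00.00.00", 8L)    # start date / time
  wr(256L + 256L * ns, 8L)                  # header bytes
  wr("", 44L)                               # reserved
  wr(n_records, 8L)
  wr("1", 8L)                               # record duration, seconds
  wr(ns, 4L)
  for (lab in record$channel_labels) wr(lab, 16L)
  for (k in seq_len(ns)) wr("", 80L)        # transducer
  for (k in seq_len(ns)) wr("uV", 8L)
  for (k in seq_len(ns)) wr(format(phys_min, nsmall = 1), 8L)
  for (k in seq_len(ns)) wr(format(phys_max, nsmall = 1), 8L)
  for (k in seq_len(ns)) wr(EDF_DIG_MIN, 8L)
  for (k in seq_len(ns)) wr(EDF_DIG_MAX, 8L)
  for (k in seq_len(ns)) wr("", 80L)        # prefiltering
  for (k in seq_len(ns)) wr(fs, 8L)         # samples per record
  for (k in seq_len(ns)) wr("", 32L)        # reserved

  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, cols, drop = FALSE])   # signal-major within the record
    writeBin(as.vector(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}
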