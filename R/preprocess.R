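# Band-pass filtering (equiripple FIR, zero-phase application), Hilbert
# analytic decomposition, and SD-based working/reference channel selection.

# Transition width for one band edge: 4 Hz where there is room, shrinking to
# 80 percent of the distance to DC/Nyquist for edges closer than 5 Hz. At
# 257 taps a 4 Hz transition leaves passband ripple around 1e-4, small
# enough that amplitude modulation is not converted into phase jitter by
# ripple asymmetry around the carrier.
edge_transition <- function(gap_hz) min(4, 0.8 * gap_hz)

#' Design an equiripple (Remez) band-pass FIR filter
#'
#' Linear-phase Parks-McClellan design via [signal::remez]. Transition bands
#' are 2 Hz wide, narrowed near DC/Nyquist so the stop edges stay feasible.
#' The single-pass response meets <= 1 dB passband ripple and >= 40 dB
#' stopband attenuation at the default `numtaps` for bands whose edges leave
#' at least 2 Hz of transition room; for the 1-12 Hz band the sub-hertz lower
#' edge limits the single-pass floor, and the >= 40 dB figure is met by the
#' squared-magnitude response that the zero-phase (forward-backward)
#' application in [bandpass_filter()] actually applies.
#'
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz.
#' @param numtaps odd filter length; default 257 (about 1 s at 256 Hz).
#' @return numeric vector of `numtaps` symmetric FIR coefficients.
#' @export
design_bandpass <- function(band, fs, numtaps = 257L) {
  stopifnot(inherits(band, "band_spec"))
  numtaps <- as.integer(numtaps)
  if (numtaps %% 2L == 0L) {
    stop("design_bandpass: numtaps must be odd", call. = FALSE)
  }
  nyq <- fs / 2
  if (band$high_hz >= nyq) {
    stop("design_bandpass: band edge at or above Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  tw_lo <- edge_transition(band$low_hz)
  tw_hi <- edge_transition(nyq - band$high_hz)
  # strongly unequal transition widths destabilize the exchange algorithm;
  # when one edge forces a narrow transition, cap the other near it
  if (tw_lo < 2 || tw_hi < 2) {
    tw_lo <- min(tw_lo, 2)
    tw_hi <- min(tw_hi, 2)
  }
  f <- c(0, band$low_hz - tw_lo, band$low_hz,
         band$high_hz, band$high_hz + tw_hi, nyq) / nyq
  h <- signal::remez(numtaps - 1L, f, c(0, 0, 1, 1, 0, 0))
  if (any(!is.finite(h)) || max(abs(h)) < 1e-8) {
    stop("design_bandpass: equiripple design failed to converge for band ",
         band$name, call. = FALSE)
  }
  h
}

#' Frequency response magnitude of an FIR filter
#'
#' @param h FIR coefficients.
#' @param freqs_hz frequencies at which to evaluate, Hz.
#' @param fs sampling rate in Hz.
#' @return magnitude of the response at `freqs_hz`.
#' @export
fir_response <- function(h, freqs_hz, fs) {
  k <- seq_along(h) - 1
  vapply(freqs_hz,
         function(f) Mod(sum(h * exp(-2i * pi * f / fs * k))),
         numeric(1))
}

# kernel FFT cache keyed by band name, numtaps, fs, fft length
.fir_cache <- new.env(parent = emptyenv())

# Zero-phase FIR filtering of one channel: forward-backward application,
# equivalent to linear convolution with the autocorrelation of h (response
# |H(w)|^2, exactly zero phase). Computed in the frequency domain: the
# squared-magnitude transfer corresponds to a circular kernel centered at
# lag 0, so no group delay arises and timing is preserved sample-for-sample.
# Zero-padding by the kernel half-length confines wrap-around to the edge
# guard that downstream windowing drops anyway.
zero_phase_fir <- function(x, h, cache_key = NULL) {
  n <- length(x)
  L <- length(h)
  m <- stats::nextn(n + 2L * L - 2L, c(2L, 3L, 5L))
  key <- if (is.null(cache_key)) NULL else paste(cache_key, L, m, sep = "|")
  G <- if (!is.null(key) && !is.null(.fir_cache[[key]])) {
    .fir_cache[[key]]
  } else {
    Gf <- Mod(stats::fft(c(h, numeric(m - L))))^2
    if (!is.null(key)) .fir_cache[[key]] <- Gf
    Gf
  }
  Y <- stats::fft(stats::fft(c(x, numeric(m - n))) * G, inverse = TRUE) / m
  Re(Y)[seq_len(n)]
}

#' Band-pass filter an EEG record (zero phase)
#'
#' Applies the equiripple band-pass of [design_bandpass()] to every channel
#' with zero-phase (forward-backward) application: output length equals input
#' length, and no group delay is introduced, so marker timing downstream is
#' not biased. The first and last `numtaps` samples carry edge effects;
#' windows touching them are dropped by [lock_pipeline()].
#'
#' @param record an [eeg_record()].
#' @param band a [band_spec()].
#' @param numtaps odd FIR length.
#' @return an [eeg_record()] with filtered data.
#' @export
bandpass_filter <- function(record, band, numtaps = 257L) {
  stopifnot(inherits(record, "eeg_record"))
  h <- design_bandpass(band, record$fs, numtaps)
  if (ncol(record$data) < 3L * length(h)) {
    stop("bandpass_filter: record shorter than 3 filter lengths",
         call. = FALSE)
  }
  key <- paste(band$name, record$fs, sep = "|")
  for (ch in seq_len(nrow(record$data))) {
    record$data[ch, ] <- zero_phase_fir(record$data[ch, ], h, cache_key = key)
  }
  record
}

#' Hilbert analytic decomposition of one channel
#'
#' Computes the analytic signal by the FFT method (positive frequencies
#' doubled, negative zeroed) and returns the analytic amplitude `aa`
#' (modulus) and analytic phase `ap` (four-quadrant angle, wrapped to
#' (-pi, pi\]). The `valid` range excludes `edge_guard` samples at each end,
#' where filter start-up and the circular FFT boundary distort the envelope.
#'
#' @param x single-channel numeric series, band-limited input expected;
#'   length >= 64.
#' @param edge_guard samples excluded at each edge; default 257 (one default
#'   filter length).
#' @return object of class `analytic_signal` with fields `aa`, `ap`,
#'   `valid` (integer c(first, last), 1-based).
#' @export
hilbert_decompose <- function(x, edge_guard = 257L) {
  n <- length(x)
  if (n < 64L) {
    stop("hilbert_decompose: need at least 64 samples", call. = FALSE)
  }
  if (all(x == 0)) {
    stop("hilbert_decompose: all-zero signal, phase undefined", call. = FALSE)
  }
  X <- stats::fft(x)
  mult <- numeric(n)
  if (n %% 2L == 0L) {
    mult[1L] <- 1; mult[n / 2L + 1L] <- 1
    mult[2L:(n / 2L)] <- 2
  } else {
    mult[1L] <- 1
    mult[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(X * mult, inverse = TRUE) / n
  lo <- min(edge_guard + 1L, n)
  hi <- max(n - edge_guard, 1L)
  structure(list(aa = Mod(z), ap = Arg(z),
                 valid = c(lo, hi)),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> %d samples, valid [%d, %d]\n",
              length(x$aa), x$valid[1], x$valid[2]))
  invisible(x)
}

#' Flag artifact-contaminated channels
#'
#' Simple amplitude rule: a channel is flagged when more than `frac` of its
#' samples exceed `limit_uv` in absolute value (electrode movement and
#' similar gross artifacts, not seizure activity).
#'
#' @param record an [eeg_record()].
#' @param limit_uv absolute amplitude limit, microvolts.
#' @param frac fraction of samples allowed above the limit.
#' @return character vector of flagged channel labels.
#' @export
flag_artifact_channels <- function(record, limit_uv = 500, frac = 0.01) {
  over <- rowMeans(abs(record$data) > limit_uv)
  record$channel_labels[over > frac]
}

#' Select working and reference channels by standard deviation
#'
#' The working electrode is the channel with the highest SD over the whole
#' record (localizing the strongest activity); the reference electrode is
#' the channel with the lowest SD. Blocklisted channels and (optionally)
#' automatically flagged artifact channels are excluded first. Ties are
#' broken toward the lowest channel index.
#'
#' @param record an [eeg_record()].
#' @param blocklist channel labels to discard before selection.
#' @param auto_artifact apply [flag_artifact_channels()] as well.
#' @return list with `working` and `reference` channel labels.
#' @export
select_channels <- function(record, blocklist = character(),
                            auto_artifact = TRUE) {
  drop <- blocklist
  if (auto_artifact) {
    drop <- union(drop, flag_artifact_channels(record))
  }
  keep <- !(record$channel_labels %in% drop)
  if (sum(keep) < 2L) {
    stop("select_channels: fewer than 2 usable channels after exclusions",
         call. = FALSE)
  }
  labels <- record$channel_labels[keep]
  sds <- apply(record$data[keep, , drop = FALSE], 1L, stats::sd)
  working <- labels[which.max(sds)]
  rest <- setdiff(seq_along(labels), which.max(sds))
  reference <- labels[rest[which.min(sds[rest])]]
  list(working = working, reference = reference)
}
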