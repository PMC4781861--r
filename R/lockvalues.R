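# Sliding-window phase and amplitude lock values.
#
# Both statistics share one construction: the modulus of the windowed mean
# of exp(i * d[t]) where d is the per-sample difference series (phases for
# PLV, analytic amplitudes for ALV). 1 means perfect locking (any constant
# difference), ~0 means independence.

# Windowed mean resultant lengths of exp(1i * d). Windowed sums are taken as
# differences of cumsum (R accumulates real cumsum in long double, so the
# result matches a naive per-window loop to ~1e-15 even on long series).
window_resultant <- function(d, window_n, stride) {
  n <- length(d)
  if (n < window_n) {
    stop("lock values: series shorter than window_n", call. = FALSE)
  }
  cre <- c(0, cumsum(cos(d)))
  cim <- c(0, cumsum(sin(d)))
  starts <- seq.int(1L, n - window_n + 1L, by = stride)
  re <- cre[starts + window_n] - cre[starts]
  im <- cim[starts + window_n] - cim[starts]
  vals <- sqrt(re * re + im * im) / window_n
  list(values = pmin(1, pmax(0, vals)), starts = starts)
}

lock_series <- function(kind, values, starts, window_n, stride, fs,
                        band = NULL) {
  structure(list(kind = kind, values = values,
                 t_centers_s = (starts - 1 + window_n / 2) / fs,
                 starts = starts, window_n = window_n, stride = stride,
                 fs = fs, band = band),
            class = "lock_series")
}

#' @export
print.lock_series <- function(x, ...) {
  cat(sprintf("<lock_series> %s: %d windows (n=%d, stride=%d)%s\n",
              x$kind, length(x$values), x$window_n, x$stride,
              if (is.null(x$band)) "" else paste0(", band ", x$band$name)))
  invisible(x)
}

#' Sliding-window phase lock value (PLV)
#'
#' For each window of `window_n` samples, the PLV is the modulus of the mean
#' unit phasor of the phase difference, `|mean(exp(i (ap1 - ap2)))|`. It is 1
#' for identical phases or any constant phase lag, and of order
#' `sqrt(pi)/2 / sqrt(n)` for independent phases. Phases may be wrapped: the
#' difference enters a complex exponential, so wrapping is harmless.
#'
#' @param ap1,ap2 phase series in radians, equal length >= `window_n`.
#' @param window_n window length in samples.
#' @param stride window stride in samples.
#' @param fs sampling rate (Hz) used only to time-stamp window centers.
#' @param band optional [band_spec()] recorded on the result.
#' @return a `lock_series` with values in \[0, 1\].
#' @export
compute_plv <- function(ap1, ap2, window_n, stride = max(1L, window_n %/% 4L),
                        fs = 256, band = NULL) {
  if (length(ap1) != length(ap2)) {
    stop("compute_plv: phase series must have equal length", call. = FALSE)
  }
  r <- window_resultant(ap1 - ap2, window_n, stride)
  lock_series("PLV", r$values, r$starts, window_n, stride, fs, band)
}

#' Sliding-window amplitude lock value (ALV)
#'
#' The PLV construction applied to analytic-amplitude differences:
#' `|mean(exp(i (a1 - a2)))|` per window. With `normalize = TRUE`
#' (recommended) each amplitude series is divided by its interictal SD first,
#' so that the difference lives on a radian-like scale regardless of the
#' microvolt scale of the patient; `normalize = FALSE` uses raw differences
#' (the literal form, whose microvolt-scale differences wrap mod 2 pi).
#'
#' @param aa1,aa2 nonnegative amplitude series, equal length >= `window_n`.
#' @param window_n,stride window geometry in samples.
#' @param normalize divide each series by its (interictal) SD.
#' @param sd1,sd2 normalization SDs; default the SD of each full series,
#'   which is interictal-dominated on realistic records.
#' @param fs sampling rate (Hz) for window-center time stamps.
#' @param band optional [band_spec()] recorded on the result.
#' @return a `lock_series` with values in \[0, 1\].
#' @export
compute_alv <- function(aa1, aa2, window_n, stride = max(1L, window_n %/% 4L),
                        normalize = TRUE, sd1 = NULL, sd2 = NULL,
                        fs = 256, band = NULL) {
  if (length(aa1) != length(aa2)) {
    stop("compute_alv: amplitude series must have equal length", call. = FALSE)
  }
  if (normalize) {
    if (is.null(sd1)) sd1 <- stats::sd(aa1)
    if (is.null(sd2)) sd2 <- stats::sd(aa2)
    if (!all(is.finite(c(sd1, sd2))) || sd1 <= 0 || sd2 <= 0) {
      stop("compute_alv: degenerate (zero-SD) amplitude series under normalization",
           call. = FALSE)
    }
    aa1 <- aa1 / sd1
    aa2 <- aa2 / sd2
  }
  r <- window_resultant(aa1 - aa2, window_n, stride)
  lock_series("ALV", r$values, r$starts, window_n, stride, fs, band)
}

#' Full lock-value pipeline for one record and band
#'
#' Selects working/reference channels by SD, band-pass filters them with
#' zero-phase equiripple FIR, Hilbert-decomposes each, and computes aligned
#' PLV and ALV series on a common window grid. Windows overlapping the
#' filter edge-effect region (one `numtaps` length at each end) are dropped,
#' not padded.
#'
#' @param record an [eeg_record()].
#' @param band a [band_spec()].
#' @param config a [run_config()].
#' @param channels optional list(working=, reference=) to bypass selection
#'   (e.g. to reuse a calibration-time selection).
#' @return list with `plv`, `alv` (aligned `lock_series`), `channels`, and
#'   `s_aa`, `s_ap` (working-channel analytic amplitude/phase SDs over the
#'   valid region, used for patient scaling and artifact acceptance).
#' @export
lock_pipeline <- function(record, band, config = run_config(),
                          channels = NULL) {
  if (ncol(record$data) < config$window_n) {
    stop("lock_pipeline: record shorter than one window", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- select_channels(record,
                                blocklist = config$artifact_channel_blocklist,
                                auto_artifact = config$auto_artifact)
  }
  sub <- subset_channels(record, c(channels$working, channels$reference))
  sub <- bandpass_filter(sub, band, numtaps = config$numtaps)
  aw <- hilbert_decompose(sub$data[1L, ], edge_guard = config$numtaps)
  ar <- hilbert_decompose(sub$data[2L, ], edge_guard = config$numtaps)

  plv <- compute_plv(aw$ap, ar$ap, config$window_n, config$stride,
                     fs = record$fs, band = band)
  v <- aw$valid
  alv <- compute_alv(aw$aa, ar$aa, config$window_n, config$stride,
                     normalize = config$alv_normalize,
                     sd1 = stats::sd(aw$aa[v[1]:v[2]]),
                     sd2 = stats::sd(ar$aa[v[1]:v[2]]),
                     fs = record$fs, band = band)

  # drop windows touching the edge-effect guard band
  keep <- plv$starts > config$numtaps &
    (plv$starts + config$window_n - 1L) <= (ncol(record$data) - config$numtaps)
  for (nm in c("values", "t_centers_s", "starts")) {
    plv[[nm]] <- plv[[nm]][keep]
    alv[[nm]] <- alv[[nm]][keep]
  }
  list(plv = plv, alv = alv, channels = channels,
       s_aa = stats::sd(aw$aa[v[1]:v[2]]),
       s_ap = stats::sd(aw$ap[v[1]:v[2]]))
}

#' Write a lock series as CSV
#' @param series a `lock_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lock_series <- function(series, path) {
  utils::write.csv(data.frame(t_center_s = series$t_centers_s,
                              value = series$values),
                   path, row.names = FALSE)
  invisible(path)
}
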