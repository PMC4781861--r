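# Patient-specific threshold calibration: lock-value histograms, the
# valley ("elbow") rule, the 95th-percentile rule, and SD-based
# cross-patient scaling with artifact-acceptance inequalities.

#' Histogram of lock values over [0, 1]
#'
#' Fixed-width bins partitioning \[0, 1\]; a value of exactly 1 falls in the
#' last bin (closed right edge).
#'
#' @param series a `lock_series` or a numeric vector of lock values.
#' @param bin_width bin width, `0 < bin_width <= 0.1`; default 0.01, matching
#'   the granularity at which thresholds are usually quoted.
#' @return object of class `sync_histogram` with `bin_edges` (length
#'   `nbins + 1`) and integer `counts`.
#' @export
build_histogram <- function(series, bin_width = 0.01) {
  v <- if (inherits(series, "lock_series")) series$values else as.numeric(series)
  if (length(v) == 0L) {
    stop("build_histogram: empty lock-value series", call. = FALSE)
  }
  if (!(bin_width > 0 && bin_width <= 0.1)) {
    stop("build_histogram: need 0 < bin_width <= 0.1", call. = FALSE)
  }
  nb <- as.integer(round(1 / bin_width))
  idx <- pmin(nb, floor(v / bin_width) + 1L)
  structure(list(bin_edges = seq(0, 1, length.out = nb + 1L),
                 counts = tabulate(idx, nbins = nb)),
            class = "sync_histogram")
}

#' @export
print.sync_histogram <- function(x, ...) {
  cat(sprintf("<sync_histogram> %d bins, %d values\n",
              length(x$counts), sum(x$counts)))
  invisible(x)
}

# local maxima of a series after collapsing plateaus; returns indices
local_maxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L] && s[i] >= s[i + 1L]) {
      # extend over a plateau
      j <- i
      while (j < n && s[j + 1L] == s[i]) j <- j + 1L
      if (j == n || s[j + 1L] < s[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Elbow (valley) threshold from a bimodal lock-value histogram
#'
#' Formalizes threshold selection by eye from the occurrence histogram: the
#' bulk of lock values forms a low-synchrony mode, genuinely synchronized
#' windows a separate high-synchrony mode, and the threshold is set at the
#' left edge of the minimum-count bin in the valley between them -- the
#' synchrony level just before the counts rise again. Modes are local maxima
#' of the 3-bin moving-average-smoothed counts; the bulk mode is the largest,
#' and the high mode is the topmost local maximum at higher synchrony that
#' holds at least `min_mode_frac` of all values and is separated from the
#' bulk by a genuine dip. When several valley bins tie at the minimum count,
#' the one adjacent to the rise (the highest-synchrony tied bin) is taken:
#' the threshold sits just before the counts rise into the synchronized
#' cluster.
#'
#' @param hist a `sync_histogram`.
#' @param min_mode_frac minimum fraction of values in the high mode for it to
#'   count as a genuine mode rather than tail noise.
#' @return threshold synchrony level in \[0, 1\].
#' @seealso [percentile_threshold()] for the fallback when no valley exists.
#' @export
elbow_threshold <- function(hist, min_mode_frac = 0.005) {
  stopifnot(inherits(hist, "sync_histogram"))
  counts <- hist$counts
  total <- sum(counts)
  s <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  s[1L] <- mean(counts[1:2])
  s[length(s)] <- mean(counts[(length(counts) - 1L):length(counts)])
  s <- as.numeric(s)

  peaks <- local_maxima(s)
  # endpoints can carry modes too (e.g. bulk piled against 0)
  if (s[1L] > s[2L]) peaks <- c(1L, peaks)
  n <- length(s)
  if (s[n] > s[n - 1L]) peaks <- c(peaks, n)
  if (length(peaks) < 2L) {
    stop("elbow_threshold: calibration failure, histogram has no separated high-synchrony mode",
         call. = FALSE)
  }
  bulk <- peaks[which.max(s[peaks])]
  above <- peaks[peaks > bulk + 1L]
  above <- above[s[above] >= min_mode_frac * total]
  # candidate high-synchrony modes, topmost first; accept the first whose
  # valley dips well below both modes (genuine separation, not tail noise)
  for (top in rev(above)) {
    valley <- (bulk + 1L):(top - 1L)
    vmin <- min(s[valley])
    if (vmin < 0.25 * min(s[bulk], s[top])) {
      vraw <- min(counts[valley])
      ties <- valley[counts[valley] == vraw]
      pick <- ties[length(ties)]            # tied bins: take the one just
      return(hist$bin_edges[pick])          # before the rise into the mode
    }
  }
  stop("elbow_threshold: calibration failure, histogram has no separated high-synchrony mode",
       call. = FALSE)
}

#' 95th-percentile threshold of a lock-value distribution
#'
#' The 95th percentile of the lock values, computed with linear interpolation
#' between order statistics; used as the significance level for synchrony,
#' and as the automatic fallback when the histogram has no separated
#' high-synchrony mode.
#'
#' @param series a `lock_series` or numeric vector.
#' @param prob percentile, default 0.95.
#' @return threshold synchrony level.
#' @export
percentile_threshold <- function(series, prob = 0.95) {
  v <- if (inherits(series, "lock_series")) series$values else as.numeric(series)
  if (length(v) == 0L) {
    stop("percentile_threshold: empty lock-value series", call. = FALSE)
  }
  unname(stats::quantile(v, prob, type = 7))
}

#' Patient-specific threshold set
#'
#' @param plv_threshold,alv_threshold lock-value thresholds in \[0, 1\].
#' @param s_aa,s_ap interictal analytic-amplitude SD (microvolts) and
#'   analytic-phase SD (radians) of the working channel.
#' @param sa_threshold,sp_threshold artifact-acceptance bounds: calibration
#'   requires `s_aa < sa_threshold` and `s_ap < sp_threshold`.
#' @param method threshold method actually used for the PLV series.
#' @param alv_method threshold method used for the ALV series.
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(plv_threshold, alv_threshold, s_aa, s_ap,
                          sa_threshold = 80, sp_threshold = 2.2,
                          method = "elbow", alv_method = method) {
  stopifnot(plv_threshold >= 0, plv_threshold <= 1,
            alv_threshold >= 0, alv_threshold <= 1,
            s_aa >= 0, s_ap >= 0)
  structure(list(plv_threshold = plv_threshold,
                 alv_threshold = alv_threshold,
                 s_aa = s_aa, s_ap = s_ap,
                 sa_threshold = sa_threshold, sp_threshold = sp_threshold,
                 method = method, alv_method = alv_method),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> PLV %.3f (%s), ALV %.3f (%s); S_AA=%.2f uV, S_AP=%.3f rad\n",
              x$plv_threshold, x$method, x$alv_threshold, x$alv_method,
              x$s_aa, x$s_ap))
  invisible(x)
}

#' Rescale thresholds to a patient's interictal signal statistics
#'
#' Cross-patient compensation: the patient's interictal analytic-amplitude
#' and analytic-phase SDs (`S_AAj`, `S_APj`) are measured from a non-seizure
#' segment and must pass the artifact-acceptance inequalities
#' `S_AAj < SA_threshold` and `S_APj < SP_threshold`; otherwise the segment
#' is rejected as artifact-contaminated. Accepted patients have the base
#' thresholds rescaled by `min(1, base * S_ref / S_patient)`: PLV by the
#' phase-SD ratio, ALV by the amplitude-SD ratio.
#'
#' @param base a [threshold_set()] whose `s_aa`/`s_ap` act as the reference
#'   SDs.
#' @param analytic an `analytic_signal` of an interictal working-channel
#'   segment (>= 60 s), or `NULL` if `s_aa`/`s_ap` are given directly.
#' @param fs sampling rate of the segment, Hz (for the length check).
#' @param s_aa,s_ap patient SDs, if already computed.
#' @return a [threshold_set()] with rescaled thresholds and the patient SDs.
#' @export
scale_thresholds <- function(base, analytic = NULL, fs = 256,
                             s_aa = NULL, s_ap = NULL) {
  stopifnot(inherits(base, "threshold_set"))
  if (!is.null(analytic)) {
    stopifnot(inherits(analytic, "analytic_signal"))
    if (length(analytic$aa) < 60 * fs) {
      stop("scale_thresholds: interictal segment shorter than 60 s",
           call. = FALSE)
    }
    v <- analytic$valid
    s_aa <- stats::sd(analytic$aa[v[1]:v[2]])
    s_ap <- stats::sd(analytic$ap[v[1]:v[2]])
  }
  if (is.null(s_aa) || is.null(s_ap)) {
    stop("scale_thresholds: need an analytic segment or explicit SDs",
         call. = FALSE)
  }
  if (s_aa >= base$sa_threshold) {
    stop("scale_thresholds: artifact contamination, S_AA ", signif(s_aa, 4),
         " >= SA_threshold ", base$sa_threshold, call. = FALSE)
  }
  if (s_ap >= base$sp_threshold) {
    stop("scale_thresholds: artifact contamination, S_AP ", signif(s_ap, 4),
         " >= SP_threshold ", base$sp_threshold, call. = FALSE)
  }
  threshold_set(
    plv_threshold = min(1, base$plv_threshold * base$s_ap / s_ap),
    alv_threshold = min(1, base$alv_threshold * base$s_aa / s_aa),
    s_aa = s_aa, s_ap = s_ap,
    sa_threshold = base$sa_threshold, sp_threshold = base$sp_threshold,
    method = base$method, alv_method = base$alv_method
  )
}

# threshold for one lock series under the configured method, with the
# documented precedence: elbow first, 95th-percentile fallback when the
# histogram has no separated high-synchrony mode.
series_threshold <- function(series, config) {
  if (config$threshold_method == "percentile95") {
    return(list(threshold = percentile_threshold(series),
                method = "percentile95"))
  }
  hist <- build_histogram(series, config$bin_width)
  thr <- tryCatch(elbow_threshold(hist, config$min_mode_frac),
                  error = function(e) NULL)
  if (is.null(thr)) {
    list(threshold = percentile_threshold(series), method = "percentile95")
  } else {
    list(threshold = thr, method = "elbow")
  }
}

#' Calibrate patient-specific thresholds from a calibration record
#'
#' Runs the full pipeline on the calibration record (one of the patient's
#' datasets, distinct from the evaluation records), builds the PLV and ALV
#' occurrence histograms, places each threshold by the elbow rule (falling
#' back to the 95th percentile when no high-synchrony mode is separated),
#' checks the artifact-acceptance inequalities, and -- when cohort reference
#' SDs are configured -- applies the cross-patient SD scaling.
#'
#' @param calib_record an [eeg_record()] used only for calibration.
#' @param config a [run_config()].
#' @param band a [band_spec()]; defaults to the config's primary band.
#' @return a [threshold_set()]; the working/reference channel selection is
#'   attached as attribute `"channels"`.
#' @export
calibrate_patient <- function(calib_record, config = run_config(),
                              band = config$bands[[config$band]]) {
  lp <- lock_pipeline(calib_record, band, config)
  pt <- series_threshold(lp$plv, config)
  at <- series_threshold(lp$alv, config)

  ts <- threshold_set(pt$threshold, at$threshold,
                      s_aa = lp$s_aa, s_ap = lp$s_ap,
                      sa_threshold = config$sa_threshold,
                      sp_threshold = config$sp_threshold,
                      method = pt$method, alv_method = at$method)
  if (ts$s_aa >= ts$sa_threshold) {
    stop("calibrate_patient: artifact contamination, S_AA ",
         signif(ts$s_aa, 4), " >= SA_threshold ", ts$sa_threshold,
         call. = FALSE)
  }
  if (ts$s_ap >= ts$sp_threshold) {
    stop("calibrate_patient: artifact contamination, S_AP ",
         signif(ts$s_ap, 4), " >= SP_threshold ", ts$sp_threshold,
         call. = FALSE)
  }
  if (!is.null(config$ref_s_aa) && !is.null(config$ref_s_ap)) {
    ref <- ts
    ref$s_aa <- config$ref_s_aa
    ref$s_ap <- config$ref_s_ap
    ts <- scale_thresholds(ref, s_aa = lp$s_aa, s_ap = lp$s_ap)
  }
  attr(ts, "channels") <- lp$channels
  ts
}

#' Write / read a per-patient calibration file
#'
#' Flat key-value YAML serialization of a [threshold_set()].
#'
#' @param ts a [threshold_set()].
#' @param path file path.
#' @return `path` (write) or a [threshold_set()] (read).
#' @export
write_threshold_set <- function(ts, path) {
  stopifnot(inherits(ts, "threshold_set"))
  yaml::write_yaml(unclass(ts), path)
  invisible(path)
}

#' @rdname write_threshold_set
#' @export
read_threshold_set <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(threshold_set, vals)
}
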