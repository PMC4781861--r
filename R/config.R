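# Run configuration: bands, window geometry, thresholds, seeds.

#' Band specification
#'
#' @param name band name.
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2` for
#'   the sampling rates the band is used with.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("band_spec: need 0 < low_hz < high_hz", call. = FALSE)
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_spec")
}

#' Default EEG analysis bands
#'
#' The five band-pass ranges used throughout: delta-theta-alpha (1-12 Hz),
#' alpha (6-12 Hz), beta (13-30 Hz), gamma (30-40 Hz) and upper-gamma
#' (40-50 Hz).
#'
#' @return named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(
    `delta-theta-alpha` = band_spec("delta-theta-alpha", 1, 12),
    alpha = band_spec("alpha", 6, 12),
    beta = band_spec("beta", 13, 30),
    gamma = band_spec("gamma", 30, 40),
    `upper-gamma` = band_spec("upper-gamma", 40, 50)
  )
}

#' Run configuration
#'
#' Assembles the tunable parameters of the prediction/detection pipeline with
#' validated defaults. Any subset can be overridden.
#'
#' @param window_n sliding-window length in samples for PLV/ALV (1000, 2500
#'   or 5000 in the reference setup).
#' @param stride window stride in samples; defaults to `window_n / 4`.
#' @param sph_window_s seizure prediction horizon (SPH + SOP) in seconds;
#'   3600 by default, 1800 for the half-hour variant.
#' @param band name of the primary analysis band (one of [default_bands()]).
#' @param bands list of [band_spec()] used by [sweep_bands()].
#' @param threshold_method `"elbow"` (histogram valley, with automatic
#'   fallback) or `"percentile95"`.
#' @param min_duration_s minimum supra-threshold run duration, seconds, for a
#'   marker event (debounce).
#' @param numtaps FIR filter length (odd); about one second at 256 Hz.
#' @param bin_width lock-value histogram bin width on \[0, 1\].
#' @param min_mode_frac minimum fraction of lock values a high-synchrony
#'   histogram mode must hold to count as a genuine mode for the elbow rule.
#' @param sa_threshold,sp_threshold artifact-acceptance bounds for the
#'   interictal analytic-amplitude SD (microvolts) and analytic-phase SD
#'   (radians): calibration segments at or above them are rejected as
#'   artifact-contaminated.
#' @param ref_s_aa,ref_s_ap optional cohort reference SDs; when set,
#'   calibrated thresholds are rescaled by `S_ref / S_patient` (see
#'   [scale_thresholds()]). `NULL` (default) keeps the patient's own
#'   calibration unscaled.
#' @param alv_normalize logical; divide analytic amplitudes by their
#'   interictal SD before the ALV exponential (recommended; `FALSE` uses raw
#'   microvolt differences, the literal form).
#' @param sph_variants SPH windows (seconds) reported by cohort summaries.
#' @param tau_w0_s chance-predictor detection interval tau_w0, seconds.
#' @param snc_form `"printed"` for the published chance-sensitivity formula,
#'   `"limit"` for its small-rate limit `1 - exp(-lambda (tau_w - tau_w0))`.
#' @param seed integer seed for every stochastic step.
#' @param artifact_channel_blocklist channel labels excluded before
#'   working/reference selection.
#' @param auto_artifact logical; additionally flag channels whose samples
#'   exceed 500 uV absolute more than 1 percent of the time.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(window_n = 1000L,
                       stride = NULL,
                       sph_window_s = 3600,
                       band = "gamma",
                       bands = default_bands(),
                       threshold_method = c("elbow", "percentile95"),
                       min_duration_s = 2,
                       numtaps = 257L,
                       bin_width = 0.01,
                       min_mode_frac = 0.005,
                       sa_threshold = 80,
                       sp_threshold = 2.2,
                       ref_s_aa = NULL,
                       ref_s_ap = NULL,
                       alv_normalize = TRUE,
                       sph_variants = c(3600, 1800),
                       tau_w0_s = 0,
                       snc_form = c("printed", "limit"),
                       seed = 1L,
                       artifact_channel_blocklist = character(),
                       auto_artifact = TRUE) {
  window_n <- as.integer(window_n)
  if (window_n < 2L) stop("run_config: window_n must be >= 2", call. = FALSE)
  if (is.null(stride)) stride <- max(1L, window_n %/% 4L)
  stride <- as.integer(stride)
  if (stride < 1L || stride > window_n) {
    stop("run_config: need 1 <= stride <= window_n", call. = FALSE)
  }
  if (sph_window_s <= 0) {
    stop("run_config: sph_window_s must be positive", call. = FALSE)
  }
  numtaps <- as.integer(numtaps)
  if (numtaps %% 2L == 0L) {
    stop("run_config: numtaps must be odd", call. = FALSE)
  }
  structure(list(
    window_n = window_n, stride = stride, sph_window_s = sph_window_s,
    band = band, bands = bands,
    threshold_method = match.arg(threshold_method),
    min_duration_s = min_duration_s, numtaps = numtaps,
    bin_width = bin_width, min_mode_frac = min_mode_frac,
    sa_threshold = sa_threshold, sp_threshold = sp_threshold,
    ref_s_aa = ref_s_aa, ref_s_ap = ref_s_ap,
    alv_normalize = isTRUE(alv_normalize),
    sph_variants = sph_variants, tau_w0_s = tau_w0_s,
    snc_form = match.arg(snc_form), seed = as.integer(seed),
    artifact_channel_blocklist = artifact_channel_blocklist,
    auto_artifact = isTRUE(auto_artifact)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value YAML; keys match the arguments of [run_config()]. Bands may
#' be given as a mapping of `name: [low_hz, high_hz]` pairs.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_run_config: no such file: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$bands)) {
    vals$bands <- lapply(seq_along(vals$bands), function(i) {
      edges <- vals$bands[[i]]
      band_spec(names(vals$bands)[i], edges[[1]], edges[[2]])
    })
    names(vals$bands) <- vapply(vals$bands, `[[`, character(1), "name")
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}
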