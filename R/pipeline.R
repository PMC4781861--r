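# End-to-end orchestration: calibrate -> detect -> classify -> aggregate,
# with chance-predictor significance per patient.

#' Evaluate one patient: calibrate, detect, classify
#'
#' Calibrates thresholds on the patient's calibration record, extracts
#' markers from each evaluation record, classifies them against the seizure
#' annotations under the SPH window, and derives the patient's
#' chance-predictor statistics. The warning proportion `rho_w` is the total
#' active duration of prediction markers divided by total evaluated time.
#'
#' @param patient list with `patient_id`, `calib` (an [eeg_record()]) and
#'   `evals` (list of [eeg_record()]), as from [generate_cohort()] or
#'   [load_patient()].
#' @param config a [run_config()].
#' @param band a [band_spec()]; defaults to the config's primary band.
#' @param thresholds optional pre-computed [threshold_set()] (skips
#'   calibration).
#' @return one-row data frame of counts and statistics, with the
#'   [threshold_set()] attached as attribute `"thresholds"` and per-TP lead
#'   times as attribute `"sph_list_s"`.
#' @export
evaluate_patient <- function(patient, config = run_config(),
                             band = config$bands[[config$band]],
                             thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- calibrate_patient(patient$calib, config, band)
  }
  tp <- 0L; fp <- 0L; fn <- 0L; redundant <- 0L
  sph_list <- numeric(0)
  warning_s <- 0
  total_s <- 0
  interictal_s <- 0
  for (rec in patient$evals) {
    lp <- lock_pipeline(rec, band, config)
    markers <- detect_markers(lp$plv, lp$alv, thresholds,
                              config$min_duration_s)
    cls <- classify_events(markers, rec$annotations, config$sph_window_s)
    tp <- tp + cls$tp; fp <- fp + cls$fp; fn <- fn + cls$fn
    redundant <- redundant + cls$redundant
    sph_list <- c(sph_list, cls$sph_list_s)
    pm <- markers[markers$kind == "P", , drop = FALSE]
    warning_s <- warning_s + sum(pm$duration_s)
    total_s <- total_s + record_duration(rec)
    interictal_s <- interictal_s + record_duration(rec) - ictal_seconds(rec)
  }
  rho_w <- min(warning_s / total_s, 1 - 1e-12)
  model <- chance_model(tau_w = config$sph_window_s, rho_w = rho_w,
                        tau_w0 = config$tau_w0_s,
                        snc_form = config$snc_form)
  n_seiz <- tp + fn
  p_value <- if (n_seiz > 0) {
    two_sided_pvalue(tp, n_seiz, model$s_nc)
  } else NA_real_
  out <- data.frame(patient = patient$patient_id,
                    tp = tp, fp = fp, fn = fn, redundant = redundant,
                    n_seizures = n_seiz,
                    interictal_hours = interictal_s / 3600,
                    rho_w = rho_w, s_nc = model$s_nc,
                    s_n = if (n_seiz > 0) tp / n_seiz else NA_real_,
                    p_value = p_value,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  attr(out, "sph_list_s") <- sph_list
  out
}

#' Evaluate a patient cohort
#'
#' Runs [evaluate_patient()] over every patient and aggregates with
#' [compute_metrics()]. The cohort median-improvement test (exact sign test
#' on `S_n - S_nc`) is attached as `$median_test_p`, the per-patient
#' [threshold_set()]s as `$thresholds`, and pooled TP lead times as
#' `$sph_list_s`.
#'
#' @param cohort list of patients (see [generate_cohort()]).
#' @param config a [run_config()].
#' @param band a [band_spec()]; defaults to the config's primary band.
#' @return an `eval_result` (see [compute_metrics()]) with the extra fields
#'   above.
#' @export
evaluate_cohort <- function(cohort, config = run_config(),
                            band = config$bands[[config$band]]) {
  rows <- vector("list", length(cohort))
  thresholds <- vector("list", length(cohort))
  sph_all <- numeric(0)
  for (i in seq_along(cohort)) {
    rows[[i]] <- evaluate_patient(cohort[[i]], config, band)
    thresholds[[i]] <- attr(rows[[i]], "thresholds")
    sph_all <- c(sph_all, attr(rows[[i]], "sph_list_s"))
  }
  df <- do.call(rbind, rows)
  res <- compute_metrics(df, sph_window_s = config$sph_window_s)
  ok <- !is.na(df$s_n)
  res$median_test_p <- if (any(ok)) {
    median_improvement_test(cbind(df$s_n[ok], df$s_nc[ok]))
  } else NA_real_
  names(thresholds) <- df$patient
  res$thresholds <- thresholds
  res$sph_list_s <- sph_all
  res$band <- band$name
  res
}

#' Sweep bands and window sizes over a cohort
#'
#' Full factorial evaluation: one [evaluate_cohort()] run per (band,
#' window size) pair, with calibration repeated per condition. Rows are
#' ordered by the given band order, then window size. Conditions are ranked
#' by F1 score (harmonic mean of macro sensitivity and precision; a band
#' that merely alarms often enough to catch every seizure by accident is
#' ranked below one that predicts with few false alarms), with ties broken
#' by lower FP/h and then higher sensitivity.
#'
#' @param cohort list of patients.
#' @param config a [run_config()]; its `window_n`/`stride` are overridden
#'   per condition (stride = window/4).
#' @param bands list of [band_spec()] to evaluate.
#' @param windows integer vector of window sizes, samples.
#' @return data frame of class `sweep_table` with one row per condition:
#'   counts, macro/pooled metrics, number of significant patients at 0.05,
#'   and `rank` (1 = best).
#' @export
sweep_bands <- function(cohort, config = run_config(),
                        bands = config$bands, windows = config$window_n) {
  rows <- list()
  for (b in bands) {
    for (w in windows) {
      cfg <- config
      cfg$window_n <- as.integer(w)
      cfg$stride <- max(1L, as.integer(w) %/% 4L)
      res <- evaluate_cohort(cohort, cfg, band = b)
      rows[[length(rows) + 1L]] <- data.frame(
        band = b$name, window_n = as.integer(w),
        tp = res$pooled$tp, fp = res$pooled$fp, fn = res$pooled$fn,
        sensitivity_pct = round(res$macro$sensitivity_pct, 2),
        precision_pct = round(res$macro$precision_pct, 2),
        fp_per_h = round(res$pooled$fp_per_h, 3),
        pooled_sensitivity_pct = round(res$pooled$sensitivity_pct, 2),
        pooled_precision_pct = round(res$pooled$precision_pct, 2),
        n_significant = sum(res$patients$p_value < 0.05, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  se <- out$sensitivity_pct
  pr <- out$precision_pct
  out$f1 <- ifelse(se + pr > 0, 2 * se * pr / (se + pr), 0)
  key <- order(-out$f1, out$fp_per_h, -out$sensitivity_pct)
  out$rank <- integer(nrow(out))
  out$rank[key] <- seq_len(nrow(out))
  class(out) <- c("sweep_table", "data.frame")
  out
}
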