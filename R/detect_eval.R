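# Marker extraction, SPH/SOP classification, and metric aggregation.

#' Extract prediction (P) and seizure (S) markers from lock-value series
#'
#' Each window is classified: `S` when both PLV and ALV exceed their
#' thresholds (amplitude entrainment marks the seizure itself), `P` when
#' only the PLV does (phase entrainment alone marks the preictal state).
#' Contiguous same-state windows form runs; a run becomes a marker event if
#' it lasts at least `min_duration_s` (debounce against isolated
#' supra-threshold windows). An `S` run absorbs immediately adjacent
#' contiguous `P` runs: the preceding buildup becomes part of the `S` event
#' (its onset is the start of the buildup), and a trailing `P` run -- an
#' artifact of windows straddling the end of the amplitude-locked interval
#' -- is folded in rather than emitted as a separate prediction.
#'
#' @param plv,alv aligned `lock_series` on identical window grids.
#' @param thresholds a [threshold_set()].
#' @param min_duration_s minimum event duration in seconds.
#' @return data frame with columns `kind` ("P"/"S"), `t_s` (first window
#'   center, seconds), `duration_s` (first window start to last window end).
#' @export
detect_markers <- function(plv, alv, thresholds, min_duration_s = 2) {
  if (length(plv$values) != length(alv$values) ||
      plv$window_n != alv$window_n || plv$stride != alv$stride ||
      (length(plv$values) > 0 &&
       any(abs(plv$t_centers_s - alv$t_centers_s) > 1e-9))) {
    stop("detect_markers: PLV and ALV are not on identical window grids",
         call. = FALSE)
  }
  empty <- data.frame(kind = character(0), t_s = numeric(0),
                      duration_s = numeric(0))
  if (length(plv$values) == 0L) return(empty)

  state <- ifelse(plv$values > thresholds$plv_threshold,
                  ifelse(alv$values > thresholds$alv_threshold, "S", "P"),
                  "-")
  r <- rle(state)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- data.frame(kind = r$values, from = begins, to = ends,
                     stringsAsFactors = FALSE)
  runs <- runs[runs$kind != "-", , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  # S absorbs contiguous P runs on either side
  if (nrow(runs) > 1L) {
    drop <- logical(nrow(runs))
    for (i in seq_len(nrow(runs) - 1L)) {
      if (runs$kind[i] == "P" && runs$kind[i + 1L] == "S" &&
          runs$to[i] + 1L == runs$from[i + 1L]) {
        runs$from[i + 1L] <- runs$from[i]
        drop[i] <- TRUE
      }
    }
    for (i in 2L:nrow(runs)) {
      if (runs$kind[i] == "P" && runs$kind[i - 1L] == "S" && !drop[i - 1L] &&
          runs$from[i] == runs$to[i - 1L] + 1L) {
        runs$to[i - 1L] <- runs$to[i]
        drop[i] <- TRUE
      }
    }
    runs <- runs[!drop, , drop = FALSE]
  }

  fs <- plv$fs
  dur <- ((runs$to - runs$from) * plv$stride + plv$window_n) / fs
  out <- data.frame(kind = runs$kind,
                    t_s = plv$t_centers_s[runs$from],
                    duration_s = dur,
                    stringsAsFactors = FALSE)
  out[out$duration_s >= min_duration_s, , drop = FALSE]
}

#' Classify prediction markers against seizure annotations (SPH/SOP)
#'
#' A prediction marker is a true positive when a seizure onset follows it
#' within `(0, sph_window_s]`; markers and seizures are matched one-to-one,
#' earliest first. A seizure with no matched marker is a false negative. A
#' marker with no seizure onset at all inside its window is a false
#' positive (an SPH with no subsequent SOP event). A marker whose window
#' does contain an onset that another, earlier marker already claimed is
#' counted as redundant: it is neither a TP (one-to-one matching) nor an FP
#' (it did forewarn a real seizure).
#'
#' @param markers data frame from [detect_markers()] (only `kind == "P"`
#'   rows are used).
#' @param annotations list of [seizure_annotation()].
#' @param sph_window_s SPH + SOP horizon, seconds.
#' @return list with counts `tp`, `fp`, `fn`, `redundant` and `sph_list_s`,
#'   the per-TP lead times (onset minus marker time) in seconds.
#' @export
classify_events <- function(markers, annotations, sph_window_s = 3600) {
  p <- markers[markers$kind == "P", , drop = FALSE]
  p <- p[order(p$t_s), , drop = FALSE]
  onsets <- sort(vapply(annotations, `[[`, numeric(1), "onset_s"))
  claimed <- logical(length(onsets))
  tp <- 0L; fp <- 0L; redundant <- 0L
  sph_list <- numeric(0)
  for (i in seq_len(nrow(p))) {
    t <- p$t_s[i]
    in_window <- which(onsets > t & onsets <= t + sph_window_s)
    free <- in_window[!claimed[in_window]]
    if (length(free) > 0L) {
      j <- free[1L]                       # earliest unclaimed onset
      claimed[j] <- TRUE
      tp <- tp + 1L
      sph_list <- c(sph_list, onsets[j] - t)
    } else if (length(in_window) > 0L) {
      redundant <- redundant + 1L
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = sum(!claimed), redundant = redundant,
       sph_list_s = sph_list)
}

# integer percent of a pooled count ratio: truncation toward zero, the
# convention consistent with printed pooled totals (24/31 -> 77, 20/31 -> 64)
#' Truncated integer percent of a count ratio
#' @param num,den nonnegative counts.
#' @return `trunc(100 * num / den)`, or `NA` when `den == 0`.
#' @export
pooled_pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  trunc(100 * num / den)
}

#' Aggregate per-patient counts into evaluation metrics
#'
#' Computes per-patient sensitivity `100 TP/(TP+FN)`, precision
#' `100 TP/(TP+FP)`, false positives per interictal hour, and the percentage
#' of interictal time covered by false SPH windows
#' (`100 * fp * sph_window_s/3600 / interictal_hours`, capped at 100).
#' Cohort totals are reported both pooled (sum the counts, then divide) and
#' macro-averaged (mean of per-patient rates, undefined rates excluded).
#' Integer-percent reporting follows the printed-table conventions: pooled
#' ratios truncate toward zero, macro averages round to the nearest percent;
#' 2-decimal values are always carried alongside.
#'
#' @param per_patient data frame with columns `patient`, `tp`, `fp`, `fn`,
#'   `interictal_hours` (and optionally `p_value`, `n_seizures`).
#' @param sph_window_s SPH window used, for the FP-percentage convention.
#' @return object of class `eval_result`: `$patients` (per-patient table),
#'   `$pooled` and `$macro` (named lists of cohort metrics).
#' @export
compute_metrics <- function(per_patient, sph_window_s = 3600) {
  df <- as.data.frame(per_patient)
  need <- c("patient", "tp", "fp", "fn", "interictal_hours")
  if (!all(need %in% names(df))) {
    stop("compute_metrics: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(df$tp >= 0), all(df$fp >= 0), all(df$fn >= 0))
  rate <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  df$n_seizures <- df$tp + df$fn
  df$sensitivity_pct <- round(rate(df$tp, df$tp + df$fn), 2)
  df$precision_pct <- round(rate(df$tp, df$tp + df$fp), 2)
  df$fp_per_h <- round(ifelse(df$interictal_hours > 0,
                              df$fp / df$interictal_hours, NA_real_), 2)
  df$fp_pct <- round(pmin(100, ifelse(df$interictal_hours > 0,
                                      100 * df$fp * (sph_window_s / 3600) /
                                        df$interictal_hours, NA_real_)), 2)

  pooled <- list(
    tp = sum(df$tp), fp = sum(df$fp), fn = sum(df$fn),
    interictal_hours = sum(df$interictal_hours),
    sensitivity_pct = rate(sum(df$tp), sum(df$tp + df$fn)),
    precision_pct = rate(sum(df$tp), sum(df$tp + df$fp)),
    fp_per_h = if (sum(df$interictal_hours) > 0)
      sum(df$fp) / sum(df$interictal_hours) else NA_real_,
    sensitivity_int = pooled_pct(sum(df$tp), sum(df$tp + df$fn)),
    precision_int = pooled_pct(sum(df$tp), sum(df$tp + df$fp))
  )
  macro <- list(
    sensitivity_pct = mean(df$sensitivity_pct, na.rm = TRUE),
    precision_pct = mean(df$precision_pct, na.rm = TRUE),
    fp_per_h = mean(df$fp_per_h, na.rm = TRUE),
    sensitivity_int = round(mean(df$sensitivity_pct, na.rm = TRUE)),
    precision_int = round(mean(df$precision_pct, na.rm = TRUE))
  )
  structure(list(patients = df, pooled = pooled, macro = macro,
                 sph_window_s = sph_window_s),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d patient(s): pooled TP=%d FP=%d FN=%d | macro sens %.1f%%, prec %.1f%%, %.2f FP/h\n",
              nrow(x$patients), x$pooled$tp, x$pooled$fp, x$pooled$fn,
              x$macro$sensitivity_pct, x$macro$precision_pct,
              x$macro$fp_per_h))
  invisible(x)
}
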