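# Synthetic multichannel EEG with planted preictal/ictal entrainment.
#
# The working and reference channels carry noisy phase oscillators at a
# shared base frequency. Outside episodes their phases random-walk apart
# (independent basal activity). During a bounded preictal burst the working
# phase is pulled toward the reference phase with strength kappa
# (phase increment = 2 pi f / fs + kappa * sin(phi_ref - phi_work) + noise),
# raising the PLV while amplitudes stay independent; the coupling then
# releases before onset (the reconstitution interval), and during the ictal
# interval both the phase coupling and amplitude entrainment are active, so
# PLV and ALV rise together.

#' Synthetic EEG configuration
#'
#' @param duration_s record length, seconds.
#' @param episodes data frame with columns `preictal_start_s`, `onset_s`,
#'   `end_s`: non-overlapping planted episodes with
#'   `preictal_start_s < onset_s < end_s <= duration_s`.
#' @param n_channels number of channels (>= 2): reference, working, then
#'   inert background channels.
#' @param fs sampling rate, Hz.
#' @param base_freq_hz shared oscillator frequency; 35 Hz by default, inside
#'   the gamma band.
#' @param detune_hz natural-frequency mismatch between the two oscillators
#'   (reference at `base - detune/2`, working at `base + detune/2`).
#'   Uncoupled, the phase difference drifts at this rate and windows
#'   decorrelate; coupling above the Adler threshold
#'   (`kappa > 2 pi detune / fs`) locks the pair at a constant small lag.
#' @param coupling kappa in \[0, 1\]: per-sample phase-coupling gain during
#'   episodes, and the amplitude blend factor during ictal intervals.
#' @param noise_sd additive measurement-noise SD on the working channel,
#'   microvolts.
#' @param phase_noise_sd per-sample phase-increment noise SD, radians;
#'   governs how fast uncoupled phases drift apart and how often coupled
#'   phases slip.
#' @param preictal_burst_s duration of the preictal coupling burst, seconds,
#'   starting at `preictal_start_s`; truncated to end at least 30 s before
#'   onset when the lead time is short.
#' @param osc_amp_work,osc_amp_ref oscillator amplitudes, microvolts.
#' @param ref_noise_sd,bg_noise_sd measurement-noise SDs of the reference
#'   and background channels, microvolts.
#' @param amp_scale patient-level amplitude scale multiplying every
#'   microvolt quantity (exercises cross-patient SD scaling).
#' @param seed integer seed; the record is fully reproducible from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(duration_s,
                         episodes = NULL,
                         n_channels = 3L,
                         fs = 256,
                         base_freq_hz = 35,
                         detune_hz = 0.5,
                         coupling = 1,
                         noise_sd = 10,
                         phase_noise_sd = 0.01,
                         preictal_burst_s = 180,
                         osc_amp_work = 40,
                         osc_amp_ref = 14,
                         ref_noise_sd = 5,
                         bg_noise_sd = 15,
                         amp_scale = 1,
                         seed = 1L) {
  if (n_channels < 2L) stop("synth_config: need >= 2 channels", call. = FALSE)
  if (!(coupling >= 0 && coupling <= 1)) {
    stop("synth_config: coupling must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(episodes)) {
    episodes <- data.frame(preictal_start_s = numeric(0),
                           onset_s = numeric(0), end_s = numeric(0))
  }
  episodes <- as.data.frame(episodes)
  if (nrow(episodes) > 0L) {
    ok <- episodes$preictal_start_s < episodes$onset_s &
      episodes$onset_s < episodes$end_s &
      episodes$preictal_start_s >= 0 & episodes$end_s <= duration_s
    if (!all(ok)) {
      stop("synth_config: episodes must satisfy 0 <= preictal_start < onset < end <= duration",
           call. = FALSE)
    }
    o <- order(episodes$preictal_start_s)
    episodes <- episodes[o, , drop = FALSE]
    if (nrow(episodes) > 1L &&
        any(episodes$preictal_start_s[-1L] <
            episodes$end_s[-nrow(episodes)])) {
      stop("synth_config: episodes overlap", call. = FALSE)
    }
  }
  structure(list(duration_s = duration_s, episodes = episodes,
                 n_channels = as.integer(n_channels), fs = fs,
                 base_freq_hz = base_freq_hz, detune_hz = detune_hz,
                 coupling = coupling,
                 noise_sd = noise_sd, phase_noise_sd = phase_noise_sd,
                 preictal_burst_s = preictal_burst_s,
                 osc_amp_work = osc_amp_work, osc_amp_ref = osc_amp_ref,
                 ref_noise_sd = ref_noise_sd, bg_noise_sd = bg_noise_sd,
                 amp_scale = amp_scale, seed = as.integer(seed)),
            class = "synth_config")
}

# slowly varying unit-SD envelope modulation: white noise smoothed with a
# Gaussian kernel (sigma ~ fs/8, i.e. ~2 Hz bandwidth). A Gaussian kernel is
# essentially band-limited, so the AM sidebands it creates stay inside the
# analysis band and are not truncated into spurious phase jitter.
slow_envelope <- function(n, fs) {
  sigma <- max(2, fs / 8)
  half <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  s <- stats::filter(stats::rnorm(n + 2L * half), k, sides = 2L)
  s <- as.numeric(s[(half + 1L):(half + n)])
  s / stats::sd(s)
}

# integrate the working phase: free (cumsum) stretches interleaved with
# coupled stretches iterated sample by sample
integrate_coupled_phase <- function(phi_ref, base_inc, noise, kappa_on,
                                    kappa) {
  n <- length(phi_ref)
  phi <- numeric(n)
  phi[1L] <- stats::runif(1L, -pi, pi)
  r <- rle(kappa_on)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  for (seg in seq_along(r$values)) {
    a <- begins[seg]; b <- ends[seg]
    from <- if (a == 1L) 2L else a
    if (from > b) next
    if (!r$values[seg] || kappa == 0) {
      phi[from:b] <- phi[from - 1L] +
        cumsum(base_inc + noise[from:b])
    } else {
      p <- phi[from - 1L]
      for (t in from:b) {
        p <- p + base_inc + kappa * sin(phi_ref[t - 1L] - p) + noise[t]
        phi[t] <- p
      }
    }
  }
  phi
}

#' Generate a synthetic EEG record with planted episodes
#'
#' See [synth_config()] for the generative model. Channel 1 is the reference
#' oscillator (lowest SD), channel 2 the working oscillator (highest SD),
#' and remaining channels are inert Gaussian background. Planted seizures
#' are carried as annotations; the truth table of episode intervals is
#' attached as attribute `"episodes"`.
#'
#' @param config a [synth_config()].
#' @return an [eeg_record()].
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  inc_ref <- 2 * pi * (config$base_freq_hz - config$detune_hz / 2) / fs
  inc_w <- 2 * pi * (config$base_freq_hz + config$detune_hz / 2) / fs
  ep <- config$episodes

  # per-sample coupling mask: preictal burst + ictal interval
  kappa_on <- logical(n)
  ictal_on <- logical(n)
  idx <- function(t) pmin(n, pmax(1L, as.integer(floor(t * fs)) + 1L))
  for (i in seq_len(nrow(ep))) {
    lead <- ep$onset_s[i] - ep$preictal_start_s[i]
    burst_end <- ep$preictal_start_s[i] +
      min(config$preictal_burst_s, lead - 30)
    if (burst_end > ep$preictal_start_s[i]) {
      kappa_on[idx(ep$preictal_start_s[i]):idx(burst_end)] <- TRUE
    }
    seiz <- idx(ep$onset_s[i]):idx(ep$end_s[i])
    kappa_on[seiz] <- TRUE
    ictal_on[seiz] <- TRUE
  }

  phi_ref <- stats::runif(1L, -pi, pi) +
    cumsum(inc_ref + stats::rnorm(n, 0, config$phase_noise_sd))
  noise_w <- stats::rnorm(n, 0, config$phase_noise_sd)
  phi_w <- integrate_coupled_phase(phi_ref, inc_w, noise_w, kappa_on,
                                   config$coupling)

  sc <- config$amp_scale
  amp_w <- config$osc_amp_work * sc
  amp_r <- config$osc_amp_ref * sc
  env_w <- pmax(0.3, 1 + 0.5 * slow_envelope(n, fs))
  env_r <- pmax(0.3, 1 + 0.5 * slow_envelope(n, fs))
  # ictal amplitude entrainment: blend the working envelope toward the
  # (scale-matched) reference envelope by kappa
  env_w[ictal_on] <- (1 - config$coupling) * env_w[ictal_on] +
    config$coupling * env_r[ictal_on]

  data <- matrix(0, nrow = config$n_channels, ncol = n)
  data[1L, ] <- amp_r * env_r * cos(phi_ref) +
    stats::rnorm(n, 0, config$ref_noise_sd * sc)
  data[2L, ] <- amp_w * env_w * cos(phi_w) +
    stats::rnorm(n, 0, config$noise_sd * sc)
  if (config$n_channels > 2L) {
    for (ch in 3L:config$n_channels) {
      data[ch, ] <- stats::rnorm(n, 0, config$bg_noise_sd * sc)
    }
  }
  labels <- c("REF", "WORK",
              if (config$n_channels > 2L)
                sprintf("BG%02d", seq_len(config$n_channels - 2L)))
  anns <- lapply(seq_len(nrow(ep)), function(i) {
    seizure_annotation(ep$onset_s[i], ep$end_s[i])
  })
  rec <- eeg_record(data, fs = fs, channel_labels = labels,
                    annotations = anns, patient_id = "synth",
                    record_id = sprintf("synth_seed%d", config$seed))
  attr(rec, "episodes") <- ep
  rec
}

#' Generate a synthetic patient cohort
#'
#' Per patient: one calibration record (1800 s, one planted episode) and
#' three evaluation records (4200 s each, one planted seizure each with
#' onset at 3900 s), giving 3 evaluation seizures and over 3 h of interictal
#' time per patient. Preictal lead times are drawn uniformly from 2 to 62
#' minutes; seizure durations from 30 to 90 s. Patients differ in amplitude
#' scale (drawn from \[0.6, 1.8\]) and in noise realization; the schedule
#' draws and per-record noise seeds all derive deterministically from
#' `seed`.
#'
#' @param n_patients number of patients.
#' @param template a [synth_config()] supplying every non-schedule parameter
#'   (its `duration_s`, `episodes` and `seed` are overridden per record).
#' @param seed cohort seed.
#' @param calib_duration_s,eval_duration_s record lengths, seconds.
#' @param n_eval_records evaluation records per patient (one seizure each).
#' @return list of patients, each a list with `patient_id`, `amp_scale`,
#'   `calib` (an [eeg_record()]) and `evals` (list of [eeg_record()]).
#' @export
generate_cohort <- function(n_patients = 10L,
                            template = synth_config(duration_s = 4200),
                            seed = 1L,
                            calib_duration_s = 1800,
                            eval_duration_s = 4200,
                            n_eval_records = 3L) {
  stopifnot(n_patients >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  amp_scales <- stats::runif(n_patients, 0.6, 1.8)
  onset <- eval_duration_s - 300
  # leads drawn uniformly over 2-62 min, truncated to fit short records
  leads <- matrix(stats::runif(n_patients * n_eval_records, 120, 3720),
                  nrow = n_patients)
  leads <- pmin(leads, onset - 60)
  durs <- matrix(stats::runif(n_patients * n_eval_records, 30, 90),
                 nrow = n_patients)
  rec_seeds <- matrix(sample.int(.Machine$integer.max,
                                 n_patients * (n_eval_records + 1L)),
                      nrow = n_patients)

  make <- function(duration_s, episodes, amp_scale, rec_seed) {
    cfg <- template
    cfg$duration_s <- duration_s
    cfg$episodes <- episodes
    cfg$amp_scale <- amp_scale
    cfg$seed <- rec_seed
    generate_record(cfg)
  }
  calib_onset <- round(calib_duration_s * 2 / 3)
  calib_ep <- data.frame(
    preictal_start_s = calib_onset - min(300, calib_onset / 2),
    onset_s = calib_onset,
    end_s = calib_onset + min(120, calib_duration_s / 6,
                              calib_duration_s - calib_onset - 60))
  lapply(seq_len(n_patients), function(p) {
    calib <- make(calib_duration_s, calib_ep, amp_scales[p],
                  rec_seeds[p, 1L])
    calib$patient_id <- sprintf("synth%02d", p)
    calib$record_id <- sprintf("synth%02d_00", p)
    evals <- lapply(seq_len(n_eval_records), function(k) {
      ep <- data.frame(preictal_start_s = onset - leads[p, k],
                       onset_s = onset, end_s = onset + durs[p, k])
      r <- make(eval_duration_s, ep, amp_scales[p], rec_seeds[p, k + 1L])
      r$patient_id <- sprintf("synth%02d", p)
      r$record_id <- sprintf("synth%02d_%02d", p, k)
      r
    })
    list(patient_id = sprintf("synth%02d", p), amp_scale = amp_scales[p],
         calib = calib, evals = evals)
  })
}

# wrap angles to (-pi, pi]
wrap_to_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Phase-slip rate between working and reference channels
#'
#' Band-pass filters and Hilbert-decomposes the working and reference
#' channels, unwraps their phase difference, and counts full 2 pi windings
#' per minute. Locked oscillator pairs show near-zero slip rates; stronger
#' noise or absent coupling raises the rate.
#'
#' @param record an [eeg_record()] (>= 60 s).
#' @param band a [band_spec()].
#' @param config a [run_config()].
#' @return slips per minute.
#' @export
phase_slip_rate <- function(record, band, config = run_config()) {
  if (record_duration(record) < 60) {
    stop("phase_slip_rate: need at least 60 s of data", call. = FALSE)
  }
  channels <- select_channels(record,
                              blocklist = config$artifact_channel_blocklist,
                              auto_artifact = config$auto_artifact)
  sub <- subset_channels(record, c(channels$working, channels$reference))
  sub <- bandpass_filter(sub, band, numtaps = config$numtaps)
  aw <- hilbert_decompose(sub$data[1L, ], edge_guard = config$numtaps)
  ar <- hilbert_decompose(sub$data[2L, ], edge_guard = config$numtaps)
  v <- c(max(aw$valid[1], ar$valid[1]), min(aw$valid[2], ar$valid[2]))
  d <- (aw$ap - ar$ap)[v[1]:v[2]]
  u <- cumsum(c(d[1L], wrap_to_pi(diff(d))))        # unwrapped difference
  # hysteresis counting: a slip is a full 2 pi advance from the last slip
  # level, so jitter around a winding boundary is not counted repeatedly
  level <- u[1L]
  slips <- 0L
  for (x in u) {
    while (x - level >= 2 * pi) { level <- level + 2 * pi; slips <- slips + 1L }
    while (level - x >= 2 * pi) { level <- level - 2 * pi; slips <- slips + 1L }
  }
  slips / (length(d) / record$fs / 60)
}

#' Write a synthetic cohort as EDF plus summary files
#'
#' Serializes every record of a cohort through the real I/O path: one EDF
#' file per record and one CHB-MIT-style summary text file per patient
#' declaring the seizure times.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return character vector of summary file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- vapply(cohort, function(pat) {
    lines <- character(0)
    for (rec in c(list(pat$calib), pat$evals)) {
      write_edf(rec, file.path(dir, paste0(rec$record_id, ".edf")))
      lines <- c(lines,
                 sprintf("File Name: %s.edf", rec$record_id),
                 sprintf("Number of Seizures in File: %d",
                         length(rec$annotations)))
      for (k in seq_along(rec$annotations)) {
        a <- rec$annotations[[k]]
        lines <- c(lines,
                   sprintf("Seizure %d Start Time: %d seconds",
                           k, as.integer(round(a$onset_s))),
                   sprintf("Seizure %d End Time: %d seconds",
                           k, as.integer(round(a$end_s))))
      }
      lines <- c(lines, "")
    }
    path <- file.path(dir, paste0(pat$patient_id, "-summary.txt"))
    writeLines(lines, path)
    path
  }, character(1))
  invisible(summaries)
}

#' Load a patient from EDF files and a summary file
#'
#' Reads each EDF and attaches the seizure annotations declared for its
#' record id in the summary file. The first record (sorted by record id) is
#' treated as the calibration record, the rest as evaluation records.
#'
#' @param edf_paths paths to the patient's EDF files.
#' @param summary_path path to the seizure summary text file.
#' @param patient_id patient identifier; default from the summary file name.
#' @return a patient list as produced by [generate_cohort()].
#' @export
load_patient <- function(edf_paths, summary_path, patient_id = NULL) {
  anns <- parse_summary(summary_path)
  if (is.null(patient_id)) {
    patient_id <- sub("-summary\\.txt$", "", basename(summary_path))
  }
  edf_paths <- sort(edf_paths)
  recs <- lapply(edf_paths, function(p) {
    r <- read_edf(p)
    r$patient_id <- patient_id
    if (r$record_id %in% names(anns)) r$annotations <- anns[[r$record_id]]
    r
  })
  list(patient_id = patient_id, amp_scale = NA_real_,
       calib = recs[[1L]], evals = recs[-1L])
}
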