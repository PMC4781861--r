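# Shared fixture builders. Everything is generated in code at test time.

# short synthetic record with one planted episode (burst 240-360, ictal
# 420-480 by default), cheap enough for per-test generation
small_episode_record <- function(seed = 101, duration_s = 600,
                                 preictal_start_s = 240, onset_s = 420,
                                 end_s = 480, coupling = 1, ...) {
  generate_record(synth_config(
    duration_s = duration_s,
    episodes = data.frame(preictal_start_s = preictal_start_s,
                          onset_s = onset_s, end_s = end_s),
    coupling = coupling, seed = seed, ...))
}

# pure-background record (no episodes)
noise_record <- function(seed = 202, duration_s = 600, ...) {
  generate_record(synth_config(duration_s = duration_s, seed = seed, ...))
}

# small numeric record for I/O tests: whole-second duration so EDF
# round-trips losslessly up to quantization
random_io_record <- function(seed, n_channels = 2, duration_s = 4,
                             fs = 256, amp = 200) {
  set.seed(seed)
  data <- matrix(stats::runif(n_channels * duration_s * fs, -amp, amp),
                 nrow = n_channels)
  eeg_record(data, fs = fs,
             channel_labels = sprintf("C%02d", seq_len(n_channels)),
             patient_id = "iotest", record_id = sprintf("rio%d", seed))
}

# naive per-window lock-value loop: the independent oracle for the
# cumsum-based sliding implementation
naive_lock <- function(d, window_n, stride) {
  starts <- seq.int(1L, length(d) - window_n + 1L, by = stride)
  vapply(starts, function(s) {
    Mod(mean(exp(1i * d[s:(s + window_n - 1L)])))
  }, numeric(1))
}

# brute-force SPH classifier: independently re-implements the earliest-first
# one-to-one matching convention over all marker x seizure pairs
brute_classify <- function(p_times, onsets, sph_window_s) {
  p_times <- sort(p_times)
  onsets <- sort(onsets)
  used <- rep(FALSE, length(onsets))
  tp <- 0L; fp <- 0L; red <- 0L
  leads <- numeric(0)
  for (t in p_times) {
    cand <- which(onsets > t & onsets - t <= sph_window_s)
    if (length(cand) == 0L) { fp <- fp + 1L; next }
    open <- cand[!used[cand]]
    if (length(open) == 0L) { red <- red + 1L; next }
    used[min(open)] <- TRUE
    tp <- tp + 1L
    leads <- c(leads, onsets[min(open)] - t)
  }
  list(tp = tp, fp = fp, fn = sum(!used), redundant = red,
       sph_list_s = leads)
}

# build an aligned PLV/ALV lock-series pair directly from value vectors on a
# 1-second window grid (window_n = fs, stride = fs)
lock_pair <- function(plv_values, alv_values, fs = 256) {
  n <- length(plv_values)
  starts <- seq.int(1L, by = fs, length.out = n)
  list(
    plv = plavdet:::lock_series("PLV", plv_values, starts, fs, fs, fs),
    alv = plavdet:::lock_series("ALV", alv_values, starts, fs, fs, fs)
  )
}
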