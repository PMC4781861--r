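# Coupled-oscillator EEG generator: determinism, planted-episode contrast,
# coupling monotonicity, phase slips, cohort structure, I/O path.

test_that("records are bit-identical given the seed, schedule held fixed", {
  sc <- synth_config(duration_s = 120,
                     episodes = data.frame(preictal_start_s = 30,
                                           onset_s = 70, end_s = 90),
                     seed = 5)
  r1 <- generate_record(sc)
  r2 <- generate_record(sc)
  expect_identical(r1$data, r2$data)

  sc2 <- sc; sc2$seed <- 6L
  r3 <- generate_record(sc2)
  expect_false(identical(r1$data, r3$data))   # new noise realization
  expect_equal(attr(r3, "episodes"), attr(r1, "episodes"))  # same schedule
})

test_that("episode layouts are validated", {
  expect_error(synth_config(duration_s = 100,
                            episodes = data.frame(preictal_start_s = 50,
                                                  onset_s = 40, end_s = 60)),
               "preictal_start < onset")
  expect_error(synth_config(duration_s = 100,
                            episodes = data.frame(
                              preictal_start_s = c(10, 30),
                              onset_s = c(40, 60), end_s = c(50, 70))),
               "overlap")
  expect_error(synth_config(duration_s = 100, n_channels = 1), ">= 2")
  expect_error(synth_config(duration_s = 100, coupling = 1.5), "coupling")
})

test_that("strong coupling elevates episode PLV far above background", {
  rec <- small_episode_record(seed = 15, noise_sd = 5)
  lp <- lock_pipeline(rec, default_bands()$gamma, run_config())
  tc <- lp$plv$t_centers_s
  seiz <- tc >= 425 & tc <= 475
  bg <- tc < 230 | tc > 490
  expect_gt(min(lp$plv$values[seiz]), 0.9)
  expect_lt(median(lp$plv$values[bg]), 0.3)
})

test_that("uncoupled episodes look like background synchrony", {
  rec0 <- small_episode_record(seed = 16, coupling = 0)
  null_rec <- noise_record(seed = 17)
  cfg <- run_config()
  lp0 <- lock_pipeline(rec0, default_bands()$gamma, cfg)
  lpn <- lock_pipeline(null_rec, default_bands()$gamma, cfg)
  tc <- lp0$plv$t_centers_s
  ep <- (tc >= 240 & tc <= 415) | (tc >= 420 & tc <= 480)
  # the episode windows are statistically indistinguishable from a matched
  # pure-noise run: their upper quantile stays below its extreme tail
  expect_lt(quantile(lp0$plv$values[ep], 0.95),
            quantile(lpn$plv$values, 0.999))
  expect_lt(abs(median(lp0$plv$values[ep]) - median(lpn$plv$values)), 0.05)
})

test_that("episode PLV grows monotonically with coupling strength", {
  cfg <- run_config()
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(k) {
    rec <- small_episode_record(seed = 18, coupling = k)
    lp <- lock_pipeline(rec, default_bands()$gamma, cfg)
    tc <- lp$plv$t_centers_s
    mean(lp$plv$values[(tc >= 245 & tc <= 385) | (tc >= 425 & tc <= 475)])
  }, numeric(1))
  # nondecreasing up to sampling noise once the lock saturates
  expect_true(all(diff(means) >= -0.005))
  expect_gt(means[5], means[1] + 0.5)
})

test_that("phase slips vanish under lock and persist without coupling", {
  band <- default_bands()$gamma
  cfg <- run_config()
  # ictal coupling spanning essentially the whole record: locked pair
  locked <- generate_record(synth_config(
    duration_s = 120,
    episodes = data.frame(preictal_start_s = 0.5, onset_s = 1.1,
                          end_s = 119.9),
    phase_noise_sd = 0.001, seed = 19))
  expect_lt(phase_slip_rate(locked, band, cfg), 0.5)

  free <- noise_record(seed = 20, duration_s = 120)
  expect_gt(phase_slip_rate(free, band, cfg), 1)

  # near the Adler threshold, stronger phase noise means more slips
  marginal <- function(noise_sd) {
    r <- generate_record(synth_config(
      duration_s = 300,
      episodes = data.frame(preictal_start_s = 0.5, onset_s = 1.1,
                            end_s = 299.9),
      coupling = 0.02, phase_noise_sd = noise_sd, seed = 21))
    phase_slip_rate(r, band, cfg)
  }
  expect_gte(marginal(0.1), marginal(0.05))
  expect_error(phase_slip_rate(noise_record(seed = 22, duration_s = 30),
                               band, cfg), "60 s")
})

test_that("cohorts carry the documented structure and exercise SD scaling", {
  cohort <- generate_cohort(3, synth_config(duration_s = 1200),
                            seed = 9, calib_duration_s = 900,
                            eval_duration_s = 1200, n_eval_records = 2)
  expect_length(cohort, 3)
  n_seiz <- sum(vapply(cohort, function(p) {
    sum(lengths(lapply(p$evals, `[[`, "annotations")))
  }, numeric(1)))
  expect_equal(n_seiz, 3 * 2)                  # one seizure per eval record
  expect_true(all(vapply(cohort, function(p) {
    length(p$calib$annotations) == 1
  }, logical(1))))
  # patient amplitude scales differ and shift S_AA proportionally
  scales <- vapply(cohort, `[[`, numeric(1), "amp_scale")
  expect_gt(diff(range(scales)), 0)
  cfg <- run_config()
  lps <- lapply(cohort, function(p) {
    lock_pipeline(p$calib, default_bands()$gamma, cfg)
  })
  s_aa <- vapply(lps, `[[`, numeric(1), "s_aa")
  expect_equal(s_aa / s_aa[1], scales / scales[1], tolerance = 0.1)

  # regenerating with the same seed reproduces the cohort
  cohort2 <- generate_cohort(3, synth_config(duration_s = 1200),
                             seed = 9, calib_duration_s = 900,
                             eval_duration_s = 1200, n_eval_records = 2)
  expect_identical(cohort[[2]]$evals[[1]]$data, cohort2[[2]]$evals[[1]]$data)
})

test_that("explicit reference SDs rescale thresholds across patients", {
  mk <- function(scale, seed) generate_record(synth_config(
    duration_s = 1200,
    episodes = data.frame(preictal_start_s = 600, onset_s = 850, end_s = 970),
    amp_scale = scale, seed = seed))
  cfg <- run_config(ref_s_aa = 12, ref_s_ap = 1.81)
  t1 <- calibrate_patient(mk(1, 23), cfg)
  t2 <- calibrate_patient(mk(2, 23), cfg)
  expect_equal(t2$s_aa / t1$s_aa, 2, tolerance = 0.1)
  expect_false(isTRUE(all.equal(t1$alv_threshold, t2$alv_threshold)))
})

test_that("the cohort writes and reloads through EDF + summary files", {
  cohort <- generate_cohort(1, synth_config(duration_s = 600),
                            seed = 13, calib_duration_s = 600,
                            eval_duration_s = 600, n_eval_records = 1)
  dir <- tempfile("cohortio")
  paths <- write_cohort(cohort, dir)
  expect_true(file.exists(paths[1]))
  edfs <- list.files(dir, pattern = "\\.edf$", full.names = TRUE)
  expect_length(edfs, 2)
  pat <- load_patient(edfs, paths[1])
  expect_equal(pat$patient_id, "synth01")
  expect_length(pat$evals, 1)
  expect_length(pat$evals[[1]]$annotations, 1)
  orig <- cohort[[1]]$evals[[1]]
  expect_equal(pat$evals[[1]]$annotations[[1]]$onset_s,
               round(orig$annotations[[1]]$onset_s))
  expect_lt(max(abs(pat$evals[[1]]$data - orig$data)), 0.05 + 1e-9)
  unlink(dir, recursive = TRUE)
})
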