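# Marker extraction, SPH/SOP classification, metric aggregation.

thr <- threshold_set(0.83, 0.8, s_aa = 10, s_ap = 1.8)

test_that("marker states follow the PLV/ALV threshold rules", {
  # windows are 1 s apart (window_n = stride = fs); baseline 0.1
  plv <- rep(0.1, 60); alv <- rep(0.1, 60)
  plv[21:25] <- 0.9                           # PLV alone -> P
  plv[41:46] <- 0.9; alv[41:46] <- 0.95       # both -> S
  lp <- lock_pair(plv, alv)
  m <- detect_markers(lp$plv, lp$alv, thr, min_duration_s = 2)
  expect_equal(m$kind, c("P", "S"))
  expect_equal(m$t_s, lp$plv$t_centers_s[c(21, 41)])
})

test_that("single isolated windows are debounced away", {
  plv <- rep(0.1, 30); plv[10] <- 0.9
  lp <- lock_pair(plv, rep(0.1, 30))
  # one 1-s window spans window_n/fs = 1 s < min_duration_s = 2
  m <- detect_markers(lp$plv, lp$alv, thr, min_duration_s = 2)
  expect_equal(nrow(m), 0)
})

test_that("an S run absorbs adjacent contiguous P runs", {
  plv <- rep(0.1, 40); alv <- rep(0.1, 40)
  plv[10:20] <- 0.9                           # buildup
  alv[15:18] <- 0.9                           # amplitude lock in the middle
  lp <- lock_pair(plv, alv)
  m <- detect_markers(lp$plv, lp$alv, thr, min_duration_s = 2)
  expect_equal(m$kind, "S")
  expect_equal(m$t_s, lp$plv$t_centers_s[10])  # onset is the buildup start
  expect_equal(m$duration_s, 11)
})

test_that("mismatched window grids are rejected", {
  lp <- lock_pair(rep(0.1, 20), rep(0.1, 20))
  short <- lock_pair(rep(0.1, 19), rep(0.1, 19))
  expect_error(detect_markers(lp$plv, short$alv, thr), "identical window")
})

test_that("SPH classification matches the worked cases", {
  mk <- function(t) data.frame(kind = rep("P", length(t)), t_s = t,
                               duration_s = rep(10, length(t)))
  ann <- list(seizure_annotation(3600, 3660))

  r <- classify_events(mk(2400), ann, 3600)
  expect_equal(r$tp, 1)
  expect_equal(r$sph_list_s, 1200)            # 20 min lead

  r2 <- classify_events(mk(100), list(), 3600)
  expect_equal(r2$fp, 1)

  r3 <- classify_events(mk(numeric(0)), ann, 3600)
  expect_equal(r3$fn, 1)

  # halving the horizon turns a 2100 s lead into a false positive
  ann2 <- list(seizure_annotation(4500, 4560))
  r4 <- classify_events(mk(2400), ann2, 1800)
  expect_equal(c(r4$tp, r4$fp, r4$fn), c(0, 1, 1))
  r5 <- classify_events(mk(2400), ann2, 3600)
  expect_equal(c(r5$tp, r5$fp, r5$fn), c(1, 0, 0))
})

test_that("classification equals the brute-force matcher on random sets", {
  set.seed(71)
  for (rep in 1:25) {
    n_m <- sample(0:8, 1)
    n_s <- sample(0:4, 1)
    p_times <- sort(runif(n_m, 0, 20000))
    onsets <- sort(runif(n_s, 0, 20000))
    window <- sample(c(900, 1800, 3600), 1)
    markers <- data.frame(kind = rep("P", n_m), t_s = p_times,
                          duration_s = rep(5, n_m))
    anns <- lapply(onsets, function(o) seizure_annotation(o, o + 30))
    mine <- classify_events(markers, anns, window)
    ref <- brute_classify(p_times, onsets, window)
    expect_equal(mine[c("tp", "fp", "fn", "redundant")],
                 ref[c("tp", "fp", "fn", "redundant")])
    expect_equal(sort(mine$sph_list_s), sort(ref$sph_list_s))
    # tp + fn always equals the number of annotated seizures
    expect_equal(mine$tp + mine$fn, n_s)
  }
})

test_that("shrinking the SPH window never increases true positives", {
  set.seed(72)
  for (rep in 1:10) {
    p_times <- sort(runif(6, 0, 20000))
    onsets <- sort(runif(3, 0, 20000))
    markers <- data.frame(kind = "P", t_s = p_times, duration_s = 5)
    anns <- lapply(onsets, function(o) seizure_annotation(o, o + 30))
    tps <- vapply(c(7200, 3600, 1800, 900), function(w) {
      classify_events(markers, anns, w)$tp
    }, numeric(1))
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("pooled integer percents truncate toward zero", {
  expect_equal(pooled_pct(24, 31), 77)        # 77.4 -> 77
  expect_equal(pooled_pct(20, 31), 64)        # 64.5 -> 64
  expect_equal(pooled_pct(0, 0), NA_real_)
  res <- compute_metrics(data.frame(patient = "pool", tp = 24, fp = 3,
                                    fn = 7, interictal_hours = 31))
  expect_equal(res$pooled$sensitivity_int, 77)
})

test_that("macro averaging of per-patient rates rounds to the printed totals", {
  sens <- c(67, 33, 100, 67, 67, 67, 100, 67, 100, 100)
  tp <- round(3 * sens / 100)
  df <- data.frame(patient = sprintf("p%02d", 1:10), tp = tp, fp = 0,
                   fn = 3 - tp, interictal_hours = 3)
  res <- compute_metrics(df)
  expect_equal(round(res$macro$sensitivity_pct, 1), 76.7)
  expect_equal(res$macro$sensitivity_int, 77)
})

test_that("undefined rates are flagged and excluded from macro means", {
  res <- compute_metrics(data.frame(
    patient = c("a", "b"), tp = c(0, 2), fp = c(0, 0), fn = c(0, 1),
    interictal_hours = c(0, 3)))
  expect_true(is.na(res$patients$sensitivity_pct[1]))
  expect_true(is.na(res$patients$precision_pct[1]))
  expect_true(is.na(res$patients$fp_per_h[1]))
  expect_equal(res$macro$sensitivity_pct, 66.67, tolerance = 0.01)
})

test_that("fp_pct covers the interictal fraction spanned by false SPH windows", {
  res <- compute_metrics(data.frame(patient = "x", tp = 0, fp = 2, fn = 1,
                                    interictal_hours = 3),
                         sph_window_s = 3600)
  expect_equal(res$patients$fp_pct, round(100 * 2 / 3, 2))
  res2 <- compute_metrics(data.frame(patient = "x", tp = 0, fp = 9, fn = 1,
                                     interictal_hours = 3))
  expect_equal(res2$patients$fp_pct, 100)     # capped
})

test_that("cohort evaluation and sweeps are deterministic given the records", {
  cohort <- list(list(
    patient_id = "t01",
    calib = small_episode_record(seed = 81, duration_s = 1200,
                                 preictal_start_s = 600, onset_s = 850,
                                 end_s = 970),
    evals = list(small_episode_record(seed = 82, duration_s = 1500,
                                      preictal_start_s = 600, onset_s = 1200,
                                      end_s = 1260))
  ))
  cfg <- run_config()
  r1 <- evaluate_cohort(cohort, cfg)
  r2 <- evaluate_cohort(cohort, cfg)
  expect_equal(r1$patients, r2$patients)
  expect_equal(r1$patients$tp + r1$patients$fn, 1)

  sw1 <- sweep_bands(cohort, cfg, bands = default_bands()["gamma"])
  sw2 <- sweep_bands(cohort, cfg, bands = default_bands()["gamma"])
  expect_equal(as.data.frame(sw1), as.data.frame(sw2))
  expect_equal(nrow(sw1), 1)
})
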