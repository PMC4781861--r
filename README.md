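# plavdet — seizure prediction and detection from phase/amplitude lock values

`plavdet` is an R toolkit for patient-specific seizure prediction and
detection on scalp EEG. Ahead of a focal seizure, the rhythms of the
epileptogenic zone progressively entrain with remote cortical activity;
`plavdet` measures that entrainment between a *working* electrode (highest
signal SD, nearest the focus) and a *reference* electrode (lowest SD,
remote from it) with two sliding-window statistics over the Hilbert
analytic signal:

```
PLV = | (1/n) Σ_t exp(i [φ1(t) − φ2(t)]) |      (analytic phase)
ALV = | (1/n) Σ_t exp(i [a1(t) − a2(t)]) |      (analytic amplitude)
```

Both lie in [0, 1]: 1 for perfect locking (any constant lag), ≈(√π/2)/√n
for independence. PLV alone crossing a patient-specific threshold is a
**prediction marker (P)**; PLV and ALV crossing together is a **seizure
marker (S)**. Prediction markers are scored under the SPH/SOP framework
(true positive if a seizure onset follows within the seizure prediction
horizon, default 1 h), and per-patient significance is assessed against a
Poisson chance predictor with an exact two-sided binomial test.

The pipeline: Remez (equiripple) band-pass filtering in five standard EEG
bands with zero-phase application → Hilbert analytic amplitude/phase →
sliding-window PLV/ALV → histogram-based threshold calibration (valley
"elbow" rule with 95th-percentile fallback, SD-based cross-patient
scaling, artifact-acceptance checks) → marker extraction → SPH/SOP
classification → aggregation and chance statistics. A coupled
noisy-oscillator EEG simulator with ground-truth annotations makes the
whole pipeline testable end-to-end without patient data; EDF and
CHB-MIT-style seizure-summary I/O connect it to real recordings.

## Worked example

Simulate one patient — a calibration record and an evaluation record with
a seizure at 1200 s preceded by phase entrainment from 600 s — then
calibrate, detect, and classify:

```r
library(plavdet)

calib <- generate_record(synth_config(
  duration_s = 1200,
  episodes = data.frame(preictal_start_s = 600, onset_s = 850, end_s = 970),
  seed = 61))
eval_rec <- generate_record(synth_config(
  duration_s = 1500,
  episodes = data.frame(preictal_start_s = 600, onset_s = 1200, end_s = 1260),
  seed = 62))

cfg <- run_config()                    # gamma band, window_n = 1000, 1 h SPH
thr <- calibrate_patient(calib, cfg)
thr
#> <threshold_set> PLV 0.930 (elbow), ALV 0.961 (percentile95); S_AA=18.75 uV, S_AP=1.814 rad

lp <- lock_pipeline(eval_rec, default_bands()$gamma, cfg)
markers <- detect_markers(lp$plv, lp$alv, thr, cfg$min_duration_s)
markers
#>   kind       t_s duration_s
#> 1    P  601.5625  180.66406
#> 2    S 1202.1484   15.62500
#> 3    S 1209.9609   34.17969
#> 4    S 1237.3047   14.64844
#> 5    S 1243.1641   18.55469

classify_events(markers, eval_rec$annotations, cfg$sph_window_s)[c("tp", "fp", "fn")]
#> $tp
#> [1] 1
#> $fp
#> [1] 0
#> $fn
#> [1] 0
```

The PLV threshold (0.930) comes from the histogram elbow; the ALV series
had no separated high mode on this calibration record, so its threshold
fell back to the 95th percentile. The P marker fires at the start of the
planted preictal entrainment (602 s, a ~10 min lead on the 1200 s onset —
a true positive under the 1 h horizon) and the S markers bracket the
seizure itself, fragmented where the ALV flickers around its threshold. On a full
synthetic cohort (10 patients, 30 planted seizures, >3 h interictal each):

```r
cohort <- generate_cohort(10, synth_config(duration_s = 4200, coupling = 1), seed = 1)
res <- evaluate_cohort(cohort, run_config())
res
#> <eval_result> 10 patient(s): pooled TP=29 FP=1 FN=1 | macro sens 96.7%, prec 96.7%, 0.03 FP/h
```

(The one miss is a planted lead above 60 min — outside the SPH window by
construction.) `sweep_bands(cohort, run_config())` repeats the evaluation
across all five bands; with coupling planted at 35 Hz the gamma band ranks
first by F1 while the no-signal bands degenerate to alarm spam.

A thin command-line wrapper for simulation and evaluation lives at
`inst/cli/plavdet.R`:

```sh
Rscript inst/cli/plavdet.R simulate --patients 2 --seed 1 --out simdir
Rscript inst/cli/plavdet.R evaluate --edf 'simdir/synth01_*.edf' \
    --summary simdir/synth01-summary.txt --out results
```

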