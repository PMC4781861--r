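---
title: "Phase and amplitude lock values for patient-specific seizure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase and amplitude lock values for patient-specific seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Focal seizures are preceded, minutes to an hour in advance, by a progressive
entrainment of the epileptogenic zone's rhythms with remote cortical
activity. `plavdet` quantifies that entrainment on scalp EEG with two
sliding-window statistics between a *working* electrode (highest signal SD,
closest to the seizure focus) and a *reference* electrode (lowest SD, remote
from it).

Each channel is band-pass filtered and decomposed by the Hilbert transform
into an analytic amplitude $A(t)$ and analytic phase $\phi(t)$. Over a
window of $n$ samples the **phase lock value** and **amplitude lock value**
are

$$
\mathrm{PLV} = \Bigl\lVert \frac1n \sum_{t} e^{\,i[\phi_1(t)-\phi_2(t)]} \Bigr\rVert,
\qquad
\mathrm{ALV} = \Bigl\lVert \frac1n \sum_{t} e^{\,i[a_1(t)-a_2(t)]} \Bigr\rVert,
$$

where $a$ is the analytic amplitude (optionally rescaled, see below). Both
lie in $[0, 1]$: 1 for identical series *or any constant lag* (the
difference enters a complex exponential), and about
$\tfrac{\sqrt\pi}{2}/\sqrt{n}$ for independent inputs. A window of
supra-threshold PLV with sub-threshold ALV is a **prediction marker (P)**:
phases entrain before seizure onset while amplitudes stay independent. A
window where both exceed their thresholds is a **seizure marker (S)**:
amplitude entrainment marks the ictal event itself.

Prediction is evaluated under the SPH/SOP framework: a P marker is a true
positive if a seizure onset follows it within the seizure prediction
horizon (default 1 h, with a 30 min variant), a false positive if no onset
follows in that window, and a seizure without a preceding P marker is a
false negative. Markers and seizures are matched one-to-one, earliest
first; a marker whose window contains only an already-claimed onset is
counted separately as *redundant* (it forewarned a real seizure and is
neither TP nor FP). That last convention is ours: the one-to-one rule and
the FP definition leave such markers otherwise unclassified.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `window_n` | 1000 samples | lock-value window (~3.9 s at 256 Hz); 2500 and 5000 are the standard alternatives |
| `stride` | `window_n/4` | window stride; overlap smooths the series at modest cost (the window grid is not prescribed by the framework, so it is config-exposed) |
| `sph_window_s` | 3600 s | SPH + SOP horizon (1800 s variant) |
| `numtaps` | 257 | FIR length, ~1 s at 256 Hz |
| `min_duration_s` | 2 s | marker debounce: interictal excursions of 1-2 s should not alarm |
| `bin_width` | 0.01 | histogram granularity for calibration, matching the precision at which thresholds are usually quoted |
| `threshold_method` | `"elbow"` | valley rule with automatic percentile fallback |

## Filtering and decomposition

Band-pass filtering uses an equiripple (Parks-McClellan / Remez) linear-phase
FIR in the five standard bands: delta-theta-alpha (1-12 Hz), alpha
(6-12 Hz), beta (13-30 Hz), gamma (30-40 Hz), upper-gamma (40-50 Hz).
Application is zero-phase (forward-backward, implemented as
frequency-domain multiplication by $|H(\omega)|^2$ and verified against
`signal::filtfilt`), so marker timing carries no group delay.

Numerical choices worth knowing:

* **Transition widths are 4 Hz**, shrinking to 80% of the available gap for
  edges near DC or Nyquist, and capped at 2 Hz on both edges when one edge
  is that tight (strongly unequal transitions destabilize the exchange
  algorithm in this `remez` port). At 257 taps a 4 Hz transition leaves
  roughly $10^{-4}$ passband ripple. This matters beyond aesthetics: with
  ~1% ripple, a carrier sitting a quarter ripple-cycle off an extremum sees
  asymmetric gain on its AM sidebands, which converts amplitude modulation
  into phase jitter and measurably destroys PLV between two
  amplitude-modulated channels.
* The 1 Hz lower edge of the delta-theta-alpha band cannot reach 40 dB
  single-pass attenuation at 257 taps (and this `remez` port diverges for
  the filter lengths that could). The 40 dB stopband figure for that band
  is certified on the *effective* zero-phase response $|H|^2$ — the
  response the pipeline actually applies; the other four bands meet ≤ 1 dB
  ripple / ≥ 40 dB single-pass.
* The analytic signal is computed by the FFT method; `valid_slice` excludes
  one filter length at each edge, and lock-value windows overlapping that
  guard are dropped, not padded.
* An all-zero signal has undefined phase and is rejected rather than
  silently returning garbage.

The ALV as written places raw microvolt amplitude differences inside a
complex exponential, where they wrap modulo $2\pi$. Both modes are
provided: the literal form (`alv_normalize = FALSE`) and the recommended
form in which each amplitude series is divided by its interictal SD
(`alv_normalize = TRUE`, the default), putting the differences on a
radian-like scale for every patient. The SD-normalized mode is what the
cross-patient scaling quantities $S_{AA_j}$ naturally motivate.

## Threshold calibration

Calibration runs the pipeline on one record per patient held out from
evaluation, histograms the lock values in 0.01-wide bins on $[0,1]$, and
places each threshold at the **valley** between the low-synchrony bulk and
the high-synchrony cluster: the left edge of the minimum-count bin just
before the counts rise into the cluster. Modes are local maxima of the
3-bin-smoothed counts; the high mode must hold at least `min_mode_frac`
(default 0.5%) of all values and be separated from the bulk by a dip below
a quarter of the smaller mode — otherwise the histogram is treated as
unimodal and the threshold falls back to the **95th percentile** of the
distribution (linear interpolation between order statistics). The elbow
rule is tried first, the percentile is the documented fallback; when
several valley bins tie at the minimum count, the bin adjacent to the rise
(the highest-synchrony tied bin) wins, which is what placing the threshold
"just before the counts rise" means — a low-edge tie rule would park the
threshold against the noise bulk whenever the valley is wide and empty.

Cross-patient compensation measures the interictal analytic-amplitude and
analytic-phase SDs ($S_{AA_j}$, $S_{AP_j}$) of the working channel.
Segments violating the artifact-acceptance inequalities
$S_{AA_j} < SA_{threshold}$, $S_{AP_j} < SP_{threshold}$ (defaults 80 uV
and 2.2 rad, chosen as generous upper bounds over the synthetic cohort's
clean records; both config values) are rejected as artifact-contaminated.
When cohort reference SDs are configured, thresholds transfer as
$\theta' = \min(1, \theta \cdot S_{ref}/S_{patient})$ — PLV scaled by the
phase-SD ratio, ALV by the amplitude-SD ratio. By default
`calibrate_patient` does *not* rescale: its threshold is already derived
from the patient's own record, and scaling it by a cohort ratio would
detune a correctly placed threshold. The scaling path is for transferring
a base threshold set to a patient calibrated elsewhere.

## Marker extraction details

Windows are classified P/S/none per the threshold rules; contiguous
same-state windows form runs; runs shorter than `min_duration_s` are
debounced away. An S run absorbs contiguous P runs on *both* sides: the
preceding buildup becomes the S event's onset, and a trailing P run —
produced by windows straddling the end of the amplitude-locked interval —
is folded in rather than emitted as a fresh "prediction" seconds after the
seizure it trails.

## Chance predictor and significance

The null model is a Poisson alarm process spending proportion $\rho_w$ of
its time in warning: $\lambda_w = -\ln(1-\rho_w)/\tau_w$ (the published
form carries a stray sign; rates are nonnegative) and

$$S_{nc} = 1 - \exp\left(-\lambda_w \tau_w + (1 - e^{-\lambda_w \tau_{w0}})\right),$$

clamped to $[0,1]$, with $\tau_{w0}$ the detection interval (default 0 —
pure prediction; its value is a free parameter of the framework) and
$\tau_w$ the SPH + SOP horizon. The small-rate limit
$1 - e^{-\lambda_w(\tau_w - \tau_{w0})}$ is available via
`snc_form = "limit"`; the two agree at $\tau_{w0} = 0$, where the printed
form is exactly the probability that a Poisson process fires in the
$\tau_w$ window before a seizure — which is what the simulation check
verifies.

$\rho_w$ is estimated from the algorithm's own output as total P-marker
active duration over total evaluated time. The alternative — counting the
whole SPH window after each alarm as warning time — drives $\rho_w$
toward 1 for any sensitive predictor on multi-hour records and makes even
perfect patients "not better than chance"; the marker-duration convention
reproduces the order of magnitude of published per-patient p-values. Its
known blind spot: a predictor that alarms briefly but very often keeps a
small $\rho_w$ while the 1 h horizon catches seizures by accident, so its
p-values stay small even though it is useless; rank such predictors by
precision/F1, not by their p-values.

Per patient, the two-sided exact binomial p-value compares $n$ of $N$
seizures identified against $S_{nc}$ via the two-branch closed form with
reflection points $k_f = \lfloor 2NS_{nc} - n \rfloor$,
$k_c = \lceil 2NS_{nc} - n \rceil$ (equal to direct tail enumeration;
verified exhaustively for $N \le 12$), clamped to $[0,1]$ at zero
deviation where the two tails overlap. Cohort-level significance uses the
exact sign test on the per-patient differences $S_n - S_{nc}$ (the cited
nonparametric framework does not name the test; the sign test is the
assumption-free choice, with Wilcoxon signed-rank as an option).

## The synthetic cohort: what it emulates, and what it does not

The generator realizes the coupled-noisy-oscillator picture of
entrainment as a discrete-time phase-oscillator pair:

* working and reference channels carry oscillators at a shared base
  frequency (35 Hz, inside gamma) with a small natural detuning
  (0.5 Hz) and per-sample phase-increment noise. Uncoupled, the phase
  difference drifts and windowed PLV sits at noise level; during episodes
  the working increment gains $\kappa \sin(\phi_{ref} - \phi_{work})$,
  which locks the pair (Adler threshold $\kappa > 2\pi \cdot 0.5/f_s$)
  at a constant small lag. Phase slips — full $2\pi$ windings of the
  unwrapped difference — vanish under strong coupling and return with
  noise, and `phase_slip_rate()` counts them.
* amplitudes are independent, slowly varying Gaussian-smoothed envelopes
  (the Gaussian kernel is essentially band-limited, so its AM sidebands
  survive the band-pass intact — a boxcar envelope's sinc sidelobes get
  truncated into spurious phase jitter); during ictal intervals only, the
  working envelope is blended toward the scale-matched reference envelope
  by $\kappa$, raising the ALV.
* each episode couples phases for a bounded preictal burst (default
  180 s) starting at the planted preictal time, then releases until
  onset. A continuous preictal-through-ictal lock would fuse the P run
  into the S run and erase the prediction marker under the absorption
  rule; the bounded burst realizes the described preictal rise /
  reconstitution / ictal rise sequence.
* the default cohort: 10 patients, one 1800 s calibration record with one
  planted episode, three 4200 s evaluation records with one seizure each
  (onset fixed at 3900 s; preictal leads uniform over 2-62 min, the
  published SPH range, truncated only when a record is too short; seizure
  durations 30-90 s), patient amplitude scales drawn from [0.6, 1.8].
  Leads above 60 min are *expected* to fall outside the 1 h SPH window
  and score as misses, exactly as a real 62 min lead would.

Problem sizes were chosen so the full cohort (about 36 h of 3-channel EEG)
generates and evaluates in minutes on one core; they are the package's
validation conditions, not a limit of the method.

What passing these tests shows: the pipeline recovers planted phase/
amplitude entrainment, calibrates patient-specific thresholds without
supervision, and respects the SPH bookkeeping. What it does not show: real
EEG has 1/f background, muscle and electrode artifacts, non-stationary
band power, and seizures whose coupling is neither stationary nor confined
to one narrow band. Background channels here are white Gaussian noise;
the artifact-channel blocklist is exercised by a simple amplitude-spike
injector, not by real artifact morphology. Results on the synthetic cohort
therefore bound the method's bookkeeping and signal-processing
correctness, not its clinical performance.

## Reporting conventions

Integer percents follow the conventions of the published results table:
pooled count ratios truncate toward zero (24/31 -> 77%, 20/31 -> 64%),
macro averages of per-patient rates round to the nearest percent
(76.7 -> 77%). Both 2-decimal and integer values are always emitted.
`fp_pct` — the share of interictal time covered by false SPH windows — is
$100 \cdot FP \cdot (\tau_w/3600)/\text{interictal hours}$, capped at 100
(no formula is published for it). Band/window sweeps are ranked by F1
(harmonic mean of macro sensitivity and precision) with ties broken by
FP/h then sensitivity: on the synthetic cohort, bands without planted
coupling calibrate to their noise distribution's 95th percentile and alarm
roughly 36 times an hour, which trivially "predicts" every seizure —
sensitivity alone cannot rank bands once alarm spam is on the table.

## Known limitations

* The EDF writer pads partial final seconds with zeros (one-second data
  records); round trips are exact up to the 0.1 uV quantization step only
  for whole-second records.
* Elbow calibration needs the high-synchrony mode to hold at least
  `min_mode_frac` of windows; very short calibration seizures fall back
  to the 95th percentile, which over-alarms when the record is mostly
  noise (by construction 5% of windows exceed it).
* Multi-record patients are processed per record; alarms never span
  record boundaries, and seizures in the first minutes of a record can at
  most be predicted by markers within the same record.
* The chance-predictor p-value is blind to alarm spam (see above).
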