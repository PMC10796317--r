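---
title: "Estimating cardiac output from ballistocardiography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cardiac output from ballistocardiography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcgco)
```

## The problem

Cardiac output (CO, the blood volume pumped per minute, in L/min) is the
quantity an emergency clinician most wants and least often has: invasive
monitors are impractical outside the hospital, and palpating a carotid pulse
is unreliable. Ballistocardiography (BCG) offers a fully non-invasive
alternative: small piezoelectric sensors on the skin over the carotid artery
and the abdominal aorta record the recoil of the body as blood is ejected at
each heartbeat. The ejection of a larger stroke volume produces a stronger
and faster mechanical fluctuation, so the *morphology* of the per-beat BCG
wave carries information about CO.

`bcgco` implements the complete estimation chain from raw multichannel
recordings (ECG, carotid BCG, abdominal BCG at 250 Hz; a reference CO
channel at 0.5 Hz) to a per-window CO estimate and its agreement analysis,
plus a seeded simulator that provides ground truth for every stage.

## The processing model

### Preprocessing

ECG is band-pass filtered at 0.5–30 Hz and the BCG channels at 0.5–3 Hz,
suppressing baseline drift below and noise above the band where the
circulatory fluctuation lives. The filter is a 4th-order Butterworth applied
forward–backward (`signal::filtfilt`), hence zero-phase: a causal filter
would delay the BCG fluctuation relative to the ECG R wave and bias every
duration feature. Because analysis segments are short (tens of seconds),
the input is reflect-padded by one transient length (`3/lo` seconds) before
filtering. The bands are the method's definition; the order and the
zero-phase choice are configuration defaults (`pipeline_config()`), exposed
because the source method names only the bands.

QRS complexes are detected on the filtered ECG with the Hamilton–Tompkins
detector: differentiation, rectification, 80-ms moving-window integration,
adaptive signal/noise thresholds with search-back for missed beats, and a
0.2-s refractory period. Each detection is refined to the largest absolute
ECG deflection near the integrated-signal peak, which compensates the
integration lag.

### Isolating the circulatory component

Each BCG channel mixes the beat-driven circulatory wave with respiration
and broadband noise. The separation exploits the one piece of side
information we have: the QRS instants. A recursive least-squares (RLS)
adaptive filter takes as input the unit impulse train with a 1 at each QRS
instant and as desired signal the preprocessed BCG. Its tap vector is then
exactly the current estimate of the per-beat mechanical response, and the
filter output — the beat-synchronous part of the BCG — is the circulatory
component `CC`. Anything not phase-locked to the beats (the 0.2–0.35 Hz
respiratory baseline, noise) cannot be predicted from the impulse train and
ends up in the residual; the decomposition `cc + residual = input` is exact
by construction. Overlapping responses at short RR intervals superpose
linearly, which the filter represents without truncation.

The tap span deserves care. The natural-looking choice — one full second,
covering a beat at any resting rate — is quietly harmful whenever the RR
interval is shorter than the span: the lag `j` of the current beat is then
always co-excited with lag `j + RR` of the previous one, the exponentially
weighted correlation matrix becomes near-singular along those paired
directions (the forgetting factor erases the little RR diversity that
would break the degeneracy), and the template grows large spurious
excursions at the unidentifiable lags — which downstream beat delineation
happily mistakes for onsets and offsets. The pipeline therefore defaults
to a 0.7-s span (`pipeline_config(rls_taps_s = 0.7)`): long enough for
the mechanical delay, the fluctuation and its band-pass undershoot, short
enough to stay below the shortest resting RR so each tap lag is refreshed
exactly once per beat and the estimate stays well-conditioned. The
generic `rls_params()` default remains a 1-s span for use with slow
rhythms; both are exposed.

The forgetting factor `lambda = 0.999` lets the template drift
beat-to-beat (time constant of roughly 1000 samples, i.e. ~4 s at 250 Hz);
`lambda = 1` recovers the growing-window least-squares template, which the
test suite checks against a direct ensemble average. `P(0) = delta I` with
`delta = 100 * var(input)` makes the first beats follow the data
aggressively; the first 3 beats are nonetheless flagged unreliable and
excluded from feature computation. All three parameters are exposed in
`rls_params()`: the construction is a standard event-synchronous
interference-cancellation configuration, and alternatives can be swapped in.

### The 66 window features

Analysis runs on 10-s windows with 80% overlap (2-s hops), fully contained
in the segment. Per window and per channel (carotid `ccc_*`, abdominal
`cca_*`) the package computes 33 features — 66 in total:

* 3 distribution features of the component's samples: SD (n−1
  denominator), skewness and kurtosis (uncorrected standardized moments;
  normal kurtosis = 3);
* the median and SD, over the window's valid beats, of 15 per-beat
  morphology scalars: 5 amplitudes (peak value, onset-to-peak,
  offset-to-peak, and the max and mean of the two limb amplitudes), 4
  durations (onset-to-peak, peak-to-offset, total, pulse width), 3 areas
  (onset-to-peak, peak-to-offset, total) and 3 curve lengths (same three
  limbs).

Beats are delineated per QRS instant: the peak is the component's maximum
within `(qrs, qrs + min(RR, 1 s)]` (the fluctuation follows its beat; the
1-s cap keeps windows bounded at slow rates), the onset is the nearest local
minimum at or before the peak, the offset the nearest local minimum after
it, with the search-window edges as fallbacks. Beats whose onset-to-peak
amplitude is not positive are invalid. A beat belongs to the window that
contains its peak; beats are never split across windows. Windows with fewer
than 2 valid beats in either channel are unusable.

Three conventions are documented reconstructions (the source description of
the exact landmark rules is not public):

* *Pulse width* — the time the component stays above
  `cc[peak] - a_mean/2`, with linearly interpolated crossings. Referencing
  the half level to the mean of the two limb amplitudes is symmetric in the
  limbs and degrades gracefully when the baseline tilts.
* *Areas* — trapezoidal integral of the component above the chord joining
  onset to offset, not above zero: robust to residual drift in the
  component.
* *Curve lengths* — `sum(sqrt(dt^2 + dcc^2))` along each limb, i.e.
  arc length in the mixed seconds-by-signal-units plane.

### Regression and wrapper selection

Windows are split **patient-wise** 75/25 into development and validation
sets; all windows of a subject land on one side. Model building uses only
the development set.

Selection is a wrapper around cross-validated multiple linear regression:

* **CV folds are subject-wise** (sorted subjects assigned round-robin to 5
  folds). Consecutive windows overlap by 80%, so window-wise folds would
  leak nearly identical rows between train and test and reward
  overfitting. This grouping is a design choice — the alternative
  (window-wise) is not defensible with this window structure.
* The **baseline** is the single most relevant feature by mRMR (greedy
  ranking by absolute Pearson correlation with CO minus mean absolute
  correlation with already-ranked features; the difference form is the
  default, a quotient variant is available). On both the simulated cohorts
  and by construction this is the median total fluctuation duration of the
  carotid component.
* **PTA(3,2)**: each iteration stepwise-adds the 3 candidates with the
  lowest CV-MSE, then stepwise-removes the 2 features whose removal lowers
  CV-MSE most, accepting the resulting (K+1)-feature model iff its CV-MSE
  improves. **Squared terms**: whenever a candidate is evaluated, its
  squared standardized term is tried too and kept iff it lowers the CV-MSE.
  Folding the squared-term test into the candidate scan (rather than only
  after acceptance) lets the wrapper see purely quadratic relationships,
  which a linear-only scan is blind to; the kept flag still requires an
  MSE decrease, so the behavior on linear features is unchanged.
* **Stopping**: a decrease counts only if it exceeds a relative tolerance
  of `1e-4` — with an absolute floor of `1e-8 * var(y)` so a numerically
  perfect fit cannot keep "improving" inside floating-point noise. Ties in
  add/remove scans break toward the lower feature index. The accepted
  CV-MSE sequence is non-increasing by construction.

The final model is ordinary least squares on the standardized selected
features (+ flagged squared terms of the standardized values), refitted on
the whole development set. Standardization constants are stored in the
model and applied at prediction.

The package also ships the frozen published model
(`published_model()`): intercept 6.70 L/min and nine coefficients on five
standardized features (carotid median total duration and peak-to-offset
curve length; abdominal skewness, median onset-to-peak duration and median
peak-to-offset curve length), four of them with squared terms. Its
standardization constants were never published, so the object requires
explicit means/SDs (or `standardization = "identity"` for inputs already
standardized); predicting without them is an error rather than a silent
reuse of another dataset's constants.

### Agreement evaluation

`agreement()` reports, with the error defined as reference minus estimate:
MAE; MSE; percentage error `PE = 100 * 1.96 * sigma / mean(y)` with the
interchangeability flag at the conventional 30% limit; Bland–Altman bias
and `bias ± 1.96 sigma` limits of agreement; R² as the squared Pearson
correlation; and per-phase quartile summaries of the absolute error. Two
conventions are ours to fix: `sigma` uses the n−1 denominator (the source
does not specify it), and the Bland–Altman abscissa is the reference CO
rather than the pair mean, matching how the source method plots it.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_cohort()` generate, per subject:

* a latent CO trajectory: a bounded mean-reverting random walk around a
  subject baseline (normal, mean 6.5, SD 0.8 L/min, clamped into
  [3, 9] L/min), with phase-specific attractor shifts (Trendelenburg
  +0.7, Infusion +0.5, Hypoventilation −0.5 L/min) over four phases of
  40/30/45/60 s — typical artifact-free segment lengths for this protocol;
* a beat train with heart rate linear in CO
  (`32 + 6*CO` bpm, 2% RR jitter), QRS+T-wave ECG;
* per-beat BCG fluctuations (raised-cosine template by default; gaussian
  and triangle available, the triangle giving closed-form feature values
  for tests) whose duration decreases with CO (−0.03 s per L/min around
  0.45 s) and amplitude increases with it (+0.08 per L/min), delayed
  ~120/220 ms after the QRS for the carotid/abdominal channel;
* a 0.27 Hz respiratory sinusoid, white noise at 10 dB SNR relative to the
  circulatory component, and a 0.5 Hz CO reference with 0.15 L/min
  measurement noise. Motion-artifact bumps exist but default to off.

The duration–CO anticorrelation is the load-bearing assumption: the source
method reports exactly this relation (longer fluctuations at lower heart
rate, hence lower CO) as what its strongest features pick up, and the
simulator reproduces it qualitatively. Every additive component, beat
landmark and the latent CO are stored as ground truth, so the simulator
serves as the oracle for QRS detection, RLS separation, delineation and
end-to-end parameter recovery.

What the simulator does **not** model: real BCG wave shapes (which are
multiphasic and subject-specific, not smooth single humps), motion and
sensor-contact artifacts of the kind that forced manual segment exclusion
in practice, arrhythmic beats, respiratory modulation of the beat
amplitude, or any physiologically detailed hemodynamics. Passing the test
suite therefore demonstrates that the pipeline's machinery is correct and
recovers a known generative law under realistic noise — not that the
published clinical accuracy transfers to real recordings.

## Numerical choices and degenerate inputs

* Window/CO alignment: CO sample `k` (0-based) sits at
  `co_t0_offset + k/fs_co`; windows are closed on the left, open on the
  right. Alignment is invariant to shifting the window and the offset
  together.
* Segments are cut sample-exact (no resampling); how the 0.5 Hz CO stream
  was registered against the 250 Hz signals in an acquisition is the
  user's statement via `co_t0_offset`.
* An all-zero ECG yields an empty QRS train, not an error; RLS requires
  ≥ 3 beats; the component is zero before the first beat.
* Delineation falls back to the search-window edges when no local minimum
  exists; an identically-zero component marks all beats invalid.
* `fit_linear()` refuses constant columns and rank-deficient designs,
  naming the offending terms.
* Serialization (records and models) writes numbers with 17 significant
  digits, so write→read round trips are bit-exact.

## Problem sizes used in the shipped checks

The test suite exercises subject-level stages on 20–60 s single-subject
simulations and the end-to-end recovery on a 20-subject cohort at the
default phase durations (175 s per subject), split 15/5 patient-wise — the
cohort size the method was designed around. The end-to-end check requires
the selected model to include at least one duration feature and to reach a
development-set MAE within twice that of an oracle regression built on the
true per-window mean beat duration taken from the simulator's ground truth.

## Known limitations

* The exact RLS formulation, landmark definitions and pulse-width level of
  the source method are not public; ours are labeled reconstructions with
  the conventions stated above, and all are parameterized.
* The published model's standardization constants are unavailable, so its
  absolute predictions on new data require the user to supply constants
  estimated on a compatible cohort.
* mRMR uses correlation-based relevance/redundancy, appropriate for a
  continuous target but blind to purely nonlinear marginal dependence
  (mitigated by the squared-term rule downstream).
* The wrapper's CV-MSE surface is noisy at small subject counts; with
  fewer than ~8 development subjects, fold counts below 5 are advisable
  (`pipeline_config(cv_folds = ...)`).
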