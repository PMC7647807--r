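---
title: "Detecting acute stress from trackpad finger dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting acute stress from trackpad finger dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padstress)
```

# Overview

`padstress` implements a pipeline for detecting acute stress from
multi-touch trackpad logs: segment each trial's events into continuous
single-finger strokes, identify the largest stroke, fit it as the step
response of a mass-spring-damper (MSD) system, compute contact-area and
kinematic metrics, process wrist EDA as a physiological manipulation check,
and run a routed paired-statistics protocol over the relaxed and stressed
task phases. Because no subject-level dataset is distributable, the package
ships a synthetic-study generator whose ground truth exercises every stage;
this vignette documents the models, the tunable parameters, and the design
decisions taken where the underlying protocol leaves choices open.

# The mass-spring-damper stroke model

## Model and assumptions

A rapid goal-directed pointing stroke toward a target at distance $D$ is
modelled as the step response of a single-degree-of-freedom linear
second-order system. In the underdamped regime (damping ratio
$\Gamma \in (0,1)$, damped frequency $\omega$ rad/s, natural frequency
$\omega_n = \omega/\sqrt{1-\Gamma^2}$):

$$x(t) = D\left[1 - e^{-\Gamma\omega_n t}\left(\cos\omega t +
  \frac{\Gamma\omega_n}{\omega}\sin\omega t\right)\right].$$

The assumptions are: the stroke starts at rest, the movement is dominated
by its horizontal component (the tasks are horizontal), and a single
second-order mode captures the trajectory. Physical mass, damping and
stiffness are not separately identifiable from a trajectory alone, so the
package reports only the identifiable pair $(\Gamma, \omega)$.

## Identification by AR(2)/LPC fitting

Uniformly sampled, the step response minus its steady state satisfies an
exact second-order linear recurrence, so `fit_ar2()` estimates
$x_n = c_0 + a_1 x_{n-1} + a_2 x_{n-2} + e_n$ by least squares (the
covariance method of linear prediction) and `ar2_to_msd()` maps the complex
pole pair $z = re^{\pm i\theta}$ through $s = (\ln r \pm i\theta)/\Delta t$
to $\Gamma = -\mathrm{Re}(s)/|s|$ and $\omega = |\mathrm{Im}(s)|$.

Three numerical decisions matter here:

* **Resampling grid.** The logger is jittered (mean 8.17 ms, SD 3.75 ms),
  so `preprocess_stroke()` linearly interpolates x onto a uniform 10 ms
  grid — close to the native rate, cheap, and fine enough that halving the
  grid changes the recovered parameters by well under 1% on clean input.
* **Detrending.** The steady state is estimated as the mean of the final
  10% of grid samples and subtracted. Any residual offset (the tail of a
  slow stroke has not fully settled) would bias a pure AR(2) fit, so the
  regression keeps an intercept $c_0$ that absorbs it exactly; the poles —
  and hence $\Gamma$ and $\omega$ — are unaffected. With the intercept, a
  noiseless sampled step response is fit exactly at any stroke length.
* **Covariance over autocorrelation method.** The covariance
  (least-squares) estimator is exact on short deterministic segments,
  which is precisely the regime of a 2-second stroke; the Yule-Walker
  estimator (available via `method = "autocorrelation"`) introduces a
  windowing bias of order $1/n$. Both are selectable.

Real pole pairs (non-oscillatory fits) are flagged `overdamped_flagged`
rather than mapped, pole moduli $\ge 1$ are flagged unstable, and
`estimate_trial_msd()` converts any per-trial failure into a flagged-absent
row so batch processing never aborts; flagged trials are excluded from
aggregation and counted.

On noiseless, jitter-free input sampled on the fitting grid the estimator
recovers $(\Gamma, \omega)$ to machine precision (the test suite requires
$10^{-4}$ relative over $\Gamma \in \{0.3,\dots,0.9\}$,
$\omega \in \{2,\dots,20\}$ rad/s). With sampling jitter the linear
interpolation onto the grid contributes an $O(\Delta t^2)$ curvature error,
which is why the strict noiseless bound is stated for grid-aligned
sampling; under the generator's default jitter and positional noise the
median recovery error stays below 5%, with near-real-pole corner cases
($\Gamma = 0.9$) occasionally flagged rather than misreported. Parameter
recovery tests use stroke durations covering the settling time
$\approx 6/(\Gamma\omega_n)$ of each grid point, since a stroke that ends
mid-transient carries no steady-state information.

# Stroke segmentation

Trials frequently contain discontinuities: subjects lift fingers, switch
fingers or hands, or rest a second finger on the pad. `split_strokes()`
partitions events by finger id and cuts wherever the inter-sample interval
exceeds `max_gap_ms` or the coordinate jump in x or y exceeds
`max_jump_mm`; fragments shorter than `min_stroke_samples` are discarded
and counted. `select_largest_stroke()` picks the stroke with the largest
net horizontal extent $|x_{end}-x_{start}|$ (ties: longer time span, then
earlier start), since x carries the displacement information for these
horizontal tasks.

Defaults: `max_gap_ms = 50` (about six mean sampling intervals),
`min_stroke_samples = 4`, and `max_jump_mm = 20`. The jump threshold
deserves a note: a fast stroke toward a 1024-pixel target reaches peak
velocities around 600 mm/s, which covers more than 5 mm between consecutive
samples and over 10 mm across a single dropped frame — so a small jump
threshold would misclassify ordinary fast motion as a gap. 20 mm cannot be
reached by continuous within-stroke motion even through a dropped sample,
while true lift-and-replace discontinuities either jump much farther or
trip the 50 ms time rule and the finger-id change. A trial "has a gap" iff
segmentation produced more than one stroke or discarded a fragment; with
the defaults this estimator calibrates to the generator's injection
probability (see below).

# The synthetic-study generator

`simulate_study()` emulates a two-arm counterbalanced study: each subject
is assigned to the Relax-Stress or Stress-Relax arm (default 8/10 at 18
subjects), completes a 120-trial condition block per phase — three
contiguous task-type blocks (click, steer, drag-and-drop) of 20
distance×width configurations × 2 repetitions in seeded random order — and
contributes self-reports at six markers plus an EDA series per phase.

What the generator emulates, and its defaults:

* **Logger timing**: truncated-normal positive inter-sample intervals,
  mean 8.17 ms, SD 3.75 ms.
* **Trajectories**: underdamped MSD step responses with per-condition
  ground truth ($\Gamma$ 0.538 relaxed / 0.540 stressed — the reported
  magnitudes for the two phases — and a physical $\omega_d$ of 8.0/8.2
  rad/s), plus 0.05 mm positional noise. The reported damped frequency of
  0.256 rad/s in the source protocol is physically implausible for
  ~2-second strokes (it implies a >24 s oscillation period) and is most
  likely a normalized discrete-time quantity; the generator therefore uses
  a frequency in the physically expected range and the package reports
  physical rad/s throughout.
* **Contact areas**: per-sample ellipse areas are lognormal (areas must
  stay positive) with per-condition means anchored to the raw click-task
  values 270.9/284.6 mm², within-trial SDs 16.7/21.2 mm², a
  between-subject SD of 26.7 mm² (the reported standard error scaled by
  $\sqrt{18}$), and a shared subject baseline across conditions so the
  condition effect is paired. Axes are drawn from the area and a lognormal
  aspect ratio (≥ 1), so major ≥ minor always holds. Setting
  `effect_spec$d_area_mean` re-derives the stressed mean as
  relaxed + d·between-SD; at 1000 simulated subjects `cohens_d()` recovers
  the configured d within ±0.15.
* **Artifacts**: with probability 0.38 per trial, a contiguous 50–300 ms
  span inside the middle 80% of the trial is removed and later events are
  re-labelled with a fresh finger id (a lift-and-replace); conditional on
  a gap, a short low-displacement concurrent second-finger trace is added
  with probability 0.3. Artifacts never touch the largest stroke's
  displacement information. Secondary traces accompany gaps rather than
  occurring independently so that the trial gap rate calibrates to the
  injection probability.
* **Self-reports**: integers on the 0–10 scale from truncated discretized
  normals whose marker means follow the reported raw phase values (2.27,
  3.78, 6.22, 4.50, with 3.5 at arrival). The marker mapping places each
  phase between consecutive markers — arm A: Relaxation (SR1,SR2),
  tRelaxed (SR2,SR3), Stressor (SR3,SR4), tStressed (SR4,SR5), with SR0 at
  arrival; arm B mirrored with the stress block first — consistent with
  the during-phase value being the mean of the flanking markers (e.g.
  SR4/SR5 for tStressed in arm A).
* **EDA**: 4 Hz (the wearable's native EDA rate), tonic level 2.06/4.22 µS
  with slow drift, Poisson SCRs at 0.10/0.17 Hz with lognormal amplitudes
  (medians 0.15/0.25 µS) and biexponential rise/decay (0.75 s / 3 s), plus
  0.005 µS Gaussian sensor noise. Ground-truth pulse times and amplitudes
  are returned for verification.

What it does **not** emulate: vertical task variants, human timing
variability beyond the stated moments (task completion times, pauses,
fatigue), learning effects across blocks, finger-specific contact-area
differences, EDA motion artifacts, and any dependence of the MSD
parameters on task configuration. Passing tests on generated data
therefore demonstrate that the pipeline recovers what the model family can
express — not that real trackpad data satisfies the model.

# EDA processing

The manipulation check follows: zero-phase 6th-order Butterworth low-pass
at 1 Hz (`filter_eda()`, forward-backward so SCR latencies are not
shifted, with demeaning and odd reflection padding so a constant series
passes through exactly); a rule-based quality screen (`screen_quality()`:
no-signal range < 0.01 µS, any sample above 20 µS, or more than 5% noisy
5-second epochs, an epoch being noisy when a sample-to-sample jump exceeds
1 µS or a value leaves [0.01, 20] µS); tonic/phasic decomposition; and SCR
counting at the 0.01 µS amplitude threshold.

`decompose_eda()` uses a sliding-window percentile baseline — the 10th
percentile over a centred 10 s window, smoothed by a 1 s moving average —
as the tonic component, with the phasic component the remainder floored at
zero. This replaces model-based continuous decomposition with a simple,
deterministic, dependency-free estimator; it is offset-invariant (adding a
constant changes only the tonic) and satisfies the exact identity
tonic + unfloored phasic = input. It will under-resolve overlapping SCRs
relative to deconvolution methods, which is acceptable for the per-phase
summary statistics used here, and means numeric parity with
deconvolution-based tonic/phasic values is not claimed.

`count_scrs()` counts local maxima of the phasic driver with prominence
above the preceding trough of at least 0.01 µS and a 1 s minimum
separation, after a 1 s moving-average smoothing of the driver: SCR pulses
are several seconds wide and pass intact, while single-sample noise bumps
that would otherwise clear the threshold are suppressed. Peak selection is
a greedy left-to-right spacing scan, which makes the count provably
monotone non-increasing in the amplitude threshold. Under the generator's
defaults, over 90% of injected pulses with amplitude ≥ 3× the noise SD are
recovered with false positives below 10%.

# The statistical protocol

`paired_compare()` routes each condition contrast through a Shapiro–Wilk
test on the *paired differences* at α = .05 (the protocol does not specify
differences versus marginals; differences are what the paired t-test
assumes normal): normal → one-tailed paired *t*; otherwise → one-tailed
Wilcoxon signed-rank, using the exact distribution below n = 10 and the
continuity-corrected normal approximation from n = 10.

Effect sizes use the pooled across-condition SD
(`cohens_d()`, the $d_{av}$ convention): this is the convention that
reproduces the protocol's reported mixed-task area effect (0.87) from its printed
condition moments, whereas $d_z = t/\sqrt{n}$ would not. The printed
"(SE)" columns behave as SDs in that arithmetic (an SE of 0.18 at n = 18
would imply an SD above 0.76 for min-max normalized data, which is
impossible), and are treated as such. Bands: negligible < 0.20, small to
0.49, medium to 0.79, large ≥ 0.80.

`power_paired_t()` computes post hoc power from the noncentral *t*
distribution with df = n − 1 and noncentrality $\delta = d\sqrt{n}$ at
one-tailed α = .05 — the combination that reproduces the published 56% and
91% for d = 0.44 and 0.73 at n = 18. A Monte-Carlo oracle (simulated
paired normals) agrees within 1.5 percentage points across the d grid.

`order_condition_anova()` tests the Order × Condition interaction as a
two-way ANOVA on the stacked per-subject condition values, giving the
interaction on (1, 2n − 4) error degrees of freedom — (1, 32) at n = 18,
matching the reported statistics. A classical mixed-design within-subject
error term would give (1, n − 2); the published degrees of freedom
identify the stacked formulation, so that is what the package implements.

Sensitivity subsets: `subset_initial()` takes the first
`round(fraction·n)` trials in production order (4 of 40 at 10%);
`subset_decimated()` keeps the first, the last, and two seeded interior
draws — exactly four trials. `bonferroni_alpha(0.05, 3)` gives the
task-specific threshold 0.0167 (displayed 0.017).

Calibration properties verified by the suite: on null data the routed
protocol rejects at ≈ α, and under a standardized effect its empirical
rejection rate matches the analytic power within 3 points (2000
replicates each).

# Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → segment → metrics/MSD → EDA → analyze,
writing plain CSV/JSON intermediates and a manifest with the config hash
and seed; identical configurations yield byte-identical reports. Every
random operation draws from a stream derived deterministically from the
single top-level seed, so datasets are reproducible component-wise.

The test suite and acceptance script choose problem sizes that make the
statistical checks informative while keeping the full run in tens of
seconds: 6-subject studies for end-to-end pipeline checks, 10,000 trials
for the gap-rate calibration (binomial SE ≈ 0.5 points), 2,000 replicates
for type-I/power calibration, and 3 replicates of the 16-point
$(\Gamma, \omega)$ grid for noisy recovery. These sizes are stated here as
the package's own verification design.

# Known limitations

* The MSD fit is x-direction only and assumes a single second-order mode;
  multi-submovement corrections or 2-D models are out of scope.
* $\pi a b$ is computed literally from the logger's axis fields. If a
  logger reports full axes rather than semi-axes the true ellipse area is
  a quarter of this; `axes_are_full = TRUE` applies the correction, but
  all defaults keep the literal product for comparability.
* The percentile-baseline EDA decomposition is not a deconvolution; tonic
  and phasic means are comparable within this pipeline, not across tools.
* Within-trial contact-area SD is computed per stroke and then averaged
  (the alternative — pooling all samples of a trial — differs when strokes
  differ in level; the per-stroke convention was chosen and is tested).
* The generator's realism boundaries (above) bound what green tests prove
  about real data.
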