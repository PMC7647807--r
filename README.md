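# padstress

Acute stress changes how fingers move: under a stressor, forearm and hand
muscles tense, and that tension shows up in the dynamics of finger strokes
on a laptop trackpad — most robustly in the contact area under the
fingertip. **padstress** implements the full analysis pipeline for detecting
that signal from multi-touch trackpad event logs, together with a
synthetic-study generator with known ground truth so that every stage is
verifiable end to end.

The package is aimed at researchers in digital biomarkers and
affective/behavioral signal processing who want a tested, reproducible
implementation of the trackpad stress protocol: stroke segmentation of
jittered multi-finger logs, mass-spring-damper (MSD) system identification
of pointing strokes, contact-area/kinematic metrics, electrodermal activity
(EDA) validation processing, and the routed paired-statistics protocol.

## The model

A goal-directed pointing stroke is approximated as the step response of a
single-degree-of-freedom mass-spring-damper system. For an underdamped
system with damping ratio Γ ∈ (0,1) and damped frequency ω (rad/s), the
horizontal displacement toward a target at distance D is

```
x(t) = D [ 1 − e^(−Γ ωₙ t) ( cos ωt + (Γ ωₙ / ω) sin ωt ) ],   ωₙ = ω / √(1 − Γ²).
```

Sampled uniformly, x(t) minus its steady state is an exact second-order
autoregression, so the package fits an AR(2) by linear-predictive least
squares and maps the complex pole pair z = r·e^(±iθ) to continuous poles
s = (ln r ± iθ)/Δt, giving **Γ = −Re(s)/|s|** and **ω = |Im(s)|**. Muscle
tension under stress is expected to change these parameters and, more
directly, the fingertip contact area **A = π·a·b** computed from the
logger's ellipse axes.

Condition contrasts (relaxed vs stressed task phase) follow a routed
protocol: Shapiro–Wilk on the paired differences gates a one-tailed paired
*t* test versus a Wilcoxon signed-rank test; effect sizes are Cohen's *d*
with the conventional bands; post hoc power comes from the noncentral *t*
distribution; task-specific models use a Bonferroni threshold of
0.05/3 = 0.017; and sensitivity models re-test the initial 10% (4 of 40)
and a decimated subset of click trials.

## Worked example

```r
library(padstress)

cfg   <- generator_config(n_subjects = 6, seed = 42)
study <- simulate_study(cfg)
study
#> Synthetic trackpad stress study: 6 subjects, 1440 annotated trials

# fit the MSD model to one trial's largest continuous stroke
ev  <- study$subjects[[1]]$conditions$tRelaxed$events[1:200, ]
fit <- msd_fit(select_largest_stroke(split_strokes(ev)))
summary(fit)
#> Mass-spring-damper stroke model
#>   regime: underdamped
#>   Gamma = 0.6723   omega = 7.6440 rad/s   omega_n = 10.3263 rad/s
#>   AR(2): a1 = 1.86041, a2 = -0.87035, |pole| = 0.9329
#>   n = 165 grid samples (10 ms), residual RMS = 0.0744 mm, steady state = 120.41 mm

# full protocol over all trials
trials <- study_trial_table(study)
rep <- analyze_trials(trials, setNames(as.list(cfg$arm_assignment),
                                       as.character(1:6)))
r <- rep$mixed_task$mean_area_mm2
sprintf("%s: d = %.2f (%s), one-tailed p = %.3g",
        r$test_name, r$cohens_d, r$effect_band, r$p_value)
#> "paired_t: d = 0.64 (medium), one-tailed p = 3.89e-10"
```

The single-trial Γ of 0.67 scatters around the generator's ground truth
(0.538) because one 2-second stroke carries limited information; the
protocol averages over 120 trials per condition before testing. The
mixed-task contrast recovers the configured positive contact-area effect;
with only 6 subjects the pooled-SD effect size (0.64) is attenuated
relative to the generator's subject-level effect, which is the expected
behavior of `d_av` under within-trial noise.

One call runs everything (simulation → segmentation → metrics/MSD → EDA →
statistics) and writes CSV/JSON artifacts plus a manifest:

```r
run_pipeline(pipeline_config(generator = cfg), out_dir = "out")
```

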