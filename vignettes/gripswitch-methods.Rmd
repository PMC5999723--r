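---
title: "Methods: simulating and detecting switched feedforward grip-force control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting switched feedforward grip-force control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When we transport a hand-held object, grip force (the normal force of the
fingers on the object) is coordinated with load force (the tangential force
that tends to make the object slip). For smoothly varying loads the
coordination is essentially synchronous; for impact-like loads — contact with
a stiff surface — the grip-force maximum trails the load peak by tens of
milliseconds, and catch-trial experiments show that this delayed peak is
programmed in advance, not a reflex. Both behaviors are feedforward, yet they
differ qualitatively, even though an elastic contact is described by a single
continuous parameter, the stiffness $k$.

This package implements a synthetic analogue of the experiment that probes
the transition between the two regimes: vertical 15-cm reaches into a
one-sided virtual spring

$$F(y) = \begin{cases} 0 & y < y_0 \\ k\,(y - y_0) & y \ge y_0 \end{cases}$$

whose stiffness grows (or shrinks) monotonically over the 45 trials of a
block, with onset position $y_0$ and stiffness $k$ co-varied so that the peak
force at the target ramps from 4 N (at $y_0$ = 3 cm, $k$ = 4/0.12 = 33.3 N/m)
to 14 N (at $y_0$ = 14.5 cm, $k$ = 14/0.005 = 2800 N/m). Six of the 45 trials
are silent catch trials ($k$ set to 0, schedule retained). The analysis asks:
does the lag between the grip-force peak and the (expected) elastic-force
peak switch between two regimes at a stiffness threshold, with hysteresis
between ascending and descending series, and is the switch aligned with the
sign of hand acceleration at force onset?

The package contains three things: a generative model of such an experiment
(`simulate_cohort()`), the standard preprocessing chain
(`derive_and_filter()`, `extract_features()`), and the switching-detection
statistics (`analyze_cohort()` and the functions it wraps). Because no raw
data are deposited, the generator doubles as ground truth for parameter
recovery: every simulated trial records the lag and thresholds that produced
it.

## The generative model

### Design

`make_schedule()` reproduces the block design exactly: 41 onsets linearly
spaced by 0.2875 cm, peak-at-target force interpolated linearly between the
two printed endpoint pairs (the simplest rule consistent with both printed
stiffness extremes), four plateau repeats of the stiffest field, descending
blocks as the exact reverse, and six catch positions drawn uniformly without
replacement subject to no-adjacency and to every 5-trial mini-block keeping a
real trial. Six catch trials cannot give all seven mini-blocks a catch trial
in every block; pooling across the ten blocks of a session, every mini-block
receives both trial types, which is what the mini-block comparisons need.

### Plant

The planned movement is two back-to-back minimum-jerk segments (home → peak →
home) scaled to a planned peak speed drawn from a truncated normal
(mean 0.499, SD 0.02, bounds 0.45–0.55 m/s). The planned amplitude is
17.5 cm: participants plan to push through the spring, so the plan overshoots
the 15-cm target. This value is a design computation, not a free fit: the
sign flip of planned acceleration occurs at half the amplitude, 8.75 cm,
which maps through the schedule to $\ln k \approx 4.97$ — the model thus
embodies the empirical coincidence between the strategy-switch threshold
($\ln k \approx 4.98$ averaged across conditions) and the
acceleration-sign transition at force onset. It also makes catch trials
overshoot the target, as observed.

On real trials the realized acceleration is the planned acceleration minus
the transmitted field force divided by the effective mass
(`m_eff` = 1.2 kg), with **no feedback correction**. Transmission is a 30-ms
transport delay followed by a first-order compliance lag (τ = 10 ms): force
rendered on the handle reaches hand acceleration neither instantly nor as a
step. This is what makes real and catch accelerations, aligned to force
onset, diverge measurably ~30 ms after onset at every stiffness — the
experiment's motor-equivalence signature. On catch trials the realized
trajectory is exactly the plan.

Two consequences of the deliberately minimal plant are worth stating
honestly. Because nothing compensates the field, soft-field real trials
undershoot the virtual target (peak ≈ 12 cm instead of 15), and the stiffest
real trials transiently exceed the device's nominal 14-N maximum. Neither
affects any estimator — the elastic-force argmax stays well defined — but
position traces should not be read as faithful reproductions of real
kinematics near the target.

### Controller

Grip force is baseline (2 N) plus two feedforward components:

* an **inertial component**, `inertial_gain` × the positive part of planned
  acceleration (0.4 N per m/s²), time-jittered per trial. The positive part,
  rather than the absolute value, is used deliberately: |a| has a V-shaped
  kink at the movement turnaround whose slope would drag the grip argmax tens
  of milliseconds off the anticipatory peak. The rectified drive yields the
  first local grip peak synchronized with the first acceleration peak, which
  is the empirical signature being modeled;
* an **anticipatory bump**, Gaussian in time (SD 80 ms), centered at the
  trial's (expected) impact time plus the generative lag plus
  $\mathcal N(0, 6\,\text{ms})$ trial noise. Its amplitude follows an
  inverted-U on the $\ln k$ axis,
  $A(\ln k) = 4\,\mathrm{e}^{-(\ln k - \theta_c)^2 / (2 \cdot 2.5^2)}$ N,
  centered on the condition's threshold ($\theta_{asc} = 5.07$,
  $\theta_{desc} = 4.89$); the width 2.5 was chosen (by a design computation,
  before any recovery test) so that a fourth-order polynomial fitted over the
  observed $\ln k$ range recovers the center to within 0.01.

The generative lag is piecewise linear in $\ln k$: from 4 ms at the softest
field it rises to 40 ms at the *effective* threshold and stays at 40 ms above
it. Hysteresis enters twice, as in the hybrid-controller interpretation: the
amplitude curve is centered on the condition's own threshold, and the lag
regime flips only three trials after the schedule crosses it
(`switch_inertia_trials`), so the effective threshold sits slightly beyond
the nominal one in the direction of travel. The softest-field lag defaults to
+4 ms; leading (negative) soft lags are available via `lag_soft < 0` for
users who prefer the individual-fit reading of the lag curves, but conflict
with the printed softest-condition mean, so they are not the default.

Catch trials use the identical grip construction, keyed to the expected
impact computed from the trial's own kinematics and scheduled field. Under
the no-feedback plant, real and catch kinematics diverge strongly after force
onset, so the two trial types reach (expected) peak force at different times;
the anticipatory bump therefore sits at different latencies from *force
onset* in the two types, and the catch-minus-neighbor grip-force-rate
difference — which is near zero in real data — is systematically negative in
the simulation. This is a known fidelity limit of the minimal plant, not of
the estimators; the test suite asserts instead the pre-onset
motor-equivalence that does hold.

### Noise and heterogeneity

Measurement noise: white position noise of 0.1 mm (typical of optical/encoder
tracking; after double differentiation and the 20-Hz zero-phase filter it
yields ≈ 0.13 m/s² acceleration noise) and 0.05 N on the grip channel.
Between participants, effective mass (SD 0.1 kg) and habitual peak speed
(SD 0.015 m/s) vary; a strictly homogeneous cohort would make
between-participant variances unrealistically tiny and every between-group
test essentially infinitely powered. What the generator does **not** emulate:
feedback corrections, muscle low-pass dynamics, slip events, fatigue or
learning trends, non-Gaussian lapses. Passing recovery tests therefore show
that the estimators are unbiased and appropriately powered under this model,
not that they are robust to every pathology of real recordings.

## Preprocessing

Velocity, acceleration and grip-force rate are central differences smoothed
with a 4th-order Butterworth low-pass (20 Hz per pass) run forward and
backward — zero net phase, squared magnitude response — with odd-reflection
padding at the edges; the phrase "zero phase-lag autoregressive filter"
admits several realizations, and this is the standard one. Movement onset is
the earliest sample from which velocity exceeds 3 cm/s for at least 100 ms.
Impact is the argmax of the rendered elastic force (real trials) or of the
expected elastic force applied to the recorded position (catch trials); ties
break to the earliest sample.

Two extraction rules had to be made fully automatic where the original
procedure relied on a visual check. The first acceleration peak is the
argmax in a 250-ms post-onset window — noise ripples on the rising flank and
filter ringing at the stiff-field impact otherwise pre-empt the genuine hump.
The first (inertial) grip peak is the *dominant* local maximum within
±150 ms of that acceleration peak (strict local maximum over five samples);
the literal earliest local maximum latches onto millinewton-scale filter
ripples. Features whose defining peak is absent are reported `NA`, never
fabricated.

## Statistics

* `fit_extremum()`: least-squares quartic of grip peak vs $\ln k$; the
  extremum is the argmax restricted to the observed range (1-m$^{-3}$ grid,
  refined by the derivative's real roots), boundary extrema flagged —
  quartics diverge outside the data, so unrestricted argmaxima are
  meaningless.
* `bootstrap_diff()`: participants resampled with replacement (default
  10,000 repetitions, seeded), percentile 95% CI of the mean difference or
  of the absolute slope difference; "excludes zero" is the decision rule.
* `piecewise_fit()`: continuous hinge with *fixed* breakpoint (3 mean
  parameters) vs the single line (2), compared by
  $\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(p+1)$, counting the residual
  variance. The breakpoint is fixed because it is estimated upstream from an
  independent quantity (each participant's grip-peak extremum); an
  unconstrained two-line variant and an AICc flag exist but are off by
  default.
* `divergence_time()`: two-sample t-tests on 20-ms bin means from force
  onset, divergence = start of the earliest bin from which p < 0.05 holds
  for bins spanning ≥ 150 ms. The pipeline feeds it per-mini-block,
  per-participant mean traces on a window reaching 300 ms past force onset
  so that the sustain criterion can be evaluated even at the stiffest
  levels.
* `acc_sign_threshold()`: first sign change of the mean
  acceleration-at-onset curve ordered by $\ln k$, linearly interpolated
  (the grid is discrete; interpolation is the minimal convention).
* The original omnibus three-way ANOVA is deliberately not reproduced; the
  targeted comparisons that the conclusions actually rest on (paired and
  one-sample t-tests, the bootstraps above) are.

The cohort-level summary converts the two condition extrema to N/m and
averages them arithmetically (matching the printed
(159.7 + 133.2)/2 ≈ 147 N/m); the geometric-mean variant
$\exp((x^*_{asc}+x^*_{desc})/2)$ is also reported.

## Numerical conventions and problem sizes

Internal units are SI; interfaces use cm and ms where the field does. All
randomness flows from a single master seed (per-participant substreams); the
bootstrap seed defaults to 20180607. Peak ties break to the earliest sample
throughout. The onset-blend half-width `w` is a free parameter (the original
smoothing is described only as second-order polynomial interpolation);
1 mm preserves both printed stiffness endpoints to three digits and renders
the force C1.

The shipped analyses and the test suite run the full-scale design —
18 participants × 10 blocks × 45 trials at 500 Hz — in about 90 s on one
core by reducing each trial to features and a short aligned acceleration
window as it is generated; property-style tests use smaller cohorts
(2–4 participants, 2–4 blocks) whose sizes are stated in the test files.

## Known limitations

Beyond the plant limitations above: the hinge breakpoint is not profiled
jointly (available only as the unconstrained variant); perceptual
stiffness-estimation models are out of scope; and the participant-level
correlation between the strategy threshold and the acceleration-sign
threshold is essentially zero in the default generator, because thresholds
are homogeneous across simulated participants — the generator can exhibit
the *coincidence* of the two thresholds at the cohort level, but not their
*covariation* across participants, which would require participant-level
threshold variation correlated with kinematic style.
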