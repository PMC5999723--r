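# gripswitch

Switched feedforward grip-force control in elastic force fields: a synthetic
experiment generator, the standard kinematic preprocessing chain, and the
switching-detection statistics, as an R package with reproducible analysis
drivers.

## The problem

When the hand transports a gripped object against a smoothly varying load,
grip force tracks load force with essentially zero lag; when the load is an
impact against a stiff surface, the grip-force maximum trails the load peak
by tens of milliseconds — and catch trials show both behaviors are planned in
advance (feedforward). An elastic contact is described by one continuous
parameter, the stiffness *k*, so how does the motor system move between the
two regimes? The hybrid-control answer this package operationalizes: two
discrete feedforward strategies, selected around a stiffness threshold, with
hysteresis between series of increasing and decreasing stiffness.

The simulated experiment: vertical 15-cm reaches into a one-sided virtual
spring *F* = *k*(*y* − *y₀*) for *y* ≥ *y₀* (C1-smoothed onset), 10 blocks ×
45 trials per participant, onset positions linearly spaced 3–14.5 cm in
0.2875-cm steps with stiffness rising 33.3 → 2800 N/m (ascending blocks; the
reverse in descending blocks), 6 silent catch trials per block (13%), 500-Hz
recordings of position, load force and grip force, 18 participants.

The statistics recover, from the simulated cohort:

- the grip-peak **lag** to (expected) impact — ~40 ms at the stiffest field,
  ~4 ms at the softest (the two regimes);
- the **inverted-U** of grip-force peak vs ln *k*, whose quartic-fit extremum
  locates the switch threshold per condition (ln *k* ≈ 5.07 ascending, 4.89
  descending; hysteresis bootstrap across participants);
- the averaged **switch threshold** in stiffness units (~146 N/m);
- the **hinge (piecewise-linear) regression** of lag vs ln *k* at a fixed,
  independently estimated breakpoint, against a single line, compared by
  AIC = *n* ln(RSS/*n*) + 2(*p* + 1), plus a participant-level bootstrap of
  the slope difference;
- the **divergence time** of real vs catch acceleration after force onset
  (iterative 20-ms-bin t-tests with a 150-ms sustain rule), ~30 ms at every
  stiffness — the motor-equivalence signature;
- the **acceleration-sign threshold**: the ln *k* at which the hand switches
  from accelerating to decelerating when the force starts, which coincides
  with the strategy threshold;
- the near-zero **inertial lag** between the first grip peak and the first
  acceleration peak, constant across stiffness.

Every simulated trial records the ground truth that produced it, so all of
the above double as parameter-recovery tests.

## Worked example

```r
library(gripswitch)

cfg  <- run_config(n_participants = 18, seed = 1)
pipe <- run_pipeline(cfg)                     # simulate + extract features
res  <- analyze_cohort(pipe, reps = 10000)    # switching statistics
print(res)
```

```
Switching analysis (18 participants)
  grip-peak extremum: ln k = 5.069 (asc), 4.883 (desc)
  averaged switch threshold: 145.5 N/m
  hysteresis CI: [0.184, 0.189] (excludes zero)
  lag: 40.5 ms (stiffest), 4.2 ms (softest)
  slopes below/above threshold: 22.96 / 0.37 ms per ln-unit
  slope-difference CI: [22.27, 22.90] (excludes zero)
  AIC piecewise vs linear: 62.2 < 153.0 (asc), 80.9 < 172.1 (desc)
  real-catch acceleration divergence: 26 ms after force onset
  acceleration-sign threshold: ln k = 4.957
  inertial lag: -0.52 ms (t-test vs 0: p = 0.038)
  mean peak velocity: 49.9 cm/s
```

Reading this: the grip-peak extremum is recovered at the generative
thresholds for each block condition, and their difference (the hysteresis)
excludes zero across participants; converting both to N/m and averaging
gives the switch threshold ≈ 146 N/m. The lag sits on the ~40-ms plateau at
the stiffest field and near 4 ms at the softest; the hinge model's soft-side
slope (~23 ms per ln-unit) collapses to ~0 above the threshold and beats the
single line by AIC in both conditions. Real and catch accelerations diverge
within one 20-ms bin of the generative 30-ms transmission latency, the
acceleration-sign flip lands on the switch threshold, and the first
(inertial) grip peak stays synchronized with the first acceleration peak at
every stiffness.

The same pipeline runs as numbered drivers writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # features.csv, truth.csv, acc_windows.csv
Rscript analysis/02_switch_stats.R  # participants.csv, divergence.csv, summary.txt
Rscript analysis/03_figures.R       # results/figures/switching.pdf
```

`run_all(run_config(...))` does the whole chain in one call, serializing its
YAML configuration alongside the outputs; `make_fixtures()` emits a
noiseless mini-cohort and pathological trials (no movement, never enters the
field, double-peaked grip) for exact-recovery and failure-path testing.

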