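---
title: "Scoring sleep and wake from waist-worn actigraphy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sleep and wake from waist-worn actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
```

## The problem

Polysomnography (PSG) is the gold standard for staging sleep, but it needs a
laboratory, electrodes and a trained scorer.  Actigraphy estimates sleep and
wake from body movement alone: a worn accelerometer counts threshold
crossings, stores a per-epoch activity intensity, and a device-specific
algorithm converts the count series into sleep/wake calls.  The device this
package targets stores one integer count on a 32-level scale (0–31) per
2-minute epoch, recorded at the waist.  Children move more during sleep than
adults do, in every stage, so an algorithm calibrated on adults misreads
children's nights; the package therefore ships a child-specific discriminant
and all the machinery needed to validate it — or any replacement — against
PSG.

## Models and procedures

### Collapsing PSG to the activity grid

PSG stages (W, N1, N2, N3, R) are scored every 30 s; the actigraph stores one
count per 2 min.  `collapse_hypnogram()` maps four consecutive 30-s stages to
one 2-min epoch: a window containing **two or more W stages is wake**;
anything else is sleep, sub-classified by the most frequent non-W stage, with
frequency ties resolved in the priority order R > N1 > N2 > N3.  The rule is
total and deterministic: the package's test suite checks it against a
brute-force transcription on all 5⁴ = 625 possible windows.  Two boundary
policies are explicit rather than implicit:

* trailing 30-s stages that do not fill a 4-window are dropped
  (`trailing = "error"` refuses them instead); and
* nights longer than the `tib_cap_min` cap (default 420 min, i.e. 7 h) are
  truncated to the cap before collapsing — the convention of analyzing only
  the first 7 h of long nights — while shorter nights are used whole.

The priority list is applied to *any* frequency tie among non-W stages,
including three-way ties (e.g. one W plus N1, N2, N3 → N1); the published
rule illustrates only two-stage ties, and extending the same priority order
is the only reading that keeps the rule total.

### The five-epoch discriminant

Each 2-min epoch is scored from its own count and its four neighbours
(10 min of context):

$$z = a_{-2}x_{-2} + a_{-1}x_{-1} + a\,x + a_{+1}x_{+1} + a_{+2}x_{+2},$$

wake iff $z \ge 1$.  The comparison is exactly `>=` with no epsilon, and the
dot product has no intercept — the threshold carries the boundary.  The
child model `child_fs760()` is a built-in constant; adult or custom
coefficient vectors load from JSON via `read_model()`.  Coefficients apply
in window order $x_{-2} \dots x_{+2}$ and are never reordered.

The first and last two epochs lack full context.  The device convention is
unrecorded, so both defensible policies are implemented and logged in the
output: `edge = "zero"` (default) treats missing neighbours as zero
activity, which is deterministic and biases edges toward sleep — harmless at
lights-off, where subjects are in bed; `edge = "extend"` replicates the
nearest recorded count.

### Sleep parameters and the run-length search

On the 2-min grid, with TIB = 2 min × epoch count:

* **SL** (sleep latency): PSG — lights-off to the first sleep epoch;
  activity — lights-off to the start of the first run of ≥ `n_sl`
  sleep-scored epochs.
* **WASO**: PSG — TIB − SL − TST; activity — the summed length of maximal
  wake-scored runs of ≥ `n_waso` epochs strictly after the onset epoch.
  Shorter wake runs count as sleep *for parameter purposes only*; epoch
  labels are never rewritten, so validation metrics are unaffected.
* **TST** = TIB − SL − WASO and **SE** = 100·TST/TIB, so
  SL + WASO + TST = TIB holds exactly on every input, PSG and activity
  alike (a property the tests assert on every random case).

The run-length defaults `n_sl = 4` and `n_waso = 5` (8 and 10 min) are the
optima of the published search, which `optimize_run_rule()` reproduces: for
each n in 1..10 it computes the cohort mean difference from PSG
(Δ = mean act − mean psg), a two-sided paired t-test, and ICC(2,1); n is
feasible when p ≥ 0.05 and ICC ≥ 0.6, and the feasible n minimizing |Δ|
wins, smallest n on ties.  `optimize_sleep_rules()` runs the search in two
stages — SL first, then WASO with each subject's onset held at the chosen
`n_sl` — because WASO is defined relative to the *optimized* onset.

The source phrase "continuously for more than *n* epochs" is ambiguous
between > n and ≥ n.  The package reads it as **≥ n**: under the strict
reading a single-epoch run would never qualify at n = 1, which contradicts
the search's own n = 1 grid point.  `strict_gt = TRUE` provides the literal
alternative everywhere the rule appears.

A related reading choice: PSG parameters are computed on the collapsed
2-min epochs (not the raw 30-s stages), matching the grid on which the two
methods are compared.

### Validation statistics

Sleep is the positive class: sensitivity = % of PSG-sleep epochs scored
sleep, specificity = % of PSG-wake epochs scored wake, agreement = % of all
epochs matching.  Per-stage agreement scores each PSG category against its
own target (sleep stages against S, wake against W), which makes the overall
agreement the epoch-count-weighted combination of the per-stage values — an
identity the tests assert.  Metrics are computed **per subject and then
averaged** across subjects (mean ± SD), matching how validation studies
report them; `pooled = TRUE` also tallies a single cohort-level confusion
table.  An absent denominator class (e.g. a night with no wake epoch) yields
a flagged `NA` that is excluded from cross-subject means.

The ICC form for method agreement is not dictated by the procedure, so the
package defaults to **ICC(2,1)** — two-way random effects, absolute
agreement, single measures — which penalizes systematic offsets between the
methods; `type = "ICC3"` (consistency) is available.  Both are computed from
the two-way mean squares, with significance from F = MSR/MSE on (n−1),
(n−1)(k−1) degrees of freedom, and both are tested against an independent
`aov()`-based decomposition.  Group comparisons use two-sided Student's
t-tests (pooled variance, df = nA+nB−2 unpaired; df = n−1 paired), with
zero-variance inputs handled exactly (t = 0, p = 1 when the means agree).

### Deriving a discriminant

`fit_discriminant()` reconstructs the derivation stage: rows are 2-min
epochs pooled across all training subjects (no per-subject weighting),
features are the five-epoch windows, labels are the collapsed PSG classes
(S = 0, W = 1).  The fit is Fisher's rule — direction
$w \propto S_\text{pooled}^{-1}(\mu_W - \mu_S)$, cut at the equal-cost
midpoint $c_0 = w\cdot(\mu_S+\mu_W)/2$ — followed by the rescaling
$w' = w/c_0$ so the boundary sits exactly at $z = 1$.  This midpoint
rescaling is a reconstruction: the original derivation reports all-positive
coefficients with a unit threshold, which is exactly what the rescaled
Fisher rule produces when wake activity exceeds sleep activity.  A
prior-weighted cut (shifting $c_0$ by the log prior odds) is available; with
it the rule is affine and the threshold absorbs the offset.  Degenerate
inputs are handled explicitly: a singular pooled covariance (integer counts
can collapse onto few distinct values) triggers a ridge refit with
λ = 10⁻⁶·trace(S)/5 and a warning; identical class means or a non-positive
cut are errors, since no unit-boundary rescaling exists.

`split_cohort()` provides the subject-level seeded split (sizes differing by
at most one) used by split-sample designs: derive on one half, validate on
the other.

## The simulator

`simulate_subject()` stands in for laboratory recordings.  It emulates the
*statistical structure the method assumes*, nothing more:

* a first-order Markov chain over the five stages at 30-s steps.  The
  default kernel was chosen for a healthy school-age regime: nights start
  awake with mean sleep latency ≈ 8–10 min, brief nocturnal awakenings, and
  a cohort mean PSG sleep efficiency near 90% (inside the 85–95% band the
  package's own tests check);
* one negative-binomial count per 2-min epoch, drawn from the law of the
  window's *dominant* stage (ties W, R, N1, N2, N3), rounded and clipped to
  0–31.  Per-stage means are ordered W > R > N1 > N2 > N3 and the child
  profile exceeds the adult profile in every stage.  Wakefulness in bed is
  strongly overdispersed (size 0.5): much of it is motionless, which is the
  recognized failure mode of actigraphy and what makes the shipped child
  coefficients produce the characteristic high-sensitivity,
  lower-specificity profile on simulated child cohorts;
* two RNG streams derived from the master seed — one for the stage chain,
  one for the counts — so changing the activity model leaves the hypnogram
  trace unchanged, and per-subject seeds derived from a cohort master seed
  so cohorts are reproducible.

What the simulator deliberately does **not** model: within-window stage
mixing (activity follows the dominant stage only), apnea or movement
disorders, circadian drift across the night, first-night effects, and any
particular child/adult activity *gap* magnitude (the profiles are tunable,
not calibrated to a published table).  Passing tests on simulated cohorts
therefore demonstrate that the pipeline's logic is correct and stable in the
regime the method assumes — they do not certify accuracy figures on real
recordings, which require the original instrument and population.

## Numerical and design choices

* Epoch indices are 0-based over half-open 2-min intervals; timestamps are
  ISO-8601; all durations are exact multiples of 2 min, so parameter
  identities hold in exact arithmetic.
* `align_series()` truncates to the shorter of the PSG and activity series
  with a warning on any length difference, and refuses differences beyond a
  tolerance (default 2 epochs) as recording faults: small drifts are routine
  device behaviour, larger ones indicate a misconfigured recording.
* Scoring compares z to the threshold with `>=` and no epsilon; score
  equality with an independent per-epoch loop is asserted to 10⁻¹²
  (double-precision summation order is the only permitted difference).
* Nights with no qualifying sleep onset are flagged rather than silently
  zeroed: SL/WASO/TST are `NA`, SE is 0, and downstream cohort statistics
  drop flagged values pairwise.

### Problem sizes used by the test suite

The suite exercises: all 625 collapse windows; 1,000 random series per edge
policy against the scoring loop oracle; 1,000 random binary series × n in
1..10 against the run-enumeration oracle; ICC/t-tests against closed-form
oracles on small worked tables; discriminant recovery on two homoscedastic
5-D Gaussian classes at 10⁴ epochs per class (relative L2 error ≤ 10%,
≥ 98% decision agreement with the generating rule on fresh draws); and a
complete 65-subject split-sample rehearsal (33/32 split, derive on A,
validate on B) checked for bit-exact reproducibility under a fixed seed.
These sizes give each stochastic check comfortable power while keeping the
whole suite around two minutes on one core.

## Known limitations

* The shipped child coefficients apply to waist-worn 2-min, 32-level count
  data; they do not transfer to wrist devices, other epoch lengths, or raw
  accelerometry.
* No rescoring corrections (e.g. post-hoc wake rescoring rules) are applied;
  the scoring rule defines none.
* The derivation stage guarantees the midpoint-rescaled Fisher form only;
  other LDA variants (least-squares on 0/1 labels) can be emulated but are
  not reconstructed.
* Printed accuracy tables from validation studies are not reproducible
  without the underlying recordings; the package's simulator reproduces the
  qualitative regime, not the published point values.
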