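---
title: "Methods: segmentation, outcomes and statistics for EQI contractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, outcomes and statistics for EQI contractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqitools)
```

This vignette is the package's account of its methods: the conventions and
rules it applies to raw dynamometer recordings, the statistical model it
fits, the mechanism behind the synthetic-data generator, and the design
choices made where the underlying procedures leave room. It states no
empirical results beyond what the package's tests and acceptance script
themselves compute.

## Sign convention

All internal computation is **plantarflexion-positive** with the neutral
ankle at 0°: plantarflexed angles and plantarflexion torques are positive,
dorsiflexed angles negative. Under this single convention the start of an
EQI contraction is a local *maximum* of the angle channel, the yield
proceeds downward, and total RoM is simply `start_angle - final_angle`,
always non-negative on a valid trial. Laboratories often quote final
(dorsiflexion) angles as positive magnitudes; that is a reporting choice —
take `abs(final_angle_deg)` at the presentation layer. Keeping one internal
convention and documenting the flip here avoids the classic sign bugs of
mixed conventions.

## Segmentation rules and their robustness parameters

Signals are processed **raw** — no filtering, no interpolation; a gap in the
time axis is a hard error. Any smoothing would have to be an explicit,
logged, opt-in step. Because the 100 Hz signals are unfiltered, the two
segmentation rules carry explicit robustness parameters:

* **Onset** (`detect_onset`): the first sample that is maximal within a
  ±`window` neighbourhood (default 0.25 s) *and* after which the angle falls
  by at least `min_drop` (default 1.0°) before the end of the trial. The
  neighbourhood makes "local maximum" well defined on noisy data; the
  confirmation drop rejects plateau edges and the rising flank. Ties within
  the window resolve to the earliest sample, so a flat apex is dated at its
  beginning. No onset is reported within the first `window` seconds: a
  recording that begins mid-decline has no identifiable apex, and a trial
  whose angle never falls (`min_drop` never reached — e.g. a pure hold) has
  no confirmable contraction at all.
* **Offset** (`detect_offset`): scanning strictly after the onset, the
  contraction ends at the earlier of (1) the angle reaching the subject's
  dorsiflexion limit within `rom_tolerance` (default 0.5° — exact equality
  with a calibrated limit is a measure-zero event on sampled data), or (2)
  torque below `half_load_fraction` (default 0.5) of the prescribed load
  continuously for `debounce` seconds (default 0.1 s, i.e. 10 samples; the
  offset is then the *first* sample of the sustained run). The debounce
  prevents a single noisy torque sample from terminating the contraction;
  whether the historical half-load rule meant instantaneous or sustained
  drops is not standardised, so the sustained reading is the package's
  choice, with `debounce = 0` recovering the instantaneous one. A
  simultaneous firing resolves to `end_of_rom`. If neither rule fires the
  segment is returned open-ended at the last sample and flagged.

Manual corrections — in laboratory practice done by visual inspection — are
replaced by `apply_override()`, which shifts indices, flags the segment
`manual_override`, stores an audit note, and preserves the original
decision.

## Outcome definitions

Over the segmented window `[onset, offset]`:

* **Total time** `(offset - onset) / sampling_rate` — a pure index
  difference, so overrides and rule changes propagate exactly.
* **Torque impulse**: composite trapezoid integral of the raw torque
  channel against the recorded time axis. The trapezoid rule is exact for
  affine integrands and has error at most `(h²/12)(b−a)·max|τ''|`
  otherwise (h = 0.01 s); both properties are asserted in the tests. It is
  also exactly additive over interior split points, which the tests use as
  an invariant.
* **Mean angular velocity**: the mean of |velocity| using the *recorded*
  velocity channel, not RoM/time. The dynamometer measures velocity as its
  own channel; the two definitions coincide on monotone motion (a tested
  identity, to 1 %) but the recorded channel remains meaningful if the
  yield briefly reverses. The magnitude is averaged because the protocol
  makes motion unidirectional; a signed mean would let measurement noise
  around holds cancel genuine yield.
* **RoM and endpoints**: angles read at the exact onset/offset samples with
  no local averaging, consistent with the no-filtering policy. Negative RoM
  is flagged `inverted_motion` rather than silently accepted.

## The statistical model

`mixed_rm_anova()` implements the univariate split-plot decomposition for
designs with one or two within-subject factors and an optional
between-subjects factor, via orthonormal contrasts: for each within effect
with contrast matrix *M* (columns orthonormal in cell space), the
subject-by-cell response matrix *Y* is reduced to scores *Z = Y M*; the
effect is the Type III test of the intercept of *Z* against the
between-group design, the effect-by-group interaction the Type III test of
the group term, and the error stratum the pooled within-group residual of
*Z* — the classical effect-by-subject-within-group term. The between effect
is tested on cell-averaged scores against subject-within-group.

Choices worth stating explicitly:

* **Type III (unweighted-means) hypotheses.** With unequal group sizes
  (e.g. 9 men vs 11 women) the weighted and unweighted formulations
  differ; general-linear-model software tests the unweighted one, and so
  does this package. A consequence is that the effect sums of squares only
  add up to the corrected total on orthogonal designs (equal group sizes or
  no between factor); the test suite asserts additivity exactly there.
* **Greenhouse–Geisser everywhere, ungated.** ε is estimated per within
  effect from the pooled covariance of its contrast scores,
  ε = tr(S)²/(q·tr(S²)), clamped to [1/q, 1], and the corrected p value
  (df multiplied by ε) is always reported next to the uncorrected one.
  Gating the correction on Mauchly's test would make the analysis path
  data-dependent; reporting both unconditionally is reproducible and at
  worst mildly conservative under sphericity (the null-calibration
  acceptance check verifies rejection rates stay near the nominal 5 %).
* **Mauchly's test** uses `W = det(S)/(tr(S)/q)^q` with the chi-square
  approximation on `k(k−1)/2 − 1` df, covariance pooled within groups. With
  two levels sphericity is trivial and the test returns not-applicable
  rather than a fabricated p value.
* **Post hocs**: paired t tests on subject-level means with the Bonferroni
  multiplier equal to the number of pairs in that factor's family only —
  the correction never spans families.
* **Estimated marginal means**: the response is averaged over the pooled
  within factors per subject first; cell estimates are means of those
  subject scores. The standard error uses the within-group variance of the
  subject scores at that within-level combination, pooled across groups
  (df = subjects − groups). A single ANOVA error stratum cannot represent
  the variance of a subject mean pooled over repetitions — it mixes four
  variance components — whereas this multivariate-model route is exact for
  balanced within-designs and robust to unequal group sizes. Shifting the
  response by a constant therefore shifts every estimate and leaves
  interval widths untouched (a tested equivariance).
* **Demographics**: Welch's t with Satterthwaite df (not the pooled-variance
  t), and Cohen's d with the **average-SD** denominator
  `(m₁ − m₂) / ((s₁ + s₂)/2)` by default — these are the variants that
  reproduce published demographic tables computed from group summaries; the
  pooled-SD d is available behind a flag. Both consume printed summary
  statistics directly, since raw demographic data are rarely shared.

Balanced completeness is a precondition, not a preference: a missing
within-cell is an error, never imputed.

## The synthetic-data generator

`simulate_study()` exists so that segmentation, outcomes and statistics can
be tested against a known ground truth. The mechanism is the smallest one
that reproduces the phenomenology of an EQI bout:

* isometric capacity `C(θ, t) = MVIC · (1 − g·θ) · (1 − f(t))`, with
  `g = force_length_gain` (default 0.024 /°) making the muscle stronger
  toward dorsiflexion;
* fatigue `f` integrating `fatigue_rate · torque/MVIC` over time (default
  0.018 /s at full effort), so sustained torque erodes capacity;
* a concentric push (15 °/s) from maximal dorsiflexion that stops where
  concentric capacity (isometric × `concentric_capacity_factor`, default
  0.93 — shortening costs force) meets the load: lower loads therefore
  reach more plantarflexed start angles, and the 7 % concentric deficit
  leaves an isometric reserve that produces the initial hold;
* a yield phase where the joint drifts dorsally at
  `yield_gain · (load − C)` °/s (default 2 °/s/Nm). Because the deficit
  stays small, the motion is quasi-static: holds re-establish whenever the
  force–length gain catches the load, and the alternation of near-zero and
  slow-yield phases emerges from the mechanism rather than being scripted;
* partial recovery between repetitions: 85 % of the fatigue newly acquired
  in a repetition is recovered in the rest interval, the remainder carries
  over, producing the progressive decline of duration, impulse and RoM
  across repetitions 1→3;
* an optional stochastic give-up event (off by default) that collapses the
  voluntary drive mid-contraction, exercising the half-load offset rule.

The measurement model reflects how dynamometers actually err: torque and
velocity carry **bounded** multiplicative noise, `x·(1 + cv·U)` with
`U ~ Uniform(−1, 1)` and cv = 2 % — bounded support makes worst-case
assertions on peak extraction possible (a best-of-three MVIC peak can be at
most cv above the true capacity) — while the angle channel is an encoder
readout, quantised at 0.01° with no proportional noise. Proportional noise
on a near-flat angle plateau would make the apex unidentifiable at the
sample level, which is not how position encoders fail.

Default magnitudes are calibrated to the population such protocols study:
true MVIC means of 200 Nm (men) and 157 Nm (women) with 17 % between-subject
CV, RoM limits near +20°/−12° (men) and −15° (women; the deeper
dorsiflexion in women drives the sex effect on the final angle), loads of
75 %/90 % of the measured pre-exercise best peak (hence mean prescribed
loads near 132 and 161 Nm), EQI durations of tens of seconds, and ranges of
motion near 20° (75 % load) vs 15° (90 %). Sample sizes follow the emulated
protocol: 20 subjects (9 men, 11 women) × 2 legs (load assignment
counterbalanced) × (3 pre-MVIC + 3 EQI + 3 post-MVIC) = 360 trials.

What the generator does **not** emulate — and hence what passing tests do
not show about laboratory data: no tremor or EMG-like torque oscillation
beyond bounded noise; no Hill-type activation dynamics or tendon
compliance; no load-by-repetition interaction structure other than the one
the fatigue mechanism implies (the simulated decline is steeper at 75 %,
i.e. the generator produces a load×repetition interaction that real data
may not show); repetition decline is strictly progressive, whereas
laboratory bouts often show repetitions 1 and 2 as equivalent with only the
third shorter; and recovery at the post-exercise MVIC is complete by
default, encoding the absence of a pre/post effect rather than predicting
it.

## Numerical choices and degenerate inputs

* Time-axis uniformity is enforced to 1e-9 s; trial CSVs are written with
  15 significant digits so write→read round-trips preserve channels and
  impulses to 1e-9.
* ε is clamped to its theoretical range [1/q, 1]; Mauchly's W to [0, 1];
  log W is guarded against exact zero.
* Paired t post hocs with zero-variance, zero-mean differences return
  p = 1 (identical level values) instead of 0/0.
* The onset tie-break is "earliest sample of the maximal plateau"; the
  offset tie-break between simultaneous rules is `end_of_rom`.
* Infeasible simulation loads (above capacity at every angle) error
  immediately; a zero-fatigue simulation that can never yield ends at
  `t_max` with an open-ended truth log.

## Problem sizes in the tests and acceptance script

The suite sizes its simulations to what the questions need: the ANOVA
engine is verified against a brute-force projection oracle on ≤6-subject
toy designs (where the oracle is exact and cheap); null calibration of the
corrected tests uses 1 000 simulated null studies at the emulated design
size (n = 20, 2×3 within, 9/11 between); effect-direction and power checks
under the simulator defaults use 200 full end-to-end studies; segmentation
is checked against the exhaustive per-sample scan on 100 simulated trials,
a fifth of them with the give-up event enabled so both offset rules are
exercised. Distributional facts (lognormal MVIC means, order-statistic bias
of best-of-three peaks) use 10 000 and 1 000 draws respectively.

## Known limitations

The statistics cover balanced complete designs only — no missing-data
handling, no Huynh–Feldt correction, no REML mixed models; the CSV dialect
is the package's own neutral format, not a vendor export; and the simulator
is a phenomenological tool for validating the pipeline, not a predictive
physiological model. Conclusions about real contractions should rest on
real recordings processed through the same interfaces.
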