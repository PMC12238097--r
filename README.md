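# eqitools

Analysis of eccentric quasi-isometric (EQI) contractions recorded on an
isokinetic dynamometer, for researchers in biomechanics and exercise
physiology.

An EQI contraction is performed against a dynamometer in isotonic mode: the
machine applies a constant resisting torque (a fraction of the participant's
maximal voluntary isometric contraction, MVIC), the participant pushes
concentrically to the most shortened position they can reach under that
load, then holds it, yielding slowly through alternating isometric holds and
eccentric phases until the end of their range of motion (RoM). `eqitools`
turns the raw 100 Hz angle/velocity/torque recordings of such protocols into
the standard outcome variables and fits the accompanying statistical models:

* **Segmentation** — contraction onset at the first local maximum of the
  angle signal (the apex of the concentric push, with a configurable
  neighbourhood and confirmation drop, since signals are analysed
  unfiltered); offset when the angle reaches the dorsiflexion limit or when
  torque stays below 50 % of the prescribed load for a debounce period.
  Programmatic overrides replace visual artefact correction, with an audit
  trail.
* **Outcomes** — total contraction time *T* (s); torque impulse
  *J = ∫ τ(t) dt* (Nm·s, composite trapezoid rule); mean angular velocity
  (°/s, mean |ω|); total RoM with its start and final angles (°).
* **Statistics** — mixed repeated-measures general linear models
  (within-subject: load 75 %/90 % MVIC and repetition 1–3; between-subject:
  sex), with split-plot sums of squares, Mauchly's sphericity test *W*,
  Greenhouse–Geisser ε (always reported, df corrected as ε·df), partial
  η² = SS_effect/(SS_effect+SS_error), Bonferroni-corrected pairwise post
  hocs, estimated marginal means with 95 % CIs, and Welch *t* / average-SD
  Cohen's *d* for group demographics.
* **Simulation** — a mechanistic contraction generator
  (capacity = MVIC · force–length factor · (1 − fatigue), quasi-static
  yield proportional to the capacity deficit, partial recovery between
  repetitions) that emits full synthetic studies with ground-truth event
  logs, so every stage of the pipeline is testable without laboratory data.

## Worked example

Simulate a 20-subject study (9 men, 11 women, two legs with the 75 %/90 %
load assignment counterbalanced), extract outcomes, and fit the model for
total contraction time:

```r
library(eqitools)

sim <- simulate_study(sim_config(seed = 42))
ext <- run_extract(sim$trials)
head(ext$study_table, 4)
#> # A tibble: 4 × 11
#>   subject_id sex   leg    load repetition total_time_s impulse_nms
#> 1 s01        M     left     75          1         26.5       5026.
#> 2 s01        M     left     75          2         22.4       4255.
#> 3 s01        M     left     75          3         19.0       3599.
#> 4 s01        M     right    90          1         15.4       3496.

fit <- mixed_rm_anova(ext$study_table, dv = "total_time_s",
                      within = c("load", "repetition"), between = "sex",
                      subject = "subject_id")
fit
#> Mixed repeated-measures ANOVA: total_time_s ~ load * repetition * sex (n = 20 subjects)
#>               effect       F df_num df_den epsilon_gg     p_gg partial_eta_sq
#>                  sex   3.484      1     18         NA 7.84e-02          0.162
#>                 load 867.978      1     18        1.0 1.10e-16          0.980
#>             load:sex   0.783      1     18        1.0 3.88e-01          0.042
#>           repetition 478.772      2     36        0.5 2.03e-14          0.964
#>       repetition:sex   3.460      2     36        0.5 7.93e-02          0.161
#>      load:repetition 905.438      2     36        0.5 7.44e-17          0.981
#>  load:repetition:sex   0.900      2     36        0.5 3.55e-01          0.048
```

Contractions at 75 % MVIC last longer than at 90 % (here roughly 24 s vs
14 s on average), and each repetition is shorter than the one before —
`F` is the split-plot F statistic, `p_gg` its Greenhouse–Geisser-corrected
p value, and `partial_eta_sq` the effect size (values above 0.14 are
conventionally "large"). `tidy(fit)` returns the same table as a tibble,
`autoplot(fit)` plots the effect sizes, and
`bonferroni_posthoc(ext$study_table, "repetition", "total_time_s",
"subject_id")` locates which repetitions differ.

Demographic comparisons work directly from printed summary statistics, e.g.
body height of 9 men (183.2 ± 4.5 cm) vs 11 women (169.9 ± 5.8 cm):

```r
welch_t(183.2, 4.5, 9, 169.9, 5.8, 11)
#>       t    df         p
#> 1  5.77  18.0 0.0000181
cohens_d_avgsd(183.2, 4.5, 169.9, 5.8)
#> [1] 2.582524
```

A complete, reproducible end-to-end run (simulate → extract → analyse, with
provenance and config hashes written alongside the outputs):

```r
run_all(sim_config(seed = 1), run_config(seed = 1), out_dir = "eqi_run")
```

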