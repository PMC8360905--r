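---
title: "Modelling two-dimensional reward choice with scalar utility theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-dimensional reward choice with scalar utility theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sutility)
```

## The model and its assumptions

`sutility` models binary foraging choices between rewards that differ in
volume (µL) and probability. The core assumption is the *scalar property*:
a remembered magnitude `r` is represented as a normal distribution
`N(r, γ r)` whose standard deviation grows proportionally with its mean, so
discriminability depends on the *relative* difference between options
(Weber-law behaviour). The constant of proportionality γ, the coefficient of
variation, is the shared free parameter of all six decision rules.

Action selection is single-sample: each option contributes one draw from its
remembered-value distribution and the larger draw wins. Partial preferences
arise naturally — the probability that the better option wins is
`Φ((μ_A − μ_B) / (γ √(μ_A² + μ_B²)))` for two independent scalar traces —
without any explicit softmax or noise parameter.

The six rules (`model_kinds()`) differ only in how the two dimensions enter
the remembered value:

* **sev** multiplies the probability estimate into the volume trace
  (`π · N(v, γv)`): a single expected-value memory, fully integrative.
* **2scal** keeps one scalar trace per dimension and multiplies the two
  samples (`N(π, γπ) · N(v, γv)`). Also integrative, but noisier on both
  dimensions. Per-dimension coefficients (`gamma_p`, `gamma_v`) are
  supported; they default to a single shared γ, the simplification used
  throughout.
* **rnonc** uses a single dimension per decision, volume with probability
  `theta_v` (default 0.5), probability otherwise.
* **wta** uses the dimension with the higher salience
  (`(max − min)/mean`, identical to the relative-intensity measure for two
  options) with probability `theta` (default 1), and reverts to a fair coin
  when the saliences are equal.
* **pfirst / vfirst** are lexicographic: they check their priority
  dimension's salience against a threshold (default 0.8, the psychometric
  threshold for probability discrimination), fall through to the other
  dimension, and revert to a fair coin when neither salience clears its
  threshold.

Virtual mice start in a learned state with remembered values equal to the
true reward dimensions. Learning, satiety, travel and spatial layout are
deliberately outside the model: the simulated environment is a bare sequence
of binary choices, which is why reward outcomes need not even be drawn when
predicting post-acquisition performance.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `gamma` | dimensionless CV | rule-specific (see `reference_models()`: sev 1.05, 2scal 0.65, rnonc 0.05, wta 0.7, pfirst 0.95, vfirst 0.5) | published grid-search calibrations against probability-baseline performance |
| `theta_v` | probability | 0.5 | unbiased dimension choice in rnonc |
| `theta` | probability | 1 | strict winner-takes-all |
| `salience_threshold` | dimensionless | 0.8 | psychometric threshold for probability discrimination |
| `n_mice`, `n_choices` | count | 100, 100 | the study's simulation scale; medians of 100 mice stabilise predictions to ~±0.01 |
| sesoi | performance units | 0.1 | smallest effect of interest for equivalence tests |
| slope sesoi | performance / background level | 0.125 | a 0.1 change across the background-level range 0.2–1 |

## What the synthetic-data generator emulates

`generate_cohort()` reproduces the statistical structure of the home-cage
design: cohorts of 8 mice, four dispensers of which two reward, sessions of
`N(477, 163)` pokes (clipped at 1) with a per-session proportion
`N(0.79, 0.10)` (clipped to [0, 1]) of pokes at the rewarding dispensers,
every condition presented on an acquisition day followed by a reversal day
on which only the two rewarding dispensers swap, and reward outcomes drawn
from the five fixed 20-element pseudo-random sequences so that whole cycles
deliver the programmed probability exactly. Choices between the two
rewarding dispensers follow a configurable ground-truth `sut_model`, which
is what makes the full pipeline testable: the post-cutoff discrimination
performance of a generated cohort must close the loop on the generating
model's closed-form choice probability, and the tests check exactly that.

What it does **not** emulate: learning and the initial acquisition ramp
(virtual mice are stationary from the first poke, so the acquisition cut-off
removes information-free pokes rather than a learning curve), satiety-driven
declines in poke counts at high volumes (available only as the
`volume_jitter_sd`-style config hooks are for delivery noise; a
volume-dependent poke-count mean is not modelled), visit durations,
social interactions, and hardware artefacts. Passing pipeline tests
therefore show the *analysis machinery* is correct and unbiased, not that
real mice behave like any of the six rules.

Timestamps are synthetic (exponential inter-poke gaps scaled to an 18-h
session) because every analysis uses poke order only.

## Numerical choices

* **No truncation at zero.** Scalar traces are sampled as plain normals even
  at γ = 2, where negative draws are common. Truncation is never part of the
  model definition and would invalidate the closed-form oracle; a
  `truncate_at_zero` flag exists for sensitivity checks and switches
  `choice_probability()` to `NA`.
* **Ties.** Exact sample ties (possible in floating point, probability zero
  in theory) and all random-choice branches resolve by a fair coin.
* **Salience comparisons.** Equality of saliences in `wta` is tested with a
  numerical tolerance (`all.equal`), because design pairs chosen to have
  *equal* relative intensity (4 vs 10 µL and 0.2 vs 0.5) differ in the last
  floating-point bit. Lexicographic thresholds are strict (`>`), so a
  salience exactly at threshold does not fire.
* **wta with θ < 1** selects the *lower-salience dimension* with probability
  1 − θ rather than reverting to random choice; the published calibration
  θ = 1 makes the two readings identical, and the dimension-mixture reading
  keeps the closed form a clean two-component mixture.
* **Acquisition cut-offs** are applied per drinking session to pokes at the
  rewarding dispensers. The windowed variant keeps pokes 151–250: exactly
  100 pokes starting at the same point as the default policy. The
  criterion-block variant uses strict `>` on non-overlapping 20-poke blocks
  and retains pokes after the second block of the first qualifying pair.
  Counts are pooled across the two condition days; records with no
  surviving pokes are flagged and excluded from group statistics rather
  than imputed.
* **Bootstrap.** Percentile bootstrap of the mean with 1000 resamples; the
  90% and 95% intervals are quantiles of the *same* resample set, which
  guarantees nesting and makes the four-outcome TOST classification
  well-defined. Classification bounds are inclusive (a degenerate CI exactly
  on a sesoi bound counts as bounded).
* **Familywise correction** divides α by `max(k²/4, 1)` so that k ≤ 2 never
  inflates α. The count of "problematic" cases defaults to a documented
  heuristic (equivalence supported and a 90% CI endpoint within 0.02 of a
  sesoi bound) and can always be set directly.
* **Grid search.** γ is calibrated on the inclusive grid 0.05–2.00 in steps
  of 0.05 (40 points; the smallest published calibration, 0.05, is itself a
  grid point). Per-cell medians are smoothed over the grid with `loess`
  (degree 1, span 0.75) before the RMSE argmin is taken. Observations enter
  the RMSE as per-condition means across mice; RMSE ties in the ranking are
  broken by canonical model order and flagged.
* **Seeding.** Every stochastic unit (mouse, session, grid cell, bootstrap)
  draws from a sub-stream derived by `substream_seed(seed, index)`, a
  Lehmer-style mix kept below 2³¹. Growing a simulation (more mice, more
  grid cells) therefore never reshuffles existing units, and the pipeline is
  byte-reproducible from one master seed.

## Design choices where the design was open

* **Sequence cursors** are per (mouse, dispenser) and restart at position 0
  each session. Cursor scope has no observable effect on any statistic used
  downstream (only cycle alignment changes), and a session-local cursor
  keeps sessions independent.
* **Experiment-3 cohort-2 relevant volumes** exist in two published
  versions, 4.7/9.4 and 4.8/9.6 µL; both are available and the 4.7/9.4 pair
  is the default (`cohort2_exp3_source`).
* **Condition pairings.** The congruent condition pairs 20 µL @ 0.5 against
  4 µL @ 0.2; the incongruent condition pairs 20 µL @ 0.2 against
  4 µL @ 0.5, so the higher-volume option is also the more profitable one in
  experiments 1 and 4 and exactly equally profitable in experiment 2. In
  equal-expected-value conditions the higher-volume option defines the
  scoring direction, and contrasts against probability baselines re-score
  the incongruent performance as `1 − p`.
* **Probabilities without a stored sequence** (anything outside
  0.2/0.3/0.5/0.7/0.8/1.0) fall back to Bernoulli draws with a warning, so
  exploratory conditions remain usable.
* **Non-rewarding dispensers** are options with probability 0; they are
  excluded from choice simulation, and the analysis ignores their pokes.

## Validation scale

The package validates itself at these problem sizes, chosen to give each
check clear resolution while staying light: oracle agreement between
simulated frequencies and closed forms at 10⁵ draws per cell over a
kind × γ × option-pair grid; γ recovery over 50 seeds per rule with
calibration data generated at the study scale (100 × 100) and grid cells
simulated at 25 mice × 40 choices, requiring the fitted γ within two grid
steps of the generating value 0.5 (a mid-grid value at which every rule's
performance curve is informative); model recovery over 100 ranking
replicates per rule at 50 mice × 50 choices with the published γ per rule;
TOST calibration over 500 replicates of 24 zero-mean differences with
sd 0.141, where the support rate should sit near the design power of 0.95;
and pipeline closure on a full default cohort (8 mice × 25 conditions × 2
days), where every condition's across-mice mean performance must fall
within 3 standard errors of the generating model's closed form.

## Known limitations

* The 2scal rule has no analytic choice probability; its checks are purely
  Monte-Carlo (reproducibility and dimension-order invariance).
* γ is only identifiable where the performance curve still moves: data at
  chance level push the fit to the flat end of the grid, and a generating γ
  in a saturated region (e.g. very small γ on a high-salience pair) is
  recoverable only up to that plateau.
* Bootstrap percentile intervals on 8–24 mice are slightly narrow compared
  with exact intervals; the TOST calibration check quantifies the net effect
  (support rate ≈ 0.93–0.95 under true equivalence).
* The generator's mice are exchangeable: no individual γ, side bias or
  condition-order effects, which real cohorts certainly have.
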