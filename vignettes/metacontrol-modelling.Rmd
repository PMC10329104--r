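---
title: "Modelling stake-sensitive arbitration in the two-step stakes task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stake-sensitive arbitration in the two-step stakes task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacontrolr)
```

# The task and the scientific question

The environment is a two-stage decision task built for middle childhood.
Four spaceships are shown in two fixed pairs; within each pair one ship
always flies to the red planet and the other to the purple planet, and
children are told (and almost always remember) this deterministic map.
Each planet pays 0–9 treasures according to its own drifting reward
series, so the better planet keeps changing and has to be tracked. A
per-trial stake cue multiplies treasures into points: 1x on low-stake
trials, 5x on high-stake trials, in a random 50/50 schedule.

The deterministic transitions make the model-based/model-free
dissociation sharp. A planner values a ship by the current value of its
destination planet, so a surprising reward on the *orange* ship (pair B,
red planet) immediately raises the value of the *dark blue* ship
(pair A, red planet). A cache-based learner updates only the ship it
chose, and cannot transfer anything between pairs. The stakes turn this
into a question about *arbitration*: if planning is costly, a rational
child should plan more when a trial is worth five times as much. The
package's central quantity is therefore the stake contrast of the
model-based weight, `metacontrol = w_high − w_low`.

# The generative agent

`simulate_subject()` implements the hybrid agent:

- Model-free values `Q_MF` (one per ship, hence per pair) follow a
  two-step temporal-difference rule with a single learning rate `α`
  shared across stages and an eligibility trace `λ`:
  first `Q_MF ← Q_MF + α(V(dest) − Q_MF)` with the *pre-update* planet
  value, then `V(dest) ← V(dest) + α(r − V(dest))`, then
  `Q_MF ← Q_MF + αλ(r − V(dest_pre))`.
- Model-based values are read off the transition map:
  `Q_MB(ship) = V(transition(ship))`.
- Choice is a softmax over
  `β[w Q_MB + (1−w) Q_MF] + π · same_planet + ρ · same_key`, with
  `w = w_high` on high-stake trials and `w_low` otherwise. `π` rewards
  repeating the previously visited planet's role within the shown pair;
  `ρ` rewards repeating the physical response side, which the simulator
  randomizes per trial.

Two modelling commitments deserve justification:

- **Learning is stake-free.** The learning signal is treasure scaled to
  [0, 1] (`treasure/9`); the 5x multiplier affects awarded points only.
  Coupling the stake into the TD signal would confound reward
  amplification with arbitration and make the two weights partially
  redundant — the stake must enter *only* through the choice of `w` for
  the metacontrol contrast to be interpretable.
- **Initialization at 0.5.** All cached and planet values start at the
  midpoint of the scaled reward range, so the first trial carries no
  directional bias and a `β = 0` or value-indifferent agent is exactly
  at chance.

## Tunable parameters

| parameter | meaning | range | population default |
|---|---|---|---|
| `alpha` | learning rate (both stages) | [0, 1] | logit-normal(−0.2, 0.6) |
| `beta` | softmax inverse temperature on [0, 1]-scaled values | [0, 20] | lognormal(log 4, 0.3) |
| `lam` | eligibility trace | [0, 1] | logit-normal(0, 0.7) |
| `w_low`, `w_high` | model-based weight per stake | [0, 1] | see cohort section |
| `pi` | planet-level choice stickiness | [−5, 5] | N(0.2, 0.2) |
| `rho` | response-key stickiness | [−5, 5] | N(0, 0.2) |

The task constants — 0–9 treasure range, 5x stake, 50/50 stake schedule,
200 trials, walk step SD 2 with reflecting bounds — are the convention
of this task lineage; all are exposed in `task_config()`.

## Numerical choices

- **Reflection.** A proposed step that crosses a bound is folded once at
  that bound (`2·lo − y` or `2·hi − y`). A step so large that one fold
  cannot return it to the interval raises a classed error instead of
  iterating: silently multi-folding would distort the step distribution
  precisely when the user has configured a physically implausible walk.
  At `walk_sd = 5` on a width-9 interval such steps occur about once per
  few thousand trials, so very long sessions at extreme SDs are
  deliberately refused rather than silently bent into range.
- **Observed treasure** is the latent walk rounded to the nearest
  integer (children see whole treasure pieces); the walk itself stays
  continuous, and the trial table stores the walk at 4 decimals so CSVs
  round-trip bit-exactly.
- **Likelihood.** The compiled likelihood (`src/nll.cpp`) and a plain-R
  reference built from the exported agent primitives are kept as two
  independent routes; tests require agreement to 1e-10. Missed trials
  contribute no likelihood and trigger no update — children receive no
  reward on them, so there is nothing to learn from.
- **Fitting.** Plain MLE with L-BFGS-B in a transformed space (logit for
  unit-interval parameters, log for `β`, identity for `π`, `ρ`) under
  box bounds (logit in [−8, 8], `β ≤ 20`, `|π|, |ρ| ≤ 5`), 20 uniform
  seeded restarts, ties broken by restart index, objective tolerance
  ~1e-6. MAP with population priors is a pluggable alternative but out
  of scope. If a session has no trial of one stake condition, that
  weight is flagged unidentified and the metacontrol score is `NA`
  rather than a bound artefact.

# The synthetic cohort: what it states and what it can show

`generate_cohort()` draws a cohort of 69 children aged 6.19–12.61 with
the individual-difference structure the downstream inference assumes:
latent Gaussian scores pass through a Gaussian copula with target
correlations — age with the model-based weight 0.25, age with
metacontrol 0, a standardized Flanker-type inhibition cost with
metacontrol 0.42, and standardized left/right dorsolateral-prefrontal
thickness proxies with metacontrol 0.37/0.42 — then map to observables:
age uniformly over the range, `w_low` through a logistic link, and
`w_high = clip(w_low + metacontrol, 0, 1)`.

Choices a user should know about:

- **Weight dispersion.** The latent logit SD of `w_low` is 1.6, which
  makes the weight distribution near-flat on [0, 1]. Fitted weights in
  this task family are strongly dispersed, often piling near both ends,
  so a tight bell around 0.5 would be the unrealistic option.
- **Metacontrol SD 0.25.** Individual stake contrasts spanning roughly
  ±0.5 match the spread such studies display; an SD much larger would
  imply children whose two weights are essentially unrelated.
- **Clipping artefact.** Because `w_high` is clipped into [0, 1], the
  realized metacontrol score picks up a small negative correlation
  (magnitude ≈ 0.09) with `w_low` and with anything correlated with it
  (age). This is a structural property of bounded difference scores,
  not a bug; the age–metacontrol "null" in the generator is therefore a
  near-null.
- **Thickness proxies are standardized synthetic scores**, not
  morphometry: no images, surfaces or atlases are simulated, so brain
  results here are calibration checks of the *pipeline*, never of any
  anatomical claim. Sex is Bernoulli(35/69) and has no generative
  effect.

A green end-to-end test therefore establishes that the pipeline
(generate → simulate → fit → correlate → mediate) preserves the signs
and rough magnitudes of the planted structure — not that any empirical
cohort behaves this way, and not that effects of this size are
detectable at n = 69 (they mostly are not; the suite tests the reliable
form at n = 500).

# Behavioural markers

The corrected reward rate is obtained treasure minus the per-trial mean
of the two planets' available treasure, averaged over non-missed trials:
zero is chance by construction, and the metric lives on the treasure
scale so the stake schedule's luck cannot contaminate it. An alternative
baseline (the richer planet's payout, `method = "max"`) is available;
its chance level is negative, which is why it is not the default.

The stay-probability analysis regresses planet-level staying on the
previous scaled reward with separate slopes for same-pair and
different-pair transitions. The different-pair slope (the
generalization index) is the model-agnostic marker of planning — but
with serially correlated reward walks it is upward-biased for *any*
value-persistent agent, because the previous reward also proxies the
planet's current richness, which cached values track. Simulation puts
planners several times above cachers (≈ 3.9 vs ≈ 0.9 at the defaults);
the index separates strategies by magnitude, not by a sharp zero, and
conditioning on observable walk state does not remove the residue.

# The inference toolkit

`pearson_test()` (Fisher-z intervals), `one_sample_t()`/`welch_t()`
(Welch–Satterthwaite df, Cohen's d with the average-variance
standardizer), `bonferroni_threshold()` and `mediation()` (OLS paths,
`indirect = a·b`, percentile bootstrap over paired resamples, default
5000; the decomposition `c = c′ + a·b` is exact for OLS) mirror a
developmental study's reporting format. p-values below 1e-15 print as a
bound.

`correlation_sample_size()` is exact: it integrates the sampling density
of the correlation coefficient (Hotelling's form; the Gauss
hypergeometric factor is summed directly, which converges fast because
its third argument grows with n) above the t-based critical value. The
one-tailed design question "how many subjects for 90% power at
ρ = 0.39" gives 53; the Fisher-z approximation is typically 1–2
subjects more conservative (54 here), which is documented rather than
asserted as equality. A seeded Monte Carlo oracle
(`mc_correlation_power()`) cross-checks the integral in the tests and
the acceptance report.

# Known limitations

- Parameter recovery of the stake-conditioned weights at 200 trials is
  modest: with ~100 trials per stake condition and `β ≈ 4`, the
  truth–estimate correlation plateaus near 0.5 for `w_low` and the
  metacontrol score even when all other parameters are fixed at truth —
  a data limit, not an optimizer limit (fits are never beaten by the
  generating parameters; recovery climbs to ~0.74/0.61 at 800 trials).
  Cohort-level correlations with fitted scores are correspondingly
  attenuated by roughly half.
- The generator plants linear-Gaussian structure only; real cohorts
  have heavier tails, measurement error in the battery scores, and age
  effects on nuisance parameters (e.g. `β`) that are deliberately not
  modelled.
- No hierarchical fitting, no model comparison, no reaction times, no
  imaging machinery.
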