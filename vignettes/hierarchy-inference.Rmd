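---
title: "Inferring resident hierarchies from correction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring resident hierarchies from correction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pullup)
```

## The problem

Residential therapeutic communities (TCs) treat substance abuse and
criminal behaviour through structured peer feedback: residents write dated
"corrections" to peers who break community norms, a committee reviews
them, and they are announced publicly. Clinical theory holds that a
resident hierarchy emerges from these exchanges — senior residents correct
junior ones far more than the reverse — and that climbing this hierarchy
reflects treatment progress. `pullup` operationalises that idea: it infers
each resident's weekly hierarchy position from the directed correction
network and relates position, and movement in position, to the binary
outcome that matters clinically, graduation.

## From events to weekly networks

The atoms are `(date, sender_id, receiver_id)` rows. Self-corrections are
dropped at parse time with a counted reason; events naming residents
absent from the roster, or dated outside either participant's
`[entry_date, exit_date]` tenure, are dropped by `cross_validate()` under
distinct reasons. Out-of-tenure events are dropped rather than treated as
fatal because archival clinical records plausibly carry entry/exit
boundary noise; the validation report preserves auditability. The drop
rule for events spanning a resident's exit week is our convention — event
sources rarely document theirs.

Days are aggregated into half-open one-week windows `[start, start + 7d)`
anchored at the earliest roster entry, tiling the observation span. The
anchor is arbitrary — any fixed anchor removes weekly periodicity equally
— but it must be fixed for reproducibility. Within a window, repeated
corrections between the same ordered pair accumulate as integer edge
weight (a `binary_edges` flag collapses them for sensitivity analysis),
and **every** resident whose tenure overlaps the window is a node, even
with no corrections that week: a resident's centrality must exist for
every tenure week or per-resident means are ill-defined.

## Centrality on reducible weekly graphs

Weekly correction graphs are sparse, mostly acyclic, and often
disconnected. Plain eigenvector centrality is ill-posed there: on a
nilpotent adjacency matrix the leading eigenvector is identically zero,
and on reducible matrices it need not be unique. We therefore score each
week with the leading eigenvector of

$$M = W^\top + \varepsilon J,$$

where $W$ is the weekly weight matrix, $J$ the all-ones matrix and
$\varepsilon > 0$ a small floor. $M$ is then strictly positive, hence
primitive, and Perron–Frobenius guarantees a unique, strictly positive
leading eigenvector. The transpose implements the direction convention
that makes the pecking-order narrative come out right: a node's score
aggregates the scores of the nodes that *correct it*, so the resident
corrected by heavily-corrected peers scores highest and sits lowest in
the hierarchy. On the four-bird example (C→B, D→B, B→A) the scores order
A > B > C = D at every $\varepsilon$ we test ($10^{-2}, 10^{-4},
10^{-6}$).

Parameters, with defaults:

- `epsilon = 1e-4` (dimensionless, relative to unit edge weight). Small
  enough to leave orderings on observed edges intact, large enough to keep
  the computation numerically comfortable. It is configurable; weekly
  scores for isolated residents equal the ε-floor value, and the scale
  invariance `scores(cW, cε) = scores(W, ε)` holds exactly, so ε also sets
  the "no corrections" baseline.
- Scores are **max-normalized** (largest = 1 per week). This matches
  summary tables in which maximum-centrality means are bounded by ~1 and
  puts all four hierarchy measures on [0, 1].

### Numerical scheme

The Perron vector is computed by the power method accelerated with
repeated matrix squaring: normalize `A = M / max(M)`, square and
renormalize, and read off `x = A 1` (max-normalized) until successive
vectors change by less than `tol = 1e-12`; `max_iter = 200` caps the
squaring steps, i.e. an effective matrix power of $2^{200}$. The
acceleration matters: small integer-weight weekly graphs routinely contain
two disjoint cycles with *exactly tied* leading roots, split only at order
ε by the coupling term, so plain power iteration has convergence ratio
$1 - O(\varepsilon)$ and cannot reach $10^{-8}$ accuracy in reasonable
time at $\varepsilon = 10^{-6}$. Squaring turns that ratio into
$(1 - O(\varepsilon))^{2^k}$ and converges in a few dozen steps. The
tolerance is set at 1e-12, below the 1e-8 agreement we require against a
full dense eigendecomposition oracle, because the per-step change
overstates proximity to the fixed point when the spectral gap is small.
Degenerate inputs: a single node scores 1; an edgeless week scores all
residents 1 (symmetry under $\varepsilon J$); `epsilon <= 0` is refused
rather than silently computed, since uniqueness is then not guaranteed.

## The four hierarchy measures

For each resident we take the maximum and the mean weekly score over the
full tenure, and over the **last four** tenure weeks ("last month"):
`max_ec`, `mean_ec`, `lm_max_ec`, `lm_mean_ec`. Residents with fewer than
four scored weeks use their whole tenure for the last-month measures —
we keep short stays rather than silently dropping them, and a `min_weeks`
argument supports exclusion-based sensitivity analysis. Tenure means
include correction-free weeks at the ε-floor score, consistent with the
trajectory definition. `lm_max_ec <= max_ec` holds exactly (a subset
maximum), which is the deterministic half of the climb hypothesis; the
stochastic half is the signed-rank decline test.

## Inference

**Climb.** Overall vs last-month centrality is compared within resident by
a Wilcoxon signed-rank test. Zero differences are dropped before ranking
(Wilcoxon's convention and the common statistical-package default);
absolute differences are ranked with average ranks for ties; V is the sum
of positive-difference ranks; p comes from the normal approximation with
tie-corrected variance and a 0.5 continuity correction. The normal
approximation is accurate here because paired samples are hundreds of
residents; our tests verify it against exact $2^n$ enumeration at small n,
where its worst-case error is below 0.03 for $n \ge 7$ (it can reach
0.036 at $n \le 6$ — an intrinsic property of the approximation).

**Graduation.** Four logistic regressions of `graduated`, one per
hierarchy measure, each with the same controls: `age` (years), `lsi_r`
(LSI-R score, points), `race_minority` (binary; minority pooled as one
indicator, consistent with reporting race as a single proportion),
`days_in_program` (raw days — coefficients of a few hundredths per day are
the expected scale). Days in program is controlled because it correlates
with hierarchy position and is almost tautologically longer for graduates.
Fitting is maximum likelihood via IRLS (`stats::glm`); we report Wald
standard errors and p-values with 0.05/0.01/0.001 stars, log-likelihood,
deviance = −2·logLik, AIC = deviance + 2k and BIC = deviance + k·log n.
Suspected separation (|β| > 15) flags the fit non-converged but still
reports estimates. No multiple-testing correction is applied across the
four models — they are four views of one construct, not independent
hypotheses — and this is a deliberate, documented caveat.
Predicted-probability curves evaluate the inverse-logit linear predictor
over a measure grid at mean covariates.

## What the simulator emulates — and what it does not

`simulate_unit()` generates a unit with the statistical structure the
analysis assumes, so that every stage is testable without clinical data:

- **Arrivals/exits:** daily Poisson arrivals (`arrival_rate = 1.2`/day)
  thinned by bed availability (`n_beds = 80`), so occupancy never exceeds
  capacity; tenures truncated-normal (`mean 135 d`, `sd 35 d`, `min 14 d`).
  With the default 604-day span this yields ~350–400 residents — the scale
  of a large unit — and those are the problem sizes our end-to-end tests
  run at. The small-unit comparison uses 16 beds over a 304-day span
  (~40–50 residents), emulating a late-starting small women's unit.
- **Hierarchy:** a latent rank per resident starting at 0 on entry
  (new arrivals are lowest), drifting up by `rank_growth_rate = 0.1`/week
  with random-walk noise (`sd 0.25`/week). A latent variable, not an
  observed program phase, drives the dynamics: the hierarchy is treated
  as self-organizing, and the latent rank gives unambiguous ground truth
  for recovery tests.
- **Corrections:** each ordered co-present pair generates weekly Poisson
  counts with mean proportional to a logistic preference
  `plogis((rank_s - rank_r) / rank_temperature)`, scaled so the unit
  produces `corrections_per_resident_week = 2`. The temperature
  (default 0.5) interpolates between random correction direction and a
  strict pecking order, letting tests sweep identifiability. Real units'
  correction volume is not publicly reported; the default makes weekly
  networks sparse but connected and is a knob, not a claim.
- **Graduation:** Bernoulli with logit
  `grad_intercept + grad_rank_coef · final_rank + grad_lsi_coef · lsi_r`
  (defaults 1.6, +0.8, −0.05). Positive `grad_rank_coef` builds in the
  effect the pipeline should recover with a *negative* sign on every
  centrality measure (high rank ⇒ low centrality ⇒ graduation). Defaults
  are calibrated so simulated descriptives land in realistic ranges:
  graduation ≈ 0.78–0.86, days in program ≈ 117–162, age ≈ 29 (sd 8.6),
  LSI-R ≈ 26 (sd 7), minority proportion 0.2. Tenure is *not*
  mechanistically linked to graduation (the relationship is
  near-tautological in real data and would contaminate recovery tests).

The simulator does **not** emulate: the committee review that filters
illegitimate corrections, reciprocity or revenge dynamics, seasonal or
cohort effects, covariate-dependent correction behaviour (age, race and
LSI-R are independent of the latent rank), dropout that depends on
hierarchy position, or measurement error in the roster. Passing tests
therefore show the pipeline recovers the structure *this* generator
plants — directionally matching the published findings — not that real TC
data satisfy the generator's assumptions.

## Design choices made where the design was open

- Direction convention `M = Wᵀ + εJ` (in-edge aggregation): the only
  reading under which the pecking-order example puts the most-corrected
  bird on top of the centrality scale.
- ε-perturbation as the well-posedness device, rather than restricting to
  strongly connected components or adding uniform self-loops: it keeps
  every resident scored every week, which the trajectory definition needs.
- "Last month" = final four week-windows, whole tenure when shorter; no
  minimum-tenure exclusion by default.
- Zero-difference pairs dropped in the signed-rank test; two-sided p by
  default, one-sided "greater" used for the directional decline test.
- Wald rather than likelihood-ratio p-values, matching the
  coefficient/standard-error reporting style of the unit tables.
- Each unit is analysed separately (no pooling, no mixed effects): units
  are distinct communities with their own hierarchies.

## Known limitations

- The ε floor compresses score differences among uncorrected residents;
  at very high ε all scores flatten to 1 (our tests assert the variance
  decreases monotonically in ε).
- The signed-rank normal approximation is used regardless of sample size;
  below ~7 informative pairs an exact test would be preferable.
- Hierarchy measures enter the regressions as fixed covariates; the
  uncertainty in the weekly centrality estimates is not propagated.
- Sign recovery and power statements rest on the simulator's latent-rank
  model; with `rank_temperature` large (random correction direction)
  centrality ceases to track rank and the effect is correctly absent, but
  intermediate regimes are only lightly explored.
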