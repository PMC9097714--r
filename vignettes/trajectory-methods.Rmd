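---
title: "Detecting temporal clinical event pairs and trajectories: methods and design notes"
author: "ClinicalTrajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting temporal clinical event pairs and trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClinicalTrajectories)
```

## The model

The package treats a longitudinal health database as a collection of
*sequence units*: one unit per person and cohort time window, each carrying
the chronologically ordered **first occurrences** of distinct clinical
concepts (conditions, drug eras, procedures, observations). Restricting to
first occurrences avoids repeatedly counting chronic conditions; a study
of genuinely recurrent events should instead define shorter cohort
windows, so that the same person contributes several units. Pair and
trajectory counts therefore count *units*, not persons, and this is
deliberate and documented in the outputs.

An ordered pair E1 → E2 is *realized* in a unit when
`date(E1) + minGapDays <= date(E2) <= date(E1) + maxGapDays`; events in
between are irrelevant. For each candidate pair the package asks two
separate questions:

1. **Association** — does a prior E1 change the probability of a future
   E2? An exposed group (units with E1; index date = first E1) is compared
   with a matched background group on the prevalence of E2 *strictly
   after* the (assigned) index date and within the gap window, using
   Fisher's exact test (two-sided, probability-mass rule). Effect size is
   the relative risk `RR = Pr(E2 | prior E1) / Pr(E2 | no prior E1)` with
   a Katz log-normal 95% interval; when a cell of the 2x2 table is zero,
   the Haldane–Anscombe correction adds 0.5 to all four cells for the
   interval (and for the point estimate when the background count is
   zero).
2. **Direction** — among all units carrying both events, does the order
   E1-before-E2 dominate? An exact two-sided binomial test at p = 0.5 on
   the two order counts (same-day co-occurrences are excluded whenever
   `minGapDays >= 1`).

The Fisher and binomial p-value families are each corrected for multiple
testing across all tested pairs — FDR (Benjamini–Hochberg) in discovery
mode, Bonferroni in validation mode. A *directional pair* passes both
corrected tests at `alpha` with `RR >= rrMin` and E1-first dominant.
Directional pairs form a directed graph; every simple path of 2 to
`maxTrajectoryLength` concepts is a candidate trajectory, counted as the
number of units whose first occurrences realize the whole chain with every
adjacent gap inside the gap window.

The association test is matched, not model-based: within each exact
stratum (gender x `ageBinYears`-wide age bin x calendar year of the index
date) each exposed unit receives `matchRatio` background units by greedy
nearest-neighbor matching on a propensity score, without replacement.
Background candidates inherit the exposed unit's index date, must be under
observation on that date, and must not carry E1 on or before it.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `minGapDays` | 1 | days | minimum E1→E2 gap; 1 enforces strict order and drops same-day co-recording |
| `maxGapDays` | `Inf` | days | maximum gap; bound it to exclude distant, likely unrelated events |
| `minPairCount` | 20 | units | floor below which a pair is not tested (see design note below) |
| `minPairPrevalence` | unset | fraction | alternative floor as a cohort fraction, converted with `ceiling()` ("at least" semantics) |
| `rrMin` | 1 | — | lower edge of the RR range of interest |
| `alpha` | 0.05 | — | level applied to corrected p-values |
| `correction` | fdr / bonferroni | — | per run mode |
| `ageBinYears` | 5 | years | exact-matching age bin width |
| `matchRatio` | 1 | — | background units per exposed unit |
| `topKConcepts` | 100 | concepts | propensity features: prior-occurrence indicators of the K most prevalent concepts plus the prior-event count |
| `maxTrajectoryLength` | 5 | concepts | cap on composed path length |
| `privacyMinCount` | 20 | units | counts below this are masked as `"<k"` in written outputs |
| `seed` | 1 | — | governs every stochastic step |

## Design choices in genuinely open territory

**Propensity model.** The "other components" entering the propensity score
are not canonical; this package declares them as the indicators of the
`topKConcepts` most prevalent concepts occurring strictly before the index
date, plus the count of all prior events (a healthcare-utilization proxy).
The model is a ridge-penalized logistic regression (glmnet, `alpha = 0`,
fixed penalty): the L2 penalty keeps scores finite under perfect
separation, and a logistic link guarantees scores strictly inside (0, 1) —
a linear-probability fit would not. If every feature is constant the score
degenerates to the marginal exposure rate for all units, which makes
within-stratum matching arbitrary-but-deterministic rather than an error.

**Reference dates for candidate scoring.** Exposed units are scored with
features evaluated at their own index date. A background candidate has no
E1 and hence no natural index; it is scored at the *median exposed index
date* of the pair. Scoring every candidate once per exposed unit would be
quadratic in group size for a marginal gain in precision.

**Background pool.** Persons carrying E1 at any time are excluded from the
background pool entirely. This is stricter than requiring no E1 before the
assigned index only, but it guarantees two invariants at once: no person
appears in both groups of one pair, and no background member is
contaminated by a prior E1.

**Nearest-neighbor matching.** Greedy 1:`matchRatio` nearest-neighbor
matching without replacement, exposed units processed in person-id order,
score ties broken by the lower person id then unit id. Optimal
(network-flow) matching is a known alternative; the interface isolates the
matcher so a different strategy can be plugged in.

**The count floor and selection effects.** The floor interacts with the
multiple-testing family in a way worth understanding. The Fisher numerator
for the exposed group is essentially the same quantity as the pair count
used for the floor, so testing *only* pairs far in the upper tail of the
count distribution selects for inflated exposed prevalence (a
winner's-curse effect). In a large database with a floor of 20 this is
negligible; in a small simulated cohort of 1000 patients a floor of 20
admits only the top ~2% of pairs and the corrected family misbehaves. The
package's internal-validation experiments therefore use
`minPairCount = 10` — below the mean pair count under their generator
settings, giving a family of several thousand pairs over which FDR
control is well behaved — while the discovery default stays 20, matching
the floor used in full-scale database runs. With floor 10 the pure-null
configuration yields zero significant associations and zero directional
pairs on every seed exercised by the tests.

**Direction test population.** The binomial test runs on *all* cohort
units carrying both events, not on the matched groups: direction is a
property of the whole database, and the matched groups are a device for
the association question only.

**Correction families.** Fisher and binomial p-values are corrected as two
separate families, each across all tested pairs of the run. Untestable
pairs (no exposed units, empty pool, degenerate propensity fit, no
exact-stratum match) are excluded from the family sizes and reported with
an explanatory status.

**Gap conventions.** Both gap bounds are inclusive. Outcome ascertainment
requires E2 strictly after the index date even if `minGapDays = 0`;
enumeration with `minGapDays = 0` counts same-day pairs in both
directions, which is why the default is 1.

**Ties and determinism.** Same-date events order by ascending concept id;
trajectory enumeration is lexicographic in concept-id sequences; ranking
ties break lexicographically. Reruns with the same inputs and seed produce
byte-identical output files.

## The synthetic generator

`generateRandomEvents()` emulates the schema the reader consumes: uniform
gender, uniform birth years (1940–2000), a shared 2010–2019 observation
window, per-person event counts uniform in a range (default 1–30),
concepts uniform over a background vocabulary (default 100), dates uniform
in the window. `injectPair()` plants an exposure E1 at a per-person anchor
date and an outcome E2 at `anchor + gap` with probability `pE2GivenE1` for
carriers — so the probability of observing E2 after E1 is the design value
by construction — and optionally gives non-carriers a baseline E2 (at
their own anchor plus gap) with probability `pE2Baseline`, making the
design relative risk `pE2GivenE1 / pE2Baseline`. `injectTrajectory()`
plants an ordered chain in exactly `nCarriers` persons with strictly
positive adjacent gaps (default uniform 30–365 days, a realistic
between-diagnosis spacing).

For the RR-recovery experiment specifically, anchors are confined to the
first year of the window and gaps drawn from 400–2000 days, so every
planted E2 falls after every possible index date and the matched
estimator's target equals the design ratio exactly; without this, a
uniform-date baseline E2 lands before the index about half the time and
the measured background risk is roughly half the planted one.

What the generator does *not* emulate: age- and gender-dependent disease
rates (a confounded mode exists only through the matching tests),
correlated comorbidity structure, non-uniform visit patterns, censoring by
death, and vocabulary realism. Passing tests on this generator show the
machinery is correct and calibrated under clean conditions; they do not
show robustness to confounding structures absent from the simulation.

## Problem sizes used in the validation suite

The test-suite and acceptance-script experiments use: 400 patients with a
3-event trajectory planted in 100 (recovered count must be exactly 100);
five 1000-patient pure-null datasets with 1–30 events each (zero
directional pairs required); twenty 1000-patient replicates with a planted
pair of design RR 2 and ~50 occurrences (≥ 90% detection required); and
fifty replicates per design ratio in {1.5, 2, 3, 5} of 1500 patients with
300 carriers for CI coverage (≥ 90% required; 300 carriers keeps the
small-sample ratio bias of the RR estimator well below the interval
width). Exact-test oracles sweep all 2x2 tables with margins ≤ 30 and all
binomial order splits with at most 25 informative units.

## Known limitations

- Binary first-occurrence events only; numeric measurements and genuinely
  recurrent events are out of scope.
- Associations are not causal claims; confounding by indication or
  utilization is only partially addressed by the propensity features.
- Greedy matching is order-dependent (deterministically so) and can be
  suboptimal versus network-flow matching.
- The candidate reference-date simplification slightly blurs propensity
  comparability within strata when exposed index dates are widely spread.
- Multi-window cohort support treats windows as independent units; effects
  spanning windows of the same person are not modelled.
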