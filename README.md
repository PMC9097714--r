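# ClinicalTrajectories

Detection of statistically significant, temporally directed clinical event
pairs and longer disease trajectories in longitudinal health-event data.

## The problem

Observational health databases record, per patient, dated clinical events
— condition diagnoses, drug eras, procedures, observations. A recurring
epidemiological question is which events systematically *precede and raise
the risk of* other events: does E1 → E2 reflect a real temporal
association, or just co-occurrence? Chains of such pairs
(E1 → E2 → E3, ...) form disease trajectories that characterize how
morbidity unfolds in a population.

This package implements that analysis for event tables flattened from an
OMOP-style schema (a person table, a long event table, optionally a cohort
window table). It is aimed at epidemiologists and health-data scientists
who want a transparent, fully scripted pipeline they can run on their own
database in either *discovery* mode (no prior hypotheses) or *validation*
mode (re-testing pairs discovered elsewhere).

## The method

1. **Sequences.** Within the study cohort (the whole database, or explicit
   per-person time windows), only the *first* occurrence of each concept
   per patient is kept, giving one chronological sequence per sequence
   unit. Same-day ties are ordered by concept id.
2. **Pairs.** Every ordered concept pair whose first occurrences satisfy
   `date(E1) + minGap <= date(E2) <= date(E1) + maxGap` (intermediate
   events allowed) is counted; pairs below a count or cohort-prevalence
   floor are discarded.
3. **Testing.** For each candidate pair, an exposed group (units with a
   prior E1, index date = first E1) is matched 1:*k* to background units
   on exact covariates — gender, age bin, calendar year of E1 — plus a
   ridge-logistic propensity score built from prior-event indicators. The
   association is tested with Fisher's exact test on E2 prevalence after
   the (assigned) index date and quantified as a relative risk

   `RR = Pr(E2 | prior E1) / Pr(E2 | no prior E1)`

   with a Katz log-normal 95% CI; the temporal direction is tested with an
   exact binomial test on the order counts among all units carrying both
   events. Both p-value families are corrected (FDR in discovery,
   Bonferroni in validation); a pair is a *directional pair* when both
   corrected tests pass at `alpha` with `RR >= rrMin` and E1-first the
   dominant order.
4. **Trajectories.** Directional pairs form a directed graph; all simple
   paths up to a maximum length are composed and their realizations
   counted against the per-unit sequences (intermediate events allowed).

A synthetic-data module generates random longitudinal tables with
plantable pairwise risks and multi-event trajectories, so the whole
pipeline is testable end-to-end without any real data.

## Worked example

```r
library(ClinicalTrajectories)

# random data for 400 patients, then plant a 3-event trajectory in 100
tabs <- generateRandomEvents(nPersons = 400, eventsPerPerson = c(1, 30),
                             seed = 5)
tabs <- injectTrajectory(tabs, c(9101L, 9102L, 9103L), nCarriers = 100,
                         seed = 6)

bundle <- runDiscovery(tabs$persons, tabs$events,
                       params = studyParams(minPairCount = 10, seed = 5))
bundle$trajectories[, c("trajectory", "length", "n_patients")]
#>                                         trajectory length n_patients
#> 1                  injected_9101 -> injected_9102      2        100
#> 2 injected_9101 -> injected_9102 -> injected_9103      3        100
#> 3                  injected_9101 -> injected_9103      2        100
#> 4                  injected_9102 -> injected_9103      2        100
```

All three adjacent/skip pairs of the planted chain are recovered as
significant directional pairs, and the full 3-event trajectory is counted
in exactly the 100 carriers it was planted in. `resultsTable(bundle$results)`
holds the per-pair statistics (counts, RR with CI, Fisher and binomial
p-values raw and adjusted, significance flags); with `outDir=` the run also
writes `pairs.tsv`, `graph.graphml`/`graph.dot`, `trajectories.tsv` and a
`manifest.json` with per-stage attrition counts. Counts below
`privacyMinCount` (default 20) are masked as `"<20"` in written outputs.

A thin command-line wrapper with `discover`, `validate` and `simulate`
subcommands is installed at `inst/cli/trajectories-cli.R`.

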