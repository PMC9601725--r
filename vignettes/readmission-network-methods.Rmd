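---
title: "Methods: a constrained Bayesian-network workflow for hospital readmissions"
author: "readmitbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a constrained Bayesian-network workflow for hospital readmissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readmitbn)
```

## The model and its assumptions

`readmitbn` fits multinomial Bayesian networks to small categorical
clinical cohorts. A network is a directed acyclic graph (DAG) over the
variables plus one conditional probability table (CPT) per node; the joint
distribution is the product of the per-node conditionals. Two variables not
joined by an arc are conditionally independent given the appropriate
separating set — in a chain A → B → C, knowing A adds nothing about C once
B is known, P(C | A, B) = P(C | B). This factorization is what makes an
8-variable clinical model estimable from 96 patients: the full joint over
the default variable set has 575 free probabilities, while the 7-arc model
shipped as `gi_bic_dag()` has 23.

The assumptions are those of any discrete Bayesian-network analysis:

* every variable is categorical with a fixed, known level set;
* records are independent and identically distributed (no clustering by
  center or repeated admissions of one patient);
* the network is a model of observational conditioning. Arc directions are
  chosen on clinical grounds (causes point at effects) and constrain the
  search, but a query such as `P(HRA | NUTR = Yes)` is a conditional
  probability in the cohort, not an intervention effect. No do-calculus is
  implemented, deliberately.

## Variables and clinical discretization

The default analysis set (`gi_variables()`) covers eight variables: cancer
site group (3 levels), BMI class, bone metastasis, serum-albumin class,
nutritional support, breakthrough-cancer-pain (BTcP) predictability,
radiotherapy, and the unplanned readmission-count class (`HRA`, ordered).
Continuous measurements enter through `discretization_rule()` objects with
cut points of clinical interest:

| raw column | units | cut points | classes | boundary |
|---|---|---|---|---|
| `bmi` | kg/m2 | 25 | `<25`, `>=25` | 25.0 is in the upper class |
| `albumin` | g/dL | 3.5 | `<=3.5`, `>3.5` | 3.5 is in the lower class |
| `hra_count` | admissions | 10, 22 | `<=10`, `11-22`, `>22` | 10 and 22 close their lower intervals |

Interval labels are taken literally, so the boundary side follows the label
(`>=25` contains 25.0). The 3.5 g/dL albumin cut is the usual
hypoalbuminemia threshold. The third readmission class is labelled `>22`:
the three classes must partition the count axis, and the class above
`11-22` can only be "more than 22". Applying a rule to an
already-categorical column is an error, never a silent re-binning, so
discretization cannot be applied twice.

Missing data are handled by complete-case deletion over the analysis
columns only; the number of dropped rows is recorded on the cohort object
and in the pipeline log. No imputation is offered — at this cohort scale an
imputation model would be larger than the analysis model.

## Association screening

`association_matrix()` runs Pearson's chi-square test on every unordered
pair. Three choices deserve explanation:

* **No Yates continuity correction** (`chisq.test(..., correct = FALSE)`),
  so 2×2 tables are treated identically to larger ones. Software that
  corrects by default will report slightly larger p-values on 2×2 tables.
* **p = α counts as significant**: the decision rule is p ≤ α, so a pair
  sitting exactly at the 0.05 boundary is flagged. A secondary suggestive
  tier at p ≤ 0.10 is reported alongside, and both thresholds are
  configurable.
* **No multiple-testing correction**: the matrix reports unadjusted
  per-pair decisions, as is conventional for this kind of descriptive
  screen. With 28 pairs at α = 0.05, one or two false flags are expected
  under global independence; the screen feeds the human constraint-building
  step, not an automated decision.

Levels with zero marginal count are dropped (with a warning) before
testing; a table left with fewer than two levels on a margin is an error.
When any expected cell count falls below 5 a warning is emitted but the
statistic is still computed — a 96-patient cohort with a 16% metastasis
rate cannot satisfy the classic rule, and refusing the test would make the
workflow unusable at exactly the scale it targets.

## Clinical constraints and the two reference structures

Prior knowledge enters as a whitelist (arcs that must be present) and a
blacklist (arcs that may never be added). The shipped lists
(`gi_constraints()`) encode: high BMI predisposes to breakthrough pain;
bone metastases induce breakthrough pain and palliative radiotherapy; low
albumin drives nutritional support (whitelist); nothing causes the tumor
type, and neither albumin nor nutritional support can cause breakthrough
pain or bone metastasis (blacklist). The clinical narrative behind these
lists also asserts links from cancer type and metastasis to readmissions;
those were not made whitelist arcs here because a forced arc can never be
removed by the data, and the selected model this package reproduces does
not contain them — they remain available to the search, which is the
weaker and more defensible reading.

Two structures ship as fixtures. `gi_bic_dag()` is the 7-arc BIC-selected
model, read directly off its factorization
P(BMI)·P(ALB)·P(CANCER)·P(MTX|CANCER)·P(NUTR|ALB)·P(BTcP|MTX,BMI)·
P(RADIO|MTX)·P(HRA|NUTR,RADIO). `gi_knowledge_dag()` is the 11-arc
hypothesized model assembled from the asserted pairwise associations with
causal orientations; where an orientation is not recoverable from the
narrative (the nutrition–radiotherapy pair) radiotherapy was oriented
toward nutritional support, matching the whitelist's causal reading that
treatment burdens drive nutritional needs. Orientation choices do not
affect the arc count, neighborhood, or branching indicators; they do
affect average Markov-blanket size, which is therefore not asserted for
the knowledge-based structure in the test suite.

`graph_indicators()` reports directed arcs, average Markov-blanket size,
average neighborhood size (2·arcs/nodes) and average branching factor
(arcs/nodes); display rounding is half-away-from-zero to two decimals
(0.875 → 0.88), since bankers' rounding would print 7/8 differently than
the conventional table style.

## Scoring

`network_score()` always fits maximum-likelihood CPTs — BIC is defined at
the maximized likelihood. Both sign conventions are carried:
`bic = k·ln(n) − 2·lnL` (minimize) and `score = lnL − (ln n/2)·k`
(maximize), with `bic = −2·score` asserted as an identity in the tests.
The per-parameter penalization coefficient `ln(n)/2` equals 2.28 at
n = 96; AIC uses coefficient 1. The score decomposes over node families,
and the hill climber caches family scores by (node, parent set), so a
move's score delta costs at most two contingency tables.

## Structure search

`hill_climb()` starts from the graph containing exactly the whitelist arcs
— the constraints are fixed before learning, so the search explores the
region around the clinically mandated backbone rather than the empty
graph (the empty start is available by passing empty constraints and is
equivalent on unconstrained problems). Moves are single-arc additions,
deletions and reversals; whitelisted arcs cannot be deleted or reversed,
blacklisted arcs cannot be added, and cycle-creating moves are rejected.
The best strictly improving move is taken; exact ties are broken
lexicographically by (move type, parent, child), which makes a
`restarts = 0` run fully deterministic — on two perfectly correlated
variables A and B, both orientations score identically and the tie-break
returns A → B. One accepted move is one step in the trace; step counts are
reported but never compared across implementations, because they depend on
move enumeration order. Random restarts (seeded, mandatory seed) perturb
the start graph with random valid moves and keep the best local optimum;
no tabu list is used — restarts are simpler and their adequacy is checked
directly against the exhaustive oracle.

`exhaustive_search()` enumerates every constraint-compliant DAG on up to
five variables (29,281 DAGs at five nodes; enumeration prunes partial
assignments that already contain a cycle) and returns the score optimum,
lexicographically least among exact ties. It exists to validate the
greedy search: the test suite checks on random 4-variable instances that
hill climbing with 20 restarts attains the exhaustive optimum score.

## Exact inference

`eliminate_query()` implements sum-product variable elimination with a
min-degree elimination heuristic (ties broken alphabetically). At this
package's scale — the default network has 576 joint states — elimination
order barely matters and a junction tree would buy nothing, so the simpler
algorithm was chosen; it is validated against `enumerate_joint()`, which
materializes the full joint (refusing state spaces above 10^6). Queries
return the posterior, the no-evidence marginal, and per-level shifts in
percentage points; evidence with probability zero under the model is an
error naming the impossible assignment rather than a silent NaN.

**Smoothing.** Structure scoring uses α = 0 (pure MLE). The inference
tables default to α = 1 (Laplace), because at n = 96 a rare parent
configuration can produce zero cells that would make clinically meaningful
queries impossible. The original analysis this workflow mirrors does not
state its smoothing, so both are exposed: `catbn(..., alpha = 0)` gives
MLE inference, and `reproduce_study_queries()` reports both side by side
as a sensitivity check. Under α = 0, a parent configuration never observed
yields the uniform distribution for that row.

## The synthetic cohort generator

`gi_reference_network()` plus `sample_cohort()` (ancestral sampling in
topological order, seed mandatory) replace the patient-level data, which
are not redistributable with the package. The generator's structure is the
7-arc model; root tables equal the published cohort proportions (e.g.
bone metastasis 16%, nutritional support 19%, predictable BTcP 26%), and
child tables are synthetic conditionals chosen once so that

* every implied marginal matches the published one-way frequency within
  0.01 — verified exactly by enumeration, not by sampling;
* the qualitative findings are encoded with effect sizes strong enough for
  structure recovery at simulation scale: P(predictable BTcP) is 0.55 with
  bone metastasis versus 0.25/0.15 without (the BMI ≥ 25 class being the
  more non-predictable one); P(radiotherapy) is 0.40 with metastasis
  versus 0.06 without; P(lowest readmission class | support, no
  radiotherapy) is 0.45.

What the generator does **not** emulate: dependencies absent from the
7-arc structure (any real BMI–albumin correlation, for instance),
missing-data patterns, center effects, or the sampling idiosyncrasies of a
96-patient observational cohort. Tests passing on synthetic data therefore
demonstrate the correctness and calibration of the machinery, not the
clinical validity of conclusions on real patients.

## Numerical choices and degenerate inputs

* CPT rows must sum to 1 within 1e-12; posteriors within 1e-10 of the
  enumeration oracle; incremental score deltas within 1e-9 of full
  rescoring.
* Strict-improvement threshold in the hill climber: 1e-12, below which a
  move is treated as a tie.
* Empty cohorts: log-likelihood 0; scoring and search refuse (no penalty
  is defined at n = 0); `marginal_summary()` warns and returns an empty
  table.
* An n = 1 cohort summarizes to proportion 1 for each observed level.
* Sampling-noise bounds in tests use exact conditional binomial standard
  errors: at n = 10,000 a parent configuration seen ~200 times has
  per-entry SE ≈ 0.03, so fixed absolute recovery tolerances tighter than
  that are not statistically meaningful for rare configurations.

## Problem sizes used by the test suite

Chosen as the smallest sizes at which each property is sharp: oracle
equivalence on the 576-state network (100 random queries); greedy-versus-
exhaustive agreement on 50 random 4-variable instances at n = 200;
chi-square type-I calibration over 300 replicates at n = 5,000; marginal
and structure recovery at n = 10,000.

## Known limitations

* No continuous or conditional-Gaussian nodes, no latent variables, no EM:
  the cohort is fully categorical by design.
* No equivalence-class (CPDAG) representation; likelihood-equivalent
  orientations of unconstrained arcs are distinguished only by the search
  tie-break, and tests compare structures up to Markov equivalence where
  appropriate.
* No Fisher exact test and no Bayesian Dirichlet Equivalent score; the
  chi-square screen and BIC/AIC are the supported primitives.
* At n = 96 the BIC penalty is severe: data-driven arcs beyond the
  whitelist appear only for strong effects, and learned structures at that
  scale should be read as conservative.
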