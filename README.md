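# readmitbn

Discrete Bayesian networks for analyzing unplanned hospital readmissions
(HRAs) in gastrointestinal-cancer cohorts.

Unplanned readmissions are frequent in advanced cancer, degrade quality of
life, and drive care costs. For a small clinical cohort described by a
handful of categorical variables — cancer site group, body-mass-index class,
bone metastasis, serum-albumin class, nutritional support, breakthrough
cancer pain (BTcP) predictability, radiotherapy, and the readmission-count
class — a multinomial Bayesian network makes the dependence structure
explicit and turns clinical questions into exact posterior queries: *how
does the probability of staying under 10 readmissions change for a patient
on nutritional support without radiotherapy?*

The package is aimed at biostatisticians and clinical data analysts working
with small categorical cohorts who want the whole workflow — discretization,
association screening, knowledge-constrained structure learning, and exact
inference — reproducible in one place, with a calibrated synthetic-cohort
generator so everything runs and is testable without access to patient data.

## The model

A Bayesian network over variables $X_1,\dots,X_m$ is a directed acyclic
graph (DAG) plus one conditional probability table (CPT) per node, so the
joint factorizes as

$$P(X_1,\dots,X_m) = \prod_{i=1}^m P\!\left(X_i \mid \mathrm{pa}(X_i)\right).$$

Structures are scored by the Bayesian Information Criterion. Both
conventions are carried explicitly: the minimization form
$\mathrm{BIC} = k\ln n - 2\ln L(\hat\theta)$ and the decomposable
maximization form $\ln L - \tfrac{\ln n}{2}\,k$, where $k$ is the number of
free parameters, $n$ the number of patients, and $\ln n/2$ the
per-parameter penalization coefficient ($\approx 2.28$ at $n = 96$). The
two are related by $\mathrm{BIC} = -2 \cdot \mathrm{score}$, so minimizing
one is maximizing the other; AIC ($\ln L - k$) is available as the named
alternative.

Search is greedy hill climbing over single-arc moves (add / delete /
reverse) under clinical **whitelist** constraints (arcs that must be
present, e.g. albumin → nutritional support) and **blacklist** constraints
(impossible arcs, e.g. anything causing the tumor type), with deterministic
lexicographic tie-breaking, optional seeded restarts, and an exhaustive
enumeration oracle for instances of up to five variables. Inference is
exact variable elimination, validated against full-joint enumeration.

## Worked example

```r
library(readmitbn)

bn     <- gi_reference_network()               # calibrated ground truth
cohort <- sample_cohort(bn, n = 96, seed = 2024)
fit    <- catbn(cohort, dag = gi_bic_dag(), alpha = 1)
fit
#> Multinomial Bayesian network: 8 nodes, 7 arcs
#>   structure: [BMI][CANCER][MTX|CANCER][ALB][NUTR|ALB][BTcP|MTX:BMI][RADIO|MTX][HRA|NUTR:RADIO]
#>   fitted on n = 96 (inference smoothing alpha = 1); BIC = 1091.84

eliminate_query(fit, "HRA", c(NUTR = "Yes", RADIO = "No"))
#> Posterior of HRA | NUTR = Yes, RADIO = No
#>  level marginal posterior shift_pp
#>   <=10   0.2387    0.5294    29.07
#>  11-22   0.4118    0.3529    -5.88
#>    >22   0.3496    0.1176   -23.19
```

Read: in this synthetic 96-patient cohort, a patient on nutritional support
who does not receive radiotherapy has a 52.9% probability of at most 10
readmissions, 29 percentage points above the 23.9% no-evidence marginal —
the model's version of "nutritional support without radiotherapy shifts
patients into the lowest readmission class". Per-arc significance from the
chi-square screen can be attached to graph exports:

```r
am <- association_matrix(cohort)               # Pearson chi-square, alpha = 0.05
export_dag(fit$dag, "model.dot", tiers = arc_significance(fit$dag, am))
```

The full nine-step pipeline (load/simulate → discretize → select → screen →
constrain → learn → fit → score → query), with every artifact written to a
directory, is one call:

```r
rep <- run_analysis(analysis_config(synthetic = list(n = 96, seed = 2024),
                                    seed = 1), outdir = "results")
```

`graph_indicators()` summarizes any structure; on the 7-arc model above it
reports an average Markov-blanket size of 2.25, average neighborhood size
1.75, and average branching factor 0.88.

Structure learning at the real cohort's size ($n = 96$) typically retains
only the whitelisted arcs plus the strongest data-driven ones — the BIC
penalty at small $n$ is severe. The generator lets you verify recovery at
larger $n$: at $n = 10{,}000$ the constrained search returns the 7-arc
generating structure.

To fit the actual study cohort instead of a synthetic one, download the
deposited patient table (Zenodo record 6769798) and pass it as
`analysis_config(input = "<path>")`, or run
`reproduce_study_queries("<path>")` to recompute the headline posterior
percentages under both maximum-likelihood and Laplace smoothing.

## Vignette

`vignettes/readmission-network-methods.Rmd` documents the model and its
assumptions, the constraint lists, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate, and
the package's numerical and design choices.
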