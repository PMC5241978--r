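# stratsig

Multidimensional signatures, prototypes and trajectories for stratified
psychiatry.

## The problem

Psychiatric trials traditionally recruit by categorical diagnosis and
measure response as change in a single aggregate score (e.g. total
PANSS).  Both steps discard structure: patients sharing a diagnosis are
heterogeneous, and a cohort in which half the patients improve
dramatically on one symptom domain can look like a *failed trial* when
domains are summed and averaged.  `stratsig` operationalises the
alternative:

* a patient's clinical state at one timepoint is a **signature** — a
  point in a d-dimensional space whose axes are instrument items or
  domain scores (30 PANSS items; 5 neurocognitive Z-scores), with
  similarity the Euclidean distance `d(x, y) = sqrt(sum_i (x_i - y_i)^2)`;
* **prototypes** are discovered by density-peak clustering: each point
  gets a local density `rho_i = #{j : d_ij < d_c}` and a separation
  `delta_i = min_{j : rho_j > rho_i} d_ij`; points where `delta` is
  anomalously large for their density are cluster prototypes, and every
  patient is assigned to the nearest prototype;
* **stratification** is hard (nearest prototype) or soft,
  `P(k | x) ∝ exp(-d_k^2 / (2*tau^2))`, optionally weighted by class
  priors via Bayes' rule;
* **trajectories** are modelled by clustering each timepoint
  independently and estimating the conditional probability table
  `P(cluster at t2 = j | cluster at t1 = i)`, queryable with soft
  evidence: `P(t2 = j) = sum_i P(t1 = i) * cpt[i, j]`;
* **outcomes** are regions of signature space (a ball around a
  prototype, one side of a Fisher linear discriminant, or unions), and
  the crude multivariate response rate is the fraction of follow-up
  signatures inside the region;
* seeded **synthetic cohorts** (bimodal treatment response, planted
  Gaussian mixtures, planted two-timepoint transitions) close the loop:
  every analysis module is tested by recovering planted truth;
* a **trial-readiness rubric** (0–5 points: specific symptoms /
  patient-specific variables; domain-level outcomes with change;
  outcomes analysed against patient variables) with an encoded
  systematic-review table as a fixture.

## Worked example

A hypothetical intervention improves *only* the positive-symptom score,
by 80%, in only half of 100 patients:

```r
library(stratsig)

sim <- simulate_bimodal_response(bimodal_response_spec(seed = 11))
sim$cohort
#> <cohort> 200 signatures x 2 items (scale 'panss_domain_totals'); timepoints: t1, t2

## two-cluster analysis of the follow-up signatures
x2 <- signature_matrix(sim$cohort, "t2")
dp <- dp_cluster(x2, clustering_config(selection = "fixed_k", k = 2))
dp
#> <dp_result> 100 points, 2 prototype(s) [selection: fixed_k, kernel: hard, d_c = 1.833]
#> cluster sizes: 50, 50

ps <- prototypes_from_dp(dp)
round(ps$centroids, 2)
#>   positive_total negative_total
#> 1           4.78          27.04
#> 2          21.63          20.31
```

Cluster 1 — half the cohort — sits at a positive-symptom score of ~4.8
against a baseline of ~22: the responder subgroup, recovered from the
follow-up geometry alone.  Among the true (planted) responders the mean
positive-score reduction is 77.2% in this draw, against the planted 80%.
The summed aggregate score sees none of this structure (its distribution
merely widens), which is the methodological point.

Soft stratification and a trajectory model over the same cohort:

```r
round(unclass(soft_assign(x2[1:3, ], ps, temperature = 5)), 3)
#>          1     2
#> [1,] 1.000 0.000
#> [2,] 1.000 0.000
#> [3,] 0.001 0.999

m1 <- soft_assign(signature_matrix(sim$cohort, "t1"),
                  prototypes_from_dp(dp_cluster(
                    signature_matrix(sim$cohort, "t1"),
                    clustering_config(selection = "fixed_k", k = 2))),
                  temperature = 5)
tr <- estimate_transition(m1, soft_assign(x2, ps, temperature = 5),
                          mode = "hard", smoothing_alpha = 0.5)
tr
#> <transition_model> 2 -> 2 clusters (hard counts, alpha = 0.5)
#>       1     2
#> 1 0.632 0.368
#> 2 0.357 0.643

round(as.numeric(predict(tr, c(0.7, 0.3))), 3)   # soft evidence
#> [1] 0.55 0.45
```

Scoring the encoded systematic-review table:

```r
res <- score_cohort(table1_trials())
res$histogram
#>  0  1  2  3  4  5
#>  1  1 12  2  6  1
```

## Command line

A subcommand launcher is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stratsig", package = "stratsig"))')
Rscript "$CLI" simulate --kind mixture --spec spec.json --seed 4 --out out/
Rscript "$CLI" cluster --input out/cohort.csv --scale scale.json \
        --selection fixed_k --k 2 --out out/
Rscript "$CLI" score-trials --out scores.csv
Rscript "$CLI" run --config pipeline.json       # full pipeline + manifest
```

Exit codes: 0 success, 1 validation error, 2 internal error.

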