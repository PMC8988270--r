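# symptomnet

Regularized partial-correlation networks of depressive symptoms, with
group comparison and stability diagnostics.

## The problem

Psychopathology network analysis treats the items of a symptom
questionnaire (here a 21-item, 0–3 scored depression inventory) as nodes of
a network whose edges are conditional dependencies between symptoms. Given
several clinical groups — e.g. current depression (CD), remitted depression
(RD), subthreshold depression (SD) and healthy controls (HC) — the questions
are: how densely connected is each group's symptom network, which symptoms
are central, and do the networks differ between groups even when symptom
severity does not?

`symptomnet` implements that full workflow for epidemiologists and clinical
researchers:

1. **Residualization** — each item score is adjusted for age and sex by OLS
   (`residualize_items()`).
2. **Network estimation** — per group, the Pearson correlation matrix of the
   residuals is fed to the graphical LASSO, which maximizes the penalized
   Gaussian log-likelihood
   `log det Θ − tr(RΘ) − λ‖Θ‖₁` over precision matrices Θ; the penalty λ is
   selected on a 100-point log-spaced path by the extended Bayesian
   information criterion `EBIC = −2ℓ + E·log n + 4γ·E·log p` (γ = 0.5), and
   edge weights are the regularized partial correlations
   `w_ij = −θ_ij / √(θ_ii θ_jj)` (`estimate_network()`). The solver is a
   block coordinate-descent glasso written in RcppArmadillo.
3. **Centrality** — strength `Σ_j |w_ij|`, closeness (inverse mean shortest
   1/|w| path distance to reachable nodes) and Brandes betweenness, with
   standardized z-scores (`centrality_table()`, `centrality_by_group()`).
4. **Group comparison** — Pearson chi-square tests on the ratio of nonzero
   edges per group pair, Holm-corrected (`edge_count_test()`), and the
   permutation Network Comparison Test on global strength
   `S = Σ_{i<j} |w_ij|` and structure `M = max_{i<j} |w_ij^A − w_ij^B|`
   (`nct()`, `compare_networks()`).
5. **Accuracy & stability** — nonparametric bootstrap percentile CIs per
   edge (`bootstrap_edges()`), case-dropping subset bootstrap with the
   CS-coefficient (`case_dropping()`, `cs_coefficient()`; CS > 0.25 is the
   conventional stability cutoff).
6. **Synthetic cohorts** — a generator with known conditional-independence
   ground truth (`make_precision_model()`, `four_group_fixture()`): ordinal
   0–3 items arise by thresholding a latent Gaussian with group-specific
   sparse precision structure, severity shifts and linear age/sex effects,
   so every stage of the pipeline can be validated without patient data.

`run_pipeline()` orchestrates all stages and `write_report()` emits
`report.json` plus flat CSVs (edge lists, centrality, comparisons,
stability, Fruchterman–Reingold layout). A thin CLI wrapper with
`simulate / estimate / centrality / compare / stability / run` subcommands
lives at `inst/scripts/symptomnet`.

## Worked example

```r
library(symptomnet)

fx    <- four_group_fixture(seed = 1)      # CD/RD share a dense structure
resid <- residualize_items(fx$cohort)      # OLS age/sex adjustment per group
nets  <- estimate_group_networks(resid)    # glasso + EBIC per group

nets$CD
#> <symptom_network> 21 nodes, 114 nonzero edges (of 210)
#>   n = 294, gamma = 0.5, lambda = 0.06201

glance(nets$CD)
#> # A tibble: 1 × 7
#>       p     n gamma lambda_selected nonzero_edges density global_strength
#>   <int> <int> <dbl>           <dbl>         <int>   <dbl>           <dbl>
#> 1    21   294   0.5          0.0620           114   0.543            9.32

edge_count_test(nets)[, 1:8]
#> # A tibble: 6 × 8
#>   group_a group_b nonzero_a nonzero_b n_pairs statistic  p_value p_adjusted
#>   <chr>   <chr>       <int>     <int>   <dbl>     <dbl>    <dbl>      <dbl>
#> 1 CD      RD            114       101     210      1.61 2.04e- 1   2.04e- 1
#> 2 CD      SD            114        26     210     83.0  8.32e-20   3.33e-19
#> 3 CD      HC            114         0     210    156.   6.68e-36   4.01e-35
#> 4 RD      SD            101        26     210     63.5  1.61e-15   4.84e-15
#> 5 RD      HC            101        0      210    133.   9.14e-31   4.57e-30
#> 6 SD      HC             26        0      210     27.7  1.41e- 7   2.81e- 7
```

Reading the output: the two clinical groups keep statistically
indistinguishable dense networks (114 vs 101 edges, adjusted p = 0.20)
although the remitted group's severity is at healthy-control level, while
every comparison against the nonclinical groups is significant — the
"trace" pattern the pipeline is built to detect. `tidy(nets$CD)` gives the
edge list, `centrality_by_group(nets)` the standardized centralities,
`autoplot(nets$CD)`/`plot_centrality()` the figures, and
`bootstrap_edges()` / `case_dropping()` the stability reports.

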