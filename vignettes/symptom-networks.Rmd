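---
title: "Estimating and comparing symptom networks: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

This vignette is the package's account of the statistical machinery it
implements: the models and their assumptions, every tunable parameter that
matters, what the synthetic-cohort generator does and does not emulate, and
the design choices made where the methodology left the design genuinely
open. Nothing stated here as an empirical result goes beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The model

The data are participant-by-item tables: `p = 21` ordinal item scores in
{0, 1, 2, 3}, age in years, binary sex, and a group label. The target of
inference per group is a Gaussian graphical model (GGM) over the items: a
network whose edge weights are partial correlations,

$$ w_{ij} \;=\; -\,\frac{\theta_{ij}}{\sqrt{\theta_{ii}\,\theta_{jj}}}, $$

where $\Theta = (\theta_{ij})$ is the precision (inverse covariance)
matrix. A zero entry of $\Theta$ means conditional independence of the two
symptoms given all others — the absence of an edge.

Treating 0–3 ordinal scores as Gaussian is an approximation; it is the
standard one in this literature, and the residualization step (below)
makes the inputs continuous. The package offers Spearman correlations as
an alternative input (`method = "spearman"`), but no polychoric or
nonparanormal transform (a stated non-goal).

### Covariate adjustment

`residualize_items()` regresses every item on an intercept, age and sex by
OLS and passes the residuals forward. Two choices were open:

* **Regression form.** Plain linear OLS with an intercept, no interactions
  or nonlinear age terms. Residuals are exactly mean-zero and orthogonal to
  the covariates within the regression sample; both properties are asserted
  by tests at 1e−10/1e−8.
* **Scope.** Whether adjustment happens within each group or pooled across
  the sample is genuinely ambiguous when networks are later estimated per
  group. The default is `scope = "per_group"` (each group self-contained,
  no leakage of between-group severity differences into the residuals);
  `scope = "pooled"` is available, and the pipeline's *descriptive*
  residual-mean table always uses the pooled fit, because per-group
  residual means are zero by construction and would carry no information.
* **Degenerate designs.** A covariate that is constant in the regression
  sample is dropped (with a message) rather than producing a rank-deficient
  fit; with both covariates constant the residual is the deviation from the
  item mean.

### Estimation: graphical LASSO with EBIC selection

With 21 nodes there are 210 candidate edges, more than the smaller groups'
sample sizes, so the precision matrix is estimated by the graphical LASSO:
maximize $\log\det\Theta - \mathrm{tr}(R\Theta) - \lambda\lVert\Theta\rVert_1$
for the residual correlation matrix $R$. The solver (`src/glasso.cpp`) is a
block coordinate descent on the penalized covariance: each column update
solves an L1 lasso subproblem by coordinate descent with soft-thresholding,
which produces *exact* zeros; the recovered precision inherits them, and a
documented hard threshold (`zero_tol = 1e-10`) removes any remaining
numerical dust so that "nonzero edge count" is well defined. Convergence is
declared when the maximum absolute change of the working covariance falls
below `tol` (default 1e−4) scaled by the mean absolute off-diagonal of
$R$; the iteration cap is 10,000 and non-convergence is an error, never a
silent result.

The penalty is chosen on a descending log-spaced path of `n_lambda = 100`
values from $\lambda_{\max} = \max_{i<j}|r_{ij}|$ (the smallest penalty
with an empty solution) down to `lambda_min_ratio = 0.01` times that, by
minimizing the extended Bayesian information criterion

$$ \mathrm{EBIC}_\gamma \;=\; -2\,\ell(\Theta) + E \log n + 4\gamma E \log p, $$

with $\ell = (n/2)(\log\det\Theta - \mathrm{tr}(R\Theta))$ and $E$ the
number of nonzero upper-triangle entries. Defaults follow the conventions
of the EBIC-glasso software family: $\gamma = 0.5$, 100 penalties, ratio
0.01. All of these are arguments and are echoed into every pipeline report
for auditability. The penalized estimate at the selected $\lambda$ is
reported as-is — there is deliberately no post-selection refit, matching
the "conservative, small connections pushed to zero" character of the
method.

Two numerical notes. First, the L1 penalty is applied to the whole matrix
including the diagonal (`penalize_diagonal = TRUE`); the unpenalized-
diagonal variant is implemented and exposed, but it shifts the likelihood
baseline of sparse models and makes EBIC selection markedly more
conservative at these sample sizes, so it is not the default. Second, the
edge count along the penalty path is monotone *up to transient single-edge
dips*: a lasso coefficient can cross zero as $\lambda$ decreases, so exact
active-set monotonicity is not a theorem — the tests assert the correct
bounded-dip form after cold-started fits confirmed the crossings are
properties of the exact solution, not solver artifacts.

### Centrality

Three node indices, computed on the weighted network:

* **Strength**: $\sum_j |w_{ij}|$. Absolute values are used (a signed
  variant is a flag) so that negative edges count as connectivity;
  estimated symptom networks are mostly positively connected, so the
  distinction is minor.
* **Closeness**: inverse *mean* shortest-path distance with edge lengths
  $1/|w|$, averaged over *reachable* nodes only, and defined as 0 for an
  isolated node. This convention matters here because near-empty networks
  (the healthy-control case) are not hypothetical; restricting to
  reachable nodes avoids propagating infinities.
* **Betweenness**: Brandes betweenness on the $1/|w|$ distance graph with
  fractional credit over tied shortest paths; raw unordered-pair counts
  are reported, with a percentage form (per $(p-1)(p-2)/2$ bridgeable
  pairs) available.

Shortest paths and betweenness are delegated to igraph; all three measures
are verified against an exhaustive simple-path-enumeration oracle on random
graphs with $p \le 7$. Z-standardization uses the sample SD; a constant
column yields all-zero z-scores with a warning. Whether standardization is
done within each group's network (default) or pooled across groups is a
flag (`centrality_by_group(standardize_within=)`), since either reading of
"standardized scores" is defensible.

### Group comparison

Two complementary tests:

* **Edge-ratio chi-square** (`edge_count_test()`): per group pair, a 2×2
  Pearson chi-square without continuity correction on (nonzero, zero)
  counts out of the 210 possible edges, Holm-corrected across the pairs.
  Expected counts are large at $p=21$, so the continuity correction is
  unnecessary (a flagged option). Treating the 210 pairs as independent
  trials is an approximation inherited from the method itself: edges of a
  jointly estimated network are not independent, and the test should be
  read as descriptive of the density difference.
* **Permutation network comparison test** (`nct()`): indicators are the
  global-strength difference $|S_A - S_B|$, $S = \sum_{i<j}|w_{ij}|$, and
  the structure statistic $M = \max_{i<j}|w^A_{ij} - w^B_{ij}|$. The null
  distribution pools the two groups' residualized rows and reassigns them
  at random to pseudo-groups of the original sizes, re-estimating both
  networks with the full path-plus-EBIC procedure each time. p-values use
  the add-one convention $(1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$,
  so they are never zero and the test is valid at finite $B$. The study
  default is $B = 5000$; tests and the acceptance script use $B = 200$ for
  time. Residualization is done once, before pooling (re-residualizing
  inside each permutation is a documented option, off by default for
  speed). Across the six group pairs, the six strength tests and the six
  structure tests are Holm-corrected as two separate families.

### Accuracy and stability

* **Edge accuracy** (`bootstrap_edges()`): nonparametric case resampling
  (the parametric bootstrap is biased under LASSO regularization),
  percentile 2.5/97.5 intervals, default $B = 2500$; edges whose CI
  excludes zero are flagged. Results are reported sorted by sample edge
  weight, descending.
* **Centrality stability** (`case_dropping()`, `cs_coefficient()`): for
  each drop proportion $q$ in a grid (default 0.05–0.75 in steps of 0.05),
  $B = 1000$ subsamples without replacement of size $\lceil(1-q)n\rceil$
  are re-estimated and their centralities correlated with the full-sample
  ones. The CS-coefficient is the largest tested $q$ at which at least 95%
  of subsamples correlate $\ge 0.7$; values above 0.25 are conventionally
  deemed stable. The correlation floor, probability level and grid are all
  arguments (the methodology fixes only the 0.25 decision cutoff), and
  replicates with undefined correlations (constant centrality vectors, the
  empty-network case) are excluded from the denominator but counted and
  reported.

## The synthetic-cohort generator

No patient data ship with the package; the generator exists so that every
downstream stage can be tested against known ground truth.

**Mechanism.** `make_precision_model()` draws a random edge set of
$\lfloor \text{density} \cdot p(p-1)/2 \rfloor$ pairs and partial
correlations with magnitudes uniform in `weight_range`, signs random by
default. The precision matrix is assembled with unit diagonal and
$-w_{ij}$ off-diagonal; if it is not positive definite, all off-diagonal
entries are scaled by 0.9 repeatedly until it is (preserving the zero
pattern), and the true partials are always recomputed from the final
matrix. `sample_group()` draws latent vectors from the implied
multivariate normal, adds a per-item severity shift plus linear effects of
centred age and sex *on the latent scale*, and discretizes at thresholds
(−0.5, 0.5, 1.5) into 0–3 scores — a Gaussian-copula-style mechanism whose
contract is only that the true conditional-independence structure is
known. The default thresholds give the right-skewed item distributions
typical of community samples; they are configurable.

**Study conditions.** `four_group_fixture()` fixes the conditions used
throughout the tests: group sizes 294/118/184/257; the two clinical groups
share one dense structure (119 of 210 edges, scaled for other $p$) and
differ only in severity shift (CD +1.0, RD −0.1 — remitted severity at or
below the healthy-control level); subthreshold depression has its own
sparse structure (20 edges); healthy controls are conditionally
independent (no edges). Age acts at 0.01 latent SD per year and sex at 0.2
latent SD, small relative to the group shifts, as covariates should be.

Two fixture-level design choices deserve emphasis, both made on
ground-truth properties:

* **Random edge signs for the dense structure.** With all-positive partial
  correlations, positive-definiteness caps the magnitudes of a 119-edge
  graph near 0.08, far too weak to estimate from 118 observations of
  discretized data; mixed signs allow realistic magnitudes
  (`weight_range = c(0.12, 0.3)` before PD scaling). The estimated
  networks remain the object of study; only the latent truth mixes signs.
* **A total-covariation floor.** Among random dense structures, those
  whose implied latent correlation matrix has small total covariation
  ($-\log\det$ below about 0.6 nats per node) sit on the wrong side of
  EBIC's selection boundary at $n = 118$ and estimate as empty — they do
  not emulate the strongly interconnected symptom system that defines a
  clinical "dense" group. The fixture therefore rejection-samples dense
  structures until the floor is met (best candidate of 50 draws when the
  floor is unreachable, as at small $p$). The criterion is computed from
  the ground truth alone, never from estimation results. The sparse
  structure instead uses stronger per-edge weights
  (`c(0.25, 0.4)`): the few retained connections of a subthreshold group
  are its strongest ones, and edges too weak ever to detect would make the
  fixture useless as a test-bed.

**What the generator does not emulate.** Real item marginals calibrated to
published norms; mostly-positive edge signs in the ground truth;
measurement error beyond discretization; longitudinal structure; missing
data mechanisms (the reader contract is listwise deletion, a documented
choice — the methodology is silent on missing data). Passing tests
therefore show that the pipeline recovers *its own* ground truth under
realistic sizes and ordinal censoring, not that any particular clinical
dataset would behave identically.

## Problem sizes used in tests and the acceptance script

Simulation-based checks run at deliberately chosen desk scales: estimator
operating characteristics on a 6-node chain (partials 0.4) at
$n \in \{100, 500, 2000\}$ and a 10-node sparse model; permutation-test
calibration with 200 replicates of two $n=200$ groups at $B=200$;
bootstrap coverage with 200 replicates at $p=5$, $n=300$, $B=200$;
stability at $n=5000$ with a coarse drop grid; and ten full four-group
fixtures at the study's sizes. The full-scale defaults
($B = 5000$ permutations, $B = 2500$ bootstraps, the 0.05–0.75 grid)
remain the exported defaults.

## Known limitations

* Pearson correlations on 0–3 items attenuate latent associations;
  recovery at the remitted-group sample size is near EBIC's selection
  boundary, which is visible in the fixture's occasional (≈1 in 15)
  failure to estimate a dense remitted network.
* The chi-square edge-ratio test ignores dependence among jointly
  estimated edges (inherited from the method; documented above).
* Closeness and betweenness are substantially less stable than strength
  under case dropping — the stability module exists precisely to quantify
  this, and the CS-coefficient should gate any centrality interpretation.
* The NCT refits the estimator inside every permutation; with
  $B = 5000$ and four groups this is minutes of compute at $p = 21$. The
  implementation is C++-backed, but the cost is inherent to the design.
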