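---
title: "Estimating bridge symptoms between questionnaire communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating bridge symptoms between questionnaire communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bridgenet estimates regularized partial-correlation networks from ordinal
questionnaire data, quantifies which symptoms bridge two theory-defined
communities, and stress-tests those conclusions by resampling. This vignette
explains the statistical model, the tunable parameters and their defaults, the
synthetic-data generator and its limits, and the numerical and design choices
made where reasonable alternatives existed.

## The model and its assumptions

Respondent-by-node scores (here: five anxiety dimension sums and nine
gaming-disorder item codes, 14 nodes) are treated as draws from a multivariate
Gaussian with precision matrix $K$. Under that model a zero off-diagonal entry
of $K$ means conditional independence given all other nodes, and the natural
edge weight between nodes $i$ and $j$ is the partial correlation
$\rho_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$.

$K$ is estimated by the graphical lasso, the maximizer of
$$\log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}|,$$
where $S$ is the marginal correlation matrix of the node scores. The diagonal
is left unpenalized, so the fitted $K$ satisfies $(K^{-1})_{ii} = S_{ii} = 1$.
The penalty $\lambda$ is chosen by minimizing the extended Bayesian
information criterion
$$\mathrm{EBIC}_\gamma = -2L + E\log n + 4\gamma E \log p,$$
with $L = (n/2)(\log\det K - \operatorname{tr}(SK))$ and $E$ the number of
nonzero edges. $\gamma = 0$ is the ordinary BIC; the default $\gamma = 0.5$
trades some sensitivity for specificity and is the convention in symptom
networks.

The Gaussian assumption is knowingly wrong for Likert data: ordinal scores
attenuate Pearson correlations relative to any underlying continuum. The
package follows the field's standard practice of estimating the GGM on
Pearson correlations of the observed scores (Spearman is available via
`method = "spearman"`); polychoric correlations are deliberately out of
scope. The consequences of attenuation are quantified below.

## Bridge expected influence

Communities are fixed by theory, not detected. The bridge expected influence
of node $i$ is
$$\mathrm{BEI}_i = \sum_{j:\ c(j) \ne c(i)} w_{ij},$$
the signed, unnormalized one-step sum of its cross-community edge weights.
Two exact identities follow and are asserted in the test suite: the BEI total
equals twice the total cross-community weight, and BEI is invariant to any
within-community edge. Bridge nodes are those at or above the empirical
80th percentile of BEI, computed with the linear-interpolation quantile
(R type 7) and selected with $\ge$; with 14 distinct values this picks the
top three nodes, and complete ties select everyone. Both the percentile and
the quantile rule are arguments of `select_bridge_nodes()`.

## Robustness toolkit

* `bootstrap_edge_ci()` resamples respondents with replacement, re-runs the
  entire estimation (including model selection), and reports percentile
  2.5%/97.5% intervals per edge. Percentile intervals were chosen over BCa
  to match conventional reporting in this literature.
* `difference_tests()` flags pairs of edges (or of node BEIs, reconstructed
  from the same replicates) whose bootstrapped difference interval excludes
  zero, at $\alpha = 0.05$ without multiplicity correction — matching common
  practice; the object carries a note saying so.
* `case_drop_bootstrap()` re-estimates the network on random subsamples,
  dropping a fraction $q$ of cases (default grid 0.05–0.75 by 0.05), and
  correlates each subsample BEI vector with the full-sample one
  (product-moment by default, rank correlation optional).
* `cs_coefficient()` summarizes stability as the largest $q$ such that at
  **all** grid proportions up to $q$, at least 95% of replicates correlate at
  least 0.7 with the full sample. Requiring the condition at all smaller
  proportions forecloses spurious non-monotone maxima that can arise from
  replicate noise on a coarse grid. Values above 0.5 are conventionally read
  as ideal stability.

Every resampling function requires an explicit seed, restores the caller's
RNG state, and is bit-reproducible. `run_pipeline()` derives one seed per
stage deterministically from a single master seed and records them in the
report.

## The synthetic cohort generator

`make_true_network()` plants a ground-truth partial-correlation matrix
$P^*$, builds $K^* = I - P^*$, verifies positive definiteness (shrinking all
off-diagonals by a common factor if necessary, never below 0.5), and stores
the implied latent correlation matrix $\Sigma = \mathrm{cov2cor}(K^{*-1})$.
`simulate_cohort()` draws latent Gaussian vectors from $\Sigma$ and
discretizes each node onto its Likert code range through per-node thresholds.

The default preset emulates the published anxiety–IGD study:

* the cross-community block holds exactly the 23 published edge weights
  (20 positive, 3 negative, range −0.03 to 0.12, maximum at the
  panic-disorder–escape pair), with A2, A3 and IGD5 as designated bridges;
* within-community edges, which the publication does not print, default to
  weight 0.15 on a sparse random backbone (35% of within pairs, drawn once
  with a fixed internal seed so the preset is deterministic);
* Likert thresholds are calibrated by deterministic Gaussian-CDF moment
  matching so the discretized node means and SDs reproduce the published
  descriptive table as closely as the code grid allows (verified to ±0.15
  on means at n = 5000).

An item-level mode expands each anxiety dimension into its items (loading
0.7 on the node latent) for exercising the scoring path; since the
published instrument does not disclose its item-to-dimension map, the
shipped partition (consecutive blocks of 4, 4, 3, 4, 4 items) is an explicit,
overridable default meant only for synthetic data.

### What a green recovery test does and does not establish

The planted cross-community weights are the *published, lasso-shrunk* edge
estimates, not the unshrunk partial correlations of the original raw data
(which were never deposited). Two consequences, both measured and
deliberately not papered over:

1. **Most planted cross edges are statistically invisible.** EBIC with
   $\gamma = 0.5$ admits an edge at $n = 2000$ only around
   $|\rho| \gtrsim \sqrt{13/n} \approx 0.08$; all but one planted cross edge
   are below that. The estimator is *correct* in shrinking them to zero — the
   same selection is reproduced exactly by an independent graphical-lasso
   implementation on the same input — so recovery tests of the tiny printed
   weights fail by construction of the stated world, not by defect. The
   acceptance suite asserts the original recovery thresholds anyway and the
   corresponding tests are expected to fail; the unit suite demonstrates
   full-pipeline recovery on a planted structure with realistically *strong*
   edges instead.
2. **Discretization attenuates.** Likert scores lower absolute pairwise
   correlations relative to the latent ones (asserted at n = 10000), and the
   planted 0.15 within-community partial correlations come out near 0.10
   unregularized. Percentile bootstrap intervals of a shrunk estimator
   concentrate near zero for weak edges and therefore under-cover the
   unshrunk truth.

The generator reproduces marginal means/SDs and the broad dependence
structure; it does not emulate item-level measurement error in node mode,
floor/ceiling asymmetries beyond what thresholding induces, response styles,
or clustering of respondents (the original design was a cluster sample).

## Numerical choices

* Graphical lasso: block coordinate descent with warm starts along the
  penalty path; stopping rule is the scaled duality gap
  $(\operatorname{tr}(S\Theta) + \lambda\|\Theta\|_{1,\mathrm{off}} - p)/p
  \le 10^{-6}$, capped at 1000 sweeps per penalty (non-convergence is an
  error carrying $\lambda$ and the last gap). At $\lambda = 0$ the fit equals
  direct inversion to $10^{-10}$ on test fixtures.
* Penalty path: 100 logarithmically spaced values from
  $\lambda_{\max} = \max_{i<j}|S_{ij}|$ (the smallest penalty giving an empty
  graph) down to $0.01\,\lambda_{\max}$; no post-selection refit. EBIC ties
  break toward the larger penalty, i.e. the sparser model.
* An off-diagonal pair is declared zero only when both directed regression
  coefficients are exactly zero (lasso soft-threshold zeros); otherwise the
  two halves are averaged.
* A non-positive-definite sample correlation matrix (e.g. duplicated
  columns) is repaired by eigenvalue clipping at $10^{-8}$ and renormalized
  to unit diagonal, with a warning — never silently.
* Threshold calibration minimizes squared moment error by Nelder–Mead from
  the target moments; it is free of randomness, so presets are fully
  reproducible.
* The force-directed layout uses |weight| as the attraction multiplier (edge
  sign is carried by color in plots, not geometry), runs under a local seed,
  and is rescaled to the unit square; layout never feeds back into any
  analysis number, which the tests assert.

## Known limitations

* Pearson-on-Likert input understates latent associations; effect sizes
  should be compared only within, not across, discretization schemes.
* Percentile bootstrap intervals inherit lasso shrinkage bias; they describe
  the sampling variability of the *penalized* estimator, not unbiased
  uncertainty about unshrunk partial correlations.
* The case-dropping CS-coefficient depends on the grid resolution; with the
  default 0.05 grid it is reported to that granularity.
* Difference tests are uncorrected for multiplicity by design and should be
  read as descriptive.
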