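# bridgenet

Symptom-network analysis for questionnaire data: regularized partial-correlation
networks (graphical lasso with extended-BIC model selection), bridge centrality
between theory-defined symptom communities, and bootstrap robustness
diagnostics — with a calibrated synthetic Likert cohort generator so the whole
pipeline can be validated against planted ground truth.

The package is aimed at psychometric / epidemiological network studies of the
kind that relate two symptom domains — the motivating application is the
anxiety–internet-gaming-disorder (IGD) network in children, with five anxiety
dimensions (SCAS-S) and nine IGD diagnostic criteria (IGDS) as the 14 nodes —
but every step is generic over scales, communities, and node counts.

## The model

Node scores are modelled as Gaussian with precision matrix `K`. Edges of the
network are partial correlations

```
rho_ij = -K_ij / sqrt(K_ii * K_jj)
```

`K` is estimated by the graphical lasso: the maximizer of the L1-penalized
log-likelihood `log det K - tr(S K) - lambda * sum_{i!=j} |K_ij|` (diagonal
unpenalized), computed over a decreasing penalty path and selected by the
extended Bayesian information criterion

```
EBIC = -2 L + E log n + 4 gamma E log p ,   gamma = 0.5
```

with `E` the number of nonzero edges. The bridge expected influence (BEI) of a
node is the signed sum of its edge weights to all nodes of *other* communities;
nodes at or above the 80th percentile of BEI are flagged as bridge symptoms.
Robustness is assessed by nonparametric bootstrap of edge weights (percentile
95% CIs), bootstrapped difference tests, and a case-dropping bootstrap of BEI
summarized by the correlation-stability (CS) coefficient — the largest fraction
of cases that can be dropped while the subsample BEI still correlates ≥ 0.7
with the full-sample BEI in ≥ 95% of replicates.

## Worked example

Bridge arithmetic on the published anxiety–IGD cross-community edge list
(shipped with the package):

```r
library(bridgenet)
library(dplyr)

bt <- bridge_expected_influence(published_edge_network())
arrange(bt, desc(bei))
#> # A tibble: 14 × 4
#>   node  community   bei percentile_rank
#> 1 A2    anxiety   0.21            100
#> 2 A3    anxiety   0.21            100
#> 3 IGD5  IGD       0.21            100
#> 4 A5    anxiety   0.173            78.6
#> ...

glance(cross_community_edges(published_edge_network()))
#> # A tibble: 1 × 5
#>   total positive negative positive_share max_possible
#> 1    23       20        3           87.0           45
```

A2 (social phobia), A3 (panic disorder) and IGD5 (escape) are the three
top-80th-percentile bridge nodes; 23 of the 45 possible cross-community edges
are nonzero, 86.96% of them positive.

End-to-end pipeline on a synthetic cohort with a strong planted two-community
structure (six nodes, cross edges +0.3 and −0.2 planted between `L1–R1` and
`L3–R3`):

```r
labels <- c("L1","L2","L3","R1","R2","R3")
P <- matrix(0, 6, 6, dimnames = list(labels, labels))
P["L1","L2"] <- P["L2","L1"] <- 0.35; P["L2","L3"] <- P["L3","L2"] <- 0.3
P["R1","R2"] <- P["R2","R1"] <- 0.35; P["R2","R3"] <- P["R3","R2"] <- 0.3
P["L1","R1"] <- P["R1","L1"] <- 0.3;  P["L3","R3"] <- P["R3","L3"] <- -0.2
spec <- make_true_network(
  pcor = P,
  communities = setNames(rep(c("left", "right"), each = 3), labels),
  targets = NULL
)
scores <- simulate_cohort(spec, n = 600, seed = 42)
report <- run_pipeline(list(scores = scores, seed = 7, B = 200,
                            grid = seq(0.1, 0.7, 0.1)))
report
#> <analysis_report>
#>   nodes: 6 (2 communities), edges: 8, lambda = 0.03222
#>   cross-community edges: 4 (positive share 50.00%)
#>   bridge nodes (top 80%): R1, L1
#>   CS-coefficient (BEI): 0.70
```

The planted bridge pair `L1`/`R1` tops the BEI ranking, the planted cross
edges are recovered with the expected lasso shrinkage (`L1–R1` estimated
0.33), and the BEI ranking survives dropping up to 70% of the cases
(CS = 0.70, "ideal" by the > 0.5 convention).

The default preset `make_true_network()` instead reproduces the *published*
14-node world: the 23 printed cross-community weights, Likert thresholds
calibrated to the published node means/SDs, and a sparse within-community
backbone. Because those printed weights are themselves already
lasso-shrunk estimates, that world is deliberately weak — see the methods
vignette (`vignettes/symptom-networks.Rmd`) for what recovery tests can and
cannot establish there.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the shipped published-edge fixture and the package's own
bridge-centrality code, the bridge expected influence of the panic-disorder
node (A3) and writes it as JSON.
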