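# mcmcModules

Soft classification of active modules in biological interaction networks by
Markov chain Monte Carlo.

## What it does

Given an undirected interaction network (e.g. protein–protein interactions)
and a p-value per vertex (e.g. from a differential-expression test),
classical active-module methods return one best-scoring connected subnetwork
— a hard in/out call per gene with no confidence attached. `mcmcModules`
instead estimates, for every vertex `v`, the posterior probability
`p_v = P(v ∈ M | W = w)` that it belongs to the active module `M`, by
sampling connected subgraphs from the posterior with a Metropolis–Hastings
chain.

The model: p-values follow a beta-uniform mixture (BUM) with density
`λ + (1 − λ) a x^(a−1)` — uniform noise with weight `λ` plus a `β(a, 1)`
signal component (`a < 1`). Module vertices carry beta-distributed weights,
background vertices uniform ones. Under a uniform prior over connected
subgraphs of fixed order, the posterior of a candidate module `S` is
proportional to `∏_{v∈S} w_v^(a−1)`, and the chain's acceptance ratio for
swapping vertex `v−` for frontier vertex `v+` is
`min{1, (w₊/w₋)^(a−1) · |nei(S)|/|nei(S′)|}`. A variable-order variant
penalizes each vertex by `a τ^(a−1)` (confidence threshold `τ`, default
`1e-7`), giving the stationary law `π(S) ∝ ∏_{v∈S} (w_v/τ)^(a−1)`.

From the sampled collection the package computes:

* per-vertex membership probabilities and probabilities of arbitrary
  boolean events about the module;
* the FDR of any vertex set (mean of `1 − p_v`);
* the expected AUC ROC of any vertex ranking, in closed form:
  `1 − (Σᵢ i·pᵢ − m(m+1)/2) / (m(n−m))` for module order `m`
  (plus an unknown-order variant);
* a *connectivity-preserving* ranking (every prefix induces a connected
  subgraph) via an O(n³) peeling heuristic, so that thresholding at any FDR
  level `q` yields nested modules `M(q₁) ⊆ M(q₂)` for `q₁ < q₂`.

Exact oracles (full enumeration of connected subgraphs, exact posteriors,
brute-force optimal CP ranking) and a synthetic-instance generator with
planted modules are included for validation and benchmarking.

## Worked example

```r
library(mcmcModules)

# a synthetic benchmark instance: scale-free graph, planted connected module,
# BUM weights with a = 0.1
inst <- generate_instance(100, model = "scale_free", a = 0.1, seed = 7)
#> synthetic_instance: 100 vertices, 197 edges (scale_free), planted module of 21, a = 0.100

fit <- fit_bum(inst$weights)
#> BUM fit: lambda = 0.8140, a = 0.1034  (n = 100, loglik = 91.17)
k <- estimate_module_order(fit, inst$graph$n)   # 19

s <- run_mcmc(inst$graph, inst$weights, mode = "fixed", k = k, a = fit$a,
              n_iterations = 1e5, burn_in = 25000, seed = 8)
p <- estimate_vertex_probabilities(s)

rk <- ocpr_heuristic(inst$graph, p)     # connectivity-preserving ranking
mod <- module_at_fdr(rk, 0.25)          # 22 vertices
set_fdr(p, mod)                         # 0.245
empirical_auc(rk, inst$module)          # 0.975 against the planted truth
expected_auc(rk, p, k)                  # 0.963 (closed form)
```

The fitted mixture (`λ ≈ 0.81`, `a ≈ 0.10`) recovers the generating signal
(21 of 100 vertices planted, `a = 0.1`); the module extracted at FDR 0.25
has 22 vertices with an achieved FDR of 0.245, and the ranking separates the
planted module from the background with AUC 0.975.

A thin command-line wrapper over the same functions is installed at
`inst/cli/activemodule.R`; `Rscript activemodule.R --help` lists the
subcommands (`fit-bum`, `sample`, `oracle`, `rank`, `module`, `auc`,
`simulate`, `full`). The `full` subcommand chains
fit → sample → rank → extract and writes probabilities, ranking, per-FDR
module files, the likelihood trace and a provenance record.

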