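# itspread

Predicting nodal spreading influence from local iterative topological
metrics.

## The problem

On a contact network, the *spreading influence* of a node is the expected
final outbreak size of an epidemic seeded at that node — here the
continuous-time Markov SIR process with per-edge infection rate β and
recovery rate γ (effective rate λ = β/γ). Knowing which nodes are
influential matters for epidemic control, viral marketing and information
diffusion, but brute-force estimation (simulating from every node) and
global centralities (eigenvector, PageRank, closeness) are expensive on
large graphs.

`itspread` implements influence prediction from *iterative metric sets*:
for three classical centralities, the package exposes the iterates of the
computation that converges to them, each order k using only the k-hop
neighborhood of a node,

| metric set | order-1 value | update | converges to |
|---|---|---|---|
| NWC | u/√N step: degree ranking | w⁽ᵏ⁾ = A w⁽ᵏ⁻¹⁾/‖A w⁽ᵏ⁻¹⁾‖₂ | eigenvector centrality |
| VP  | teleporting walk, 1 step | pᵢ⁽ᵏ⁾ = α Σⱼ Aⱼᵢ pⱼ⁽ᵏ⁻¹⁾/dⱼ + (1−α)/N | PageRank (α = 0.85) |
| HI  | degree | hᵢ⁽ᵏ⁾ = H[neighbor values] | coreness |

The orders 1..K form the feature matrix of a node-level regression
(random forest by default): the model is trained on the ~10% of nodes
whose influence is known and predicts the rest. Prediction quality is
measured by r², Kendall's τ-b (with tie terms), and the top-10%
recognition rate, averaged over independent training-split realizations.
A seven-centrality benchmark model (degree, neighborhood, two-hop
neighborhood, coreness, eigenvector, PageRank, closeness) provides the
comparison point. Already at K ≈ 4 the NWC-based model matches the
benchmark on small-world networks, at O(K·|E|) feature cost.

The package also provides: an exact event-driven SIR simulator (C++ core,
per-(node, run) RNG substreams), epidemic-threshold estimation by
maximizing the variability √(⟨ρ²⟩−⟨ρ⟩²)/⟨ρ⟩ of nodal influence over λ, an
LFR benchmark-network generator with planted communities mirroring the
canonical construction, readers for plain and KONECT-style edge lists,
and structural descriptors (diameter, Newman modularity, k-hop coverage).

## Worked example

Generate an LFR network with communities (N = 1000, mixing μ = 0.05),
estimate its epidemic threshold, compute ground-truth influence at λ_c,
and compare the NWC(K = 4) model against the seven-centrality benchmark:

```r
library(itspread)

net <- generate_lfr(1000, mu = 0.05, seed = 1)
g <- net$graph

scan <- estimate_threshold(g, lambda_grid = seq(0.01, 0.20, by = 0.01),
                           config = sir_config(beta = 1, runs = 500, seed = 2),
                           sample_size = 300)
scan$lambda_c
#> [1] 0.08

infl <- estimate_influence(g, config = sir_config(beta = scan$lambda_c,
                                                  runs = 1000, seed = 3))
head(infl, 3)
#>   node influence   stderr runs
#> 1    1     7.500 0.709553 1000
#> 2    2    20.101 1.283349 1000
#> 3    3    17.312 1.070063 1000

cfg <- experiment_config(q = 0.10, realizations = 50, K = 4, rng_seed = 4)
summary(run_experiment(nwc_iterate(g, 4), infl, cfg))
#>            measure      mean         sd
#> 1        r_squared 0.8978418 0.01659951
#> 2      kendall_tau 0.8073927 0.00771418
#> 3 recognition_rate 0.8102222 0.02287477
summary(run_experiment(benchmark_centralities(g), infl, cfg))
#>            measure      mean         sd
#> 1        r_squared 0.9036148 0.01838121
#> 2      kendall_tau 0.8242732 0.00653218
#> 3 recognition_rate 0.8148889 0.02940666
```

Read: the threshold scan places λ_c at 0.08; a node's influence at that
rate is its mean outbreak size over 1000 simulations (node 2 infects ≈ 20
nodes on average when it seeds the epidemic, node 1 only ≈ 7.5). Trained
on a random 10% of nodes, the NWC(4) model explains ≈ 90% of the
influence variance on the held-out nodes, rank-correlates at τ ≈ 0.81
with the simulated influence, and recovers ≈ 81% of the true top-10%
spreaders — within 1–2% of the seven-centrality benchmark on every
measure, while using only 4-hop information.

`run_k_sweep()`, `run_correlation_profiles()` and `run_lambda_sweep()`
reproduce the full experiment grids (prediction quality vs K, per-order
correlation with influence and with the converged centrality, and
robustness across λ/λ_c ∈ {0.5, 1, 1.5, 2}); `run_experiment_manifest()`
drives all of it from a single seeded manifest and writes CSV tables. A
thin command-line front end lives in `inst/cli/itspread-cli.R`.

## Documentation

The methods vignette (`vignettes/influence-prediction.Rmd`) documents the
model and its assumptions, the estimator and generator design choices,
numerical tolerances, and known limitations.
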