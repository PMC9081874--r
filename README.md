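# wcnet — connectome-coupled Wilson–Cowan network dynamics

`wcnet` builds and evaluates whole-brain network models in which every
cortical region is a Wilson–Cowan excitatory/inhibitory neural-mass pair,
coupled through a directed binary connectome. It is aimed at researchers who
want to understand *why* such models fit resting-state functional
connectivity (FC): instead of treating the fit as a black box, the package
analyses each region's dynamical repertoire — fixed points, bistability,
limit cycles — as a function of the net input it receives from the rest of
the network.

## The model

Each region obeys

```
tau_e dE/dt = -E + (1 - E) S(a_e w_ee E - w_ei I - B_e + J_e)
tau_i dI/dt = -I + (1 - I) S(a_i w_ie E - w_ii I - B_i)
```

with logistic gain `S(v) = h / (1 + exp(-v))` and inter-regional coupling
`J_e^(a) = G * sum_b A_ab E^(b)` over a binary directed adjacency `A`. All
single-node analysis is expressed in the net input `J_tot = J_e - B_e`.
Regional heterogeneity enters by scaling each population's output weights
with z-scored excitatory/inhibitory cell densities:
`w_xy^(a) = w_xy * (1 + sigma * z^(a))`, where `sigma = 0` recovers the
homogeneous model exactly.

The package provides, as separately testable layers:

* **Bifurcation analysis** — equilibrium branches over `J_tot`, stability,
  saddle-node and Hopf detection, simulation-based limit-cycle envelopes,
  regime classification, and perturbation studies of the diagram under
  cell-density-style weight changes.
* **Stochastic simulation** — a compiled Euler–Maruyama integrator
  (bit-reproducible under `set.seed`), transient handling, per-region input
  ranges, attractor-occupancy annotation, carpet-plot data.
* **Evaluation** — FC computation, the Spearman FC–FC score over unique
  region pairs, the SC–FC baseline, `G`–`B_e` and `sigma` sweeps with seed
  replicates, and a permutation test against shuffled cell-density maps.
* **Synthetic data** — generators for connectomes (heavy-tailed in-degree),
  correlated density maps, and target FC matrices planted at a known working
  point, so the full analysis runs end to end without external data.

## Worked example

Classify the shipped limit-cycle regime and fit a synthetic 12-region study
at its planted working point:

```r
library(wcnet)

p <- regime_params("limit_cycle")
d <- annotate_diagram(trace_branches(p, c(-5, 3), 121), envelope_points = 61)
print(d)
#> Bifurcation diagram over J_tot in [-5, 3] (121 samples, 1 branch(es))
#>   folds: 0
#>   Hopf points: 2
#>   limit-cycle envelope: 12 oscillatory of 61 samples
round(d$hopfs, 4)
#>     J_tot      E     im
#> 1 -2.5363 0.1396 0.0724
#> 2 -0.9134 0.3523 0.1040

spec  <- synth_spec(N = 12, seed = 1)
con   <- synth_connectome(spec)
model <- build_network(con, p, G = 0.5)
target <- synth_target_fc(model, sim_config(T = 1e4, seed = 501, store_every = 10),
                          observation_noise_sd = 0.05, noise_seed = 901, n_avg = 5)
rs <- replicate_scores(model, sim_config(T = 1e4, seed = 1, store_every = 10),
                       target, n_rep = 3, seed_base = 100)
sprintf("rho_FCFC = %.3f +/- %.3f", rs$mean, rs$sd)
#> "rho_FCFC = 0.991 +/- 0.002"
sprintf("rho_SCFC = %.3f", scfc_score(con, target))
#> "rho_SCFC = -0.028"
```

Reading the output: the node has two Hopf bifurcations at
`J_tot = -2.54` and `-0.91` mV bounding a window of stable oscillations
(eigenfrequency `im` in rad/ms, i.e. periods of roughly 60–90 ms). The
model at the true working point reproduces the planted target FC almost
perfectly (`rho_FCFC ≈ 0.99` across three replicate seeds), while the raw
structural matrix alone carries no rank information about this oscillatory
FC (`rho_SCFC ≈ 0`) — coupling the dynamics, not the wiring by itself, is
what produces the correlation structure here.

The `analysis/` directory holds the full workflow as numbered drivers
(`01_synthesize_data.R` … `05_heterogeneity.R`): data synthesis, regime
diagrams and perturbation studies, network simulation with occupancy
annotation, the `G`–`B_e` sweep against the target, and the heterogeneity
sweep with its permutation test. Each writes tables (and figures, if
ggplot2 is installed) under `results/`.

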