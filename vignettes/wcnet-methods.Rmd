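---
title: "Methods: connectome-coupled Wilson-Cowan dynamics in wcnet"
author: "wcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-coupled Wilson-Cowan dynamics in wcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Each cortical region is a Wilson-Cowan pair: a mean excitatory rate
$E(t)$ and a mean inhibitory rate $I(t)$, both dimensionless in $[0, 1]$,
evolving as

$$\tau_e \dot E = -E + (1 - E)\, S(a_e w_{ee} E - w_{ei} I - B_e + J_e),$$
$$\tau_i \dot I = -I + (1 - I)\, S(a_i w_{ie} E - w_{ii} I - B_i),$$

with the logistic gain $S(v) = h / (1 + e^{-v})$ and $h = 1$ by
convention (kept as an explicit parameter so the sigmoid contract is
testable at other values). The $(1 - E)$ and $(1 - I)$ refractory factors
make the unit box forward-invariant under the deterministic flow, which
is the basis of several simulator contracts in the test suite.

Regions are coupled through their excitatory populations only. With a
binary directed adjacency $A$ (row $a$ lists the afferents of region $a$)
and a global coupling constant $G$,

$$J_e^{(a)}(t) = G \sum_b A_{ab} E^{(b)}(t),$$

and the *net input* $J_{tot} = J_e - B_e$ is the coordinate in which all
single-node analysis is expressed: a region's dynamical repertoire is a
function of the aggregate drive it receives relative to its firing
threshold.

Internal units are millivolts and milliseconds throughout. Some
published parameterisations of this model family are quoted in V and s;
`params_from_vs()` converts them.

### Regional heterogeneity from cell densities

The heterogeneous model assumes local connectivity from each population
is uniform, so coupling strength from a population is proportional to
the density of its cells. Excitatory and inhibitory cell-density maps
are z-scored across regions ($e^{(a)}$, $i^{(a)}$) and mapped to
relative weight perturbations through a single scaling parameter
$\sigma \ge 0$:

$$R_e^{(a)} = \sigma e^{(a)}, \quad R_i^{(a)} = \sigma i^{(a)},$$
$$w_{ee}^{(a)} = \hat w_{ee}(1 + R_e^{(a)}), \quad
  w_{ie}^{(a)} = \hat w_{ie}(1 + R_e^{(a)}), \quad
  w_{ii}^{(a)} = \hat w_{ii}(1 + R_i^{(a)}), \quad
  w_{ei}^{(a)} = \hat w_{ei}(1 + R_i^{(a)}).$$

$\sigma = 0$ reproduces the homogeneous model exactly — in this package
*bit*-exactly: the zero field returns the identical parameter objects, so
homogeneous and $\sigma = 0$ pipelines produce identical trajectories and
scores under matching seeds, and the test suite asserts this.

Two conventions deserve a note:

* **z-score denominator.** Densities are z-scored with the sample
  standard deviation ($N - 1$), so raw densities $(1, 2, 3)$ map to
  $(-1, 0, 1)$ and the z-scored maps have unit sample SD; the
  population-SD convention is available via an argument. Loaders z-score
  over the regions present in the connectome, after alignment.
* **Negative weights.** A field with $1 + R \le 0$ anywhere would demand
  a non-positive coupling weight. This is a hard error naming the
  offending regions, never a silent clamp — clamping would change the
  mapping itself.

## Nominal regimes

`regime_params()` ships three named single-node parameter sets chosen so
that an isolated node, as a function of $J_{tot}$, sits in qualitatively
different regimes:

| regime | structure | mechanism |
|---|---|---|
| `fixed_point` | one stable branch, monotone in $J_{tot}$ | weak recurrent excitation ($w_{ee} = 3$) |
| `hysteresis` | bistable window between two saddle-nodes | strong self-excitation ($w_{ee} = 12$), fast weak inhibition ($\tau_i = 5$ ms) |
| `limit_cycle` | oscillatory window between two Hopf points | strong excitation ($w_{ee} = 16$) balanced by slower inhibitory feedback ($\tau_i = 20$ ms) |

The sets are validated *by topology*: the test suite asserts the
classified regime, the exact fold and Hopf counts, and cross-validates
each against direct simulation (bistable settling from two initial
conditions; oscillation onset inside the Hopf window). They are not tied
to any particular published table — the published sources for this model
family differ among themselves in conventions — and the excitatory
threshold $B_e$ is a sweep axis anyway, so only the shape of the diagram
matters, not its absolute offset.

## Bifurcation machinery

**Equilibria.** The inhibitory equation is strictly decreasing in $I$ at
fixed $E$, so the I-nullcline $I^*(E)$ is unique and is found by
bisection; substituting it reduces equilibrium-finding to a 1-D
root-scan in $E$ over $[0, 1]$ (1001-point sign scan + `uniroot` +
2-D Newton polish). This model class admits 1-3 equilibria. The choice
of a reduction + scan over pseudo-arclength continuation is deliberate:
the state space is compact, roots are few, and a dense scan is robust to
branch birth/death, which is exactly where continuation needs care.

**Stability.** Analytic Jacobian (using $S' = S(h - S)/h$), eigenvalues
of the 2x2 linearisation; labels `stable`, `unstable-saddle`
(negative determinant), `unstable-focus` otherwise.

**Branches.** A uniform $J_{tot}$ grid (default 201 points) with
nearest-neighbour linking of roots between consecutive grid columns
(link tolerance 0.2 in the max-norm on $(E, I)$).

**Folds** are located by bisection on the *root count* between grid
points where it changes, refined to $10^{-6}$ mV; at the reported fold
point the Jacobian determinant vanishes to $\sim 10^{-8}$.

**Hopf points** are sign changes of $\mathrm{Re}\,\lambda$ of a complex
pair along a branch, refined by bisection (re-solving the tracked
equilibrium at each midpoint) to $10^{-6}$ mV, and only accepted when
$\mathrm{Im}\,\lambda \neq 0$ there. The imaginary part at the crossing
is reported: near a supercritical Hopf the simulated oscillation period
approaches $2\pi/\mathrm{Im}\,\lambda$, and a test asserts agreement
within 10%.

**Limit-cycle envelope.** Computed by direct deterministic simulation
rather than by continuation of the periodic orbit: for each probed
$J_{tot}$ the node is started just off the most unstable equilibrium,
integrated for 2 s of model time, the first 1 s discarded, and the
min/max of $E$ recorded. Peak-to-peak amplitude above $10^{-4}$ counts
as oscillatory; below it the envelope collapses onto the equilibrium.
Simulation was chosen because it measures the attractor the stochastic
network will actually visit, and because amplitude growth away from the
Hopf point doubles as an independent check on the eigenvalue analysis.

Default tolerances (all overridable through `bif_tol()`): root residual
$10^{-9}$, fold/Hopf bisection $10^{-6}$ mV, duplicate-root merge
distance $10^{-5}$, oscillation threshold $10^{-4}$.

## Stochastic simulation

Euler-Maruyama with fixed step:
$x_{k+1} = x_k + f(x_k)\,\Delta t + s \sqrt{\Delta t}\, \xi_k$,
$\xi_k \sim \mathcal N(0, 1)$ i.i.d. per state variable and step.
Defaults follow the reference protocol: $\Delta t = 0.1$ ms, total
duration $1.2 \times 10^5$ ms, noise SD $s = 1.3\times10^{-5}$, and a
1 s initial transient discarded before any statistic is computed. Two
ambiguities in that protocol were resolved as follows:

* *Transient length.* The protocol names both "1 s" and "1,000 time
  steps", which disagree at $\Delta t = 0.1$ ms. The duration (1 s =
  10,000 steps) is taken as authoritative; the discarded window is
  configurable.
* *Noise target.* The protocol says only that the system is driven by
  white noise. Noise is applied to **both** state variables (the
  convention of the simulator ecosystem this protocol came from), with a
  config flag to restrict it to $E$ only. $s$ multiplies $\sqrt{\Delta t}$
  per the update rule above, i.e. it is a noise *intensity*, not an
  increment SD.

After each step the state is clipped to $[0, 1]$: the deterministic flow
cannot leave the box, but noise can. Clips are counted and, at default
noise, essentially never occur (the suite asserts a clip fraction below
$10^{-6}$). A pre-clip excursion beyond $|x| > 10$ — possible only with
pathological settings — aborts with the offending region and step.

Initial conditions default to $E = I = 0.25$ plus seed-controlled jitter
of SD $10^{-3}$ (presets `low`, `high`, `random` and explicit states are
available); the reference protocol is silent on this point, and the
discarded transient makes the choice immaterial for steady-state
statistics. Replicate runs use seeds $\{s_0 + k\}_{k=0}^{n-1}$; a fixed
seed gives bit-identical output, and storage can be thinned
(`store_every`) independently of the integration step.

The integrator core is compiled (Rcpp), drawing its normals from R's RNG
so that `set.seed()` controls it. Contracts asserted in the suite:
zero-noise constancy at an equilibrium to $10^{-9}$ over $10^4$ steps;
bit-identical seeds; first-order convergence in $\Delta t$ (log-log
slope $1.0 \pm 0.2$); stationary variance under small noise within 20%
of the Lyapunov-equation solution of the linearised SDE.

## Evaluation

Functional connectivity is the matrix of pairwise Pearson correlations
between regional excitatory time series over the full retained window
(static FC, no windowing, no hemodynamic forward model). The **FC-FC
score** $\rho_{FCFC}$ is the Spearman rank correlation between the
$N(N-1)/2$ unique upper-triangle values of model and target FC — rank
correlation to capture monotone but possibly nonlinear agreement; ties
get average ranks. The **SC-FC baseline** $\rho_{SCFC}$ is the same rank
correlation between structural pair values and target FC; the directed
adjacency is reduced to one value per pair with
$\max(A_{ab}, A_{ba})$ by default (FC is undirected; a pair is
structurally connected if either direction is), with `mean` and `both`
switchable. Binary structural vectors make this correlation tie-heavy,
which is why the tie convention is documented.

Sweeps evaluate replicate scores (default 5 per cell for desk-scale
work; 40 is the reference full setting) on a $G \times B_e$ grid with
$B_e$ set uniformly across regions, or on a $\sigma$ axis with the
heterogeneous model rebuilt per value; infeasible $\sigma$ cells
(negative weights) are marked, not clamped. Default sweep axes
$G \in [0, 1]$ (21 points) and $B_e \in [1, 5]$ mV (21 points) cover the
regimes' sensitive windows.

The **permutation test** asks whether the *measured assignment* of
densities to regions explains the target FC better than chance: each of
the $n_{perm}$ null draws permutes the $(e, i)$ z-score pairs jointly
across regions (preserving the e-i match), rebuilds the model at the
tested $\sigma$, and records the mean replicate score;
$p = (1 + \#\{null \ge obs\}) / (n_{perm} + 1)$, one-sided. Permuting
z-scored rather than raw vectors is equivalent up to the z-scoring
convention and avoids re-standardising per draw; $n_{perm}$ defaults to
199 (the reference analysis does not state its count).

## The synthetic data generator

The generator produces the three inputs the analysis needs, with the
statistical structure the method assumes, so the whole pipeline runs and
is testable without any external data:

* **Connectome**: binary, directed, zero diagonal; heavy-tailed mode
  draws lognormal in-degree propensities (sdlog 0.8) so hub regions
  exist — the driver of the cross-regional diversity of net inputs —
  with per-row edge probabilities renormalised so the expected density
  matches the request. 37 regions and density 0.3 by default, matching
  the scale of a single-hemisphere cortical connectome.
* **Densities**: correlated lognormal pairs (common-latent construction;
  default e-i correlation 0.7, CV 0.2), strictly positive, with means in
  the range typical of cortical excitatory (~8e4/mm^3) and inhibitory
  (~1.2e4/mm^3) counts.
* **Target FC**: forward simulation of a ground-truth model, averaged
  over `n_avg` runs in Fisher-z space — emulating the group-average FC
  it stands in for, which is a mean over many subjects — plus symmetric
  Fisher-z observation noise. Generating the target from the same model
  family is a deliberate self-consistency choice: it makes recovery
  questions (does the sweep find the planted working point? does the
  permutation test find the planted density map?) well-posed.

What the generator does **not** emulate: the degree sequence or density
values of any real atlas, spatial embedding and distance-dependent
connection probability, hemodynamic filtering, measurement artefacts, or
subject-level variability beyond run-averaging. Passing the recovery
tests therefore shows the *method* is sound on data satisfying its own
assumptions — not that real cortical data satisfies them.

The planted fixture uses the limit-cycle regime at $G^* = 0.5$,
$B_e^* = 1.5$ mV. Near the Hopf window the FC pattern depends sharply on
which regions oscillate, so the working point is well identified; in the
fixed-point regime the rank structure of FC changes only slowly along a
$G$-$B_e$ ridge and a sweep cannot pin the working point tightly —
itself a finding about identifiability of such fits, and the reason the
recovery fixture is planted where the score surface is informative.

## Problem sizes used by the tests

The suite and the acceptance script run at deliberately small scale,
chosen as the smallest sizes at which each property is cleanly
measurable: fixtures of 6-12 regions; simulations of 1-10 s of model
time at the reference step; 7x7 sweep grids with 3 replicates; 99
permutations with 2 replicates per draw. The reference protocol's full
scale (37 regions, 120 s runs, 40 replicates, 21x21 grids) is available
by changing the corresponding arguments, and the `analysis/` drivers run
an intermediate scale.

## Known limitations

* No conduction delays, no distinct synaptic receptor kinetics, no
  multiple inhibitory subtypes, and no BOLD/hemodynamic forward model:
  scores compare neuronal-rate FC with the target directly.
* The sigmoid gain parameters $a_e, a_i$ multiply only the recurrent
  excitation term inside each sigmoid (the convention of the source
  equations); parameterisations from the wider literature may place the
  gain around the whole argument and need converting before use.
* Two-parameter bifurcation surfaces and Floquet analysis of cycle
  stability are out of scope; the envelope is simulation-based.
* The permutation test permutes region assignment only; it does not test
  against alternative spatial gradients.
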