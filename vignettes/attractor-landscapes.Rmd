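---
title: "Attractor landscapes of Boolean networks: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor landscapes of Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attractorscape)
```

# The modelling framework

A biomolecular network is abstracted as $N$ binary nodes $s_i \in \{0,1\}$
(a protein or gene is active or inactive) connected by signed, weighted
edges. Two synchronous update semantics are supported.

**Weighted-sum threshold dynamics.** Each node receives the net input

$$h_i(t) = \sum_j w_{ij}\, s_j(t) + b_i,$$

where $w_{ij}$ is the weight of the edge $j \to i$ and $b_i$ a constant
basal input modelling constitutive activation or repression. All nodes
update together:

$$s_i(t+1) = \begin{cases} 1 & h_i > 0\\ 0 & h_i < 0\\ s_i(t) & h_i = 0.\end{cases}$$

The hold-at-zero convention is the classical choice for the budding-yeast
cell-cycle model, and the bundled `yeast11` fixture reproduces that model's
published behavior exactly under it (seven fixed points, the largest basin
1764/2048). Self-degradation of unregulated transient proteins is encoded
as a small negative self-loop ($-0.1$): because every other net input in
such models is an integer, a $-0.1$ self-loop changes the sign of $h_i$
only when the rest of the input sums to zero — exactly the published
"decay when unregulated" rule.

**Rules-based dynamics.** Alternatively each node carries a Boolean update
rule (an expression over node names, or an explicit truth table); all rules
are evaluated synchronously on the current state. Nodes without a rule hold
their state (identity rule), so partial rule files remain usable; a warning
lists the affected nodes. Fixing a node (a mutation or a sustained drug
effect) overrides both semantics.

Because the synchronous map is total and the state space finite, every
trajectory enters a cycle: a **point attractor** (cycle length 1) or a
**cyclic attractor**. The set of initial states reaching an attractor is
its **basin of attraction**; its share of the analyzed space is the basin
fraction. Cycles are canonicalized by rotating the minimum state code (or
lexicographically minimal bit-key for networks above 53 nodes) to the
front, which makes attractor identity testable and deduplication exact.

# Deterministic analysis

`deterministic_analysis()` iterates the map over either the exhaustive
$2^N$ space (capacity-limited, default 24 nodes) or `k` states sampled
uniformly with replacement; duplicates count each time, matching the
uniform-propensity reading of basin size. Two result-equivalent engines
exist: a batch engine that advances all trajectories in lock step
(tortoise-and-hare cycle detection on matrix columns) and a per-trajectory
walk engine with an optional memo table. The walk engine is the
reference implementation; the batch engine is the default because it turns
the inner loop into matrix operations. A property test asserts they
produce identical results, and that memoization never changes output.

# Probabilistic analysis

Intrinsic signalling noise is modelled by softening the threshold rule.
With noise parameter $\mu > 0$ (an inverse temperature), a regulated node
switches on with probability

$$P(s_i(t+1)=1) = \frac{1}{1 + e^{-2\mu h_i}}, \qquad h_i \neq 0,$$

which recovers the deterministic rule as $\mu \to \infty$ and saturates
safely in floating point. For an *unregulated* node ($h_i = 0$) the
degradation constant $c \ge 0$ gives the per-step odds of a spontaneous
flip: the node retains its state with probability $1/(1+c)$. Thus $c = 0$
freezes unregulated nodes (the deterministic hold), $c = 0.01$ flips them
about once per hundred steps, and $c = 1$ is a fair coin. We considered
the alternative of placing $c$ inside the logistic exponent
($1/(1+e^{-2\mu c})$), but at the conventional operating point $\mu = 5$,
$c = 0.01$ that form yields retention $\approx 0.52$, which destabilizes
exactly the attractors whose nodes are mostly unregulated — for the yeast
network it makes the stationary-G1 state (9 of 11 nodes unregulated) a
minor state rather than the landscape's global mode. The flip-odds form
restores the published picture (G1 is the mode, $p \approx 0.35$ at
$\mu=5$, $c=0.01$), and a scan over retention values 0.95–0.9999 shows the
qualitative results do not depend on the precise mapping from $c$.

Synchronous updating makes nodes conditionally independent given the
current state, so the state-to-state transition probability factorizes,
$T(s'|s) = \prod_i P(s_i'|s)$; a fixed node contributes 1 or 0. Every
column of $T$ sums to one (tested to $10^{-12}$).

The steady state solves $p = Tp$. Two routes are provided:

* `exhaustive_steady_state()` iterates the master equation
  $p_{t+1}(s') = \sum_s T(s'|s)\,p_t(s)$ from the uniform distribution
  until the $L_1$ residual falls below `tol` (default $10^{-10}$, cap
  10,000 iterations; non-convergence is flagged in the metadata, not
  hidden). The dense matrix limits this to 14 nodes by default. A test
  checks the result against the dominant eigenvector of the explicit
  matrix on a small random network.
* `heuristic_steady_state()` simulates `n_traj` noisy trajectories from
  uniform random starts and counts all post-burn-in state visits; it
  scales to arbitrary $N$ and is seed-reproducible. Counting all visits
  (not only terminal states) is the natural estimator of the stationary
  distribution for this chain.

`most_probable_path()` follows the per-node argmax successor (ties broken
toward 0, i.e. the lowest state code), which for $c < 1$ coincides with
the deterministic successor — so in the low-noise regime greedy paths equal
deterministic trajectories, another tested invariant. On the yeast network
at $\mu=5$, $c=0.01$ the greedy path from the excited-G1 "start signal"
state is the 13-state physiological trajectory through S, G2 and M into
stationary G1. Steady-state probability rises along 10 of its 12
transitions; two small dips ($\approx 1\text{--}2\%$ relative, at the
S-to-G2 hand-off and within the M phase) remain. The M-phase dip persists
at every retention level we examined and appears to be a structural
feature of this stochastic formulation rather than a numerical artifact.

# Cell fates and perturbation screens

Fate logic is an ordered list of `FATE label: predicate` lines; the first
matching rule wins, so compound fates ("tumor progression = abnormal
proliferation **and** metastasis") must precede their components. For
cyclic attractors the aggregation policy decides how cycle states combine:
`any` (default — a marker active anywhere in the cycle counts), `all`, or
`majority`. Propensities aggregate basin fractions (deterministic input)
or probability mass (steady-state input) and always sum to one including
the fallback label. `apoptosis_rate()` is simply 100 times the propensity
mass of the chosen death labels.

`screen_perturbations()` runs control plus perturbed arms under one
configuration. When the space is sampled, the identical initial-state set
is reused across arms so that sampling noise cancels from control-relative
values; a fate absent in the control yields `NA` ("undefined"), never
infinity. Failing arms are recorded with their error message and do not
abort the screen.

# Landscapes

The Waddington-style potential is $U = -\ln p$; states with $p = 0$
receive a cap (potential of the smallest positive probability plus one) so
exports stay finite. Two projections to the plane are offered:

* **Sammon mapping** minimizes
  $E = \frac{1}{\sum_{i<j}\delta_{ij}} \sum_{i<j} (\delta_{ij}-d_{ij})^2/\delta_{ij}$
  with $\delta$ the Hamming distance between state bit-vectors and $d$ the
  output Euclidean distance. The optimizer is `MASS::sammon()` (Sammon's
  original step factor 0.3, 500 iterations, relative-change tolerance
  $10^{-9}$) started from a seeded random-uniform configuration in
  $[0,1]^2$, so coordinates are reproducible per seed. Final stress is
  recomputed with the package's own stress function and verified in tests
  against a grid-search optimum on three-state configurations, and against
  the descent contract (final stress never exceeds the initialization's).
  Cost is quadratic in the number of states, so landscapes default to the
  top 500 most probable states.
* **Naive mapping** sorts states by descending probability (ties by state
  code) and lays them row-major on a $\lceil\sqrt{n}\rceil$-column grid,
  the most probable state at the origin. It preserves no distances — it
  exists so that large state spaces can still be drawn — and is a
  deterministic bijection onto grid cells, independent of input order.

# Bundled fixtures and what they can show

**`yeast11`** is a transcription of the published 11-node budding-yeast
cell-cycle network (Li et al. 2004, PNAS 101:4781; the same model
underlies later landscape analyses). Its results here — seven point
attractors, stationary-G1 basin $1764/2048 = 0.861$, the 13-state
trajectory — are exact reproductions of published values and serve as the
package's strongest external anchor.

**`mcf7_p53`** is a *synthetic* 16-node p53-pathway network. The published
MCF-7 network this case study follows exists only as journal supplementary
data, so the fixture was designed from the same circuitry instead: the
ATM–p53 axis with Wip1 and MDM2 negative feedbacks, the
p53–PTEN–AKT–MDM2 positive feedback, a BCL2-gated BAX/caspase switch with
a self-sustaining committed state, and a p21/14-3-3σ/Rb arrest arm. Its
design goals, stated in the file header, are qualitative: a single
proliferation attractor with basin 1.0 for the untreated network, inert
WIP1 knock-down alone, and a strict ordering of apoptotic basin share
E+N+W > N+W > E+N > N > E+W ≥ E across the treatment encodings (E: basal
ATM to 1; N: delete MDM2→P53; W: basal WIP1 to −1000). The exhaustively
computed rates (38.5, 24.4, 18.2, 17.4, 13.4 and 1.0 percent over
$2^{16}$ initial states) realize that ordering; their absolute values are
properties of this synthetic network, not estimates of experimental
apoptosis rates, and tests assert only the designed qualitative behavior.

**`crc201`** is a *synthetic* 201-node rules-mode signalling network with
13 input nodes (growth factors, cytokines and stresses, held at their
sampled values through identity rules), a curated
WNT/MAPK/PI3K/p53/TGF-β/JAK-STAT core including a SPRY-mediated negative
feedback that makes wild-type MAPK signalling oscillate, 8 output nodes,
and five-deep transcriptional relay chains to reach realistic size. Driver
mutations are node fixings (APC 0, KRAS 1, PTEN 0, TP53 0, cumulatively;
RAS 1 + PI3K 1 for an HCT-116-like line). Under sampled deterministic
analysis (10,000 states) normal-proliferation propensity is non-increasing
and combined abnormal-fate propensity non-decreasing across the cumulative
arms — the designed analogue of stepwise colorectal tumorigenesis. Again,
absolute propensities are fixture properties, not biological estimates.

Because two of the three fixtures are synthetic, green tests on them
demonstrate that the *pipeline* (parsing, dynamics, basin accounting, fate
aggregation, screening) behaves correctly and that networks designed with
textbook circuitry produce the expected pharmacology; they do not validate
any specific published cancer network. The yeast fixture, being a faithful
transcription, does provide such external validation for the weighted
dynamics and the deterministic pipeline.

# Numerical and implementation choices

* **State encoding**: node 1 is the least-significant bit; integer codes
  are exact up to 53 nodes, beyond which bit-string keys are used
  throughout (hashing, cycle canonicalization, export).
* **Capacity guards**: exhaustive enumeration refuses beyond 24 nodes and
  the dense transition matrix beyond 14, both with errors that point to
  the sampling/heuristic alternatives.
* **Degenerate inputs**: Sammon projection refuses duplicate states (zero
  distances) and all-identical inputs; `potential()` rejects probabilities
  outside $[0,1]$; contradictory sampling constraints error.
* **Problem sizes in the test-suite**: exhaustive analyses up to
  $2^{16}$ states, sampled analyses of the 201-node fixture at $10^4$
  states, master-equation runs at $2^{11}$; chosen to exercise every code
  path at full case-study scale while keeping a complete run in minutes.
* **Reproducibility**: every sampling function takes an integer seed and
  restores the caller's RNG state; the CLI writes a JSON manifest with the
  full configuration and seed per run.

# Known limitations

* Only synchronous updating is implemented; asynchronous and
  continuous-time semantics are out of scope, and attractors of
  asynchronous schemes can differ.
* The exhaustive probabilistic pipeline stores a dense $2^N \times 2^N$
  matrix; large networks must use the heuristic estimator, which cannot
  produce state-transition trajectories.
* The master-equation iteration reports, but does not overcome, slow
  mixing: for nearly reducible chains (very small $c$, large $\mu$) the
  iteration cap may be reached before the residual tolerance.
* Fate logic is propositional over node states; quantitative markers
  (expression levels, dose response) are not representable.
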