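---
title: "Growth-induced percolation: model, theory, and numerical methods"
author: "growthperc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-induced percolation: model, theory, and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthperc)
```

## The model

Growth-induced percolation describes activation spreading through *indirect*
influence. Nodes are binary (active/inactive); each node is seeded active
independently with probability $q$. An inactive node $i$ activates when its
**induced index**
$$m_i \;=\; \max_{j \in \partial^{\mathrm{in}}_i,\ s_j = 1}\ \bigl|\{\,l \in
\partial^{\mathrm{in}}_j : s_l = 1\,\}\bigr|$$
reaches the threshold $m$: at least one active in-neighbour $j$ must itself
have at least $m$ active in-neighbours. In undirected networks
"in-neighbours" are simply neighbours. Updates repeat until no node changes.

Two conventions deserve emphasis.

* **The empty maximum is undefined, not zero.** A node with no active
  in-neighbour cannot activate for any $m$ — the rule requires an active
  inducer. `induced_index()` returns `NA` in that case, and at $m = 0$ the
  cascade reduces to directed reachability from the seed set rather than
  global activation.
* **The focal node never counts toward its inducer's tally.** When an
  active $j$ is tested for inducing an inactive $i$, $i$ is inactive at
  evaluation, so $j$'s count is automatically over its *other* neighbours.
  This matches the $k-1$ (cavity) convention of the undirected theory.

Because activation is monotone — states only ever switch $0 \to 1$, and the
activation predicate is nondecreasing in the state — the final configuration
is the unique **least fixed point** above the seeding, independent of update
order. `run_growth()` exploits this with an event-driven work queue
(only nodes whose second neighbourhood changed are re-examined); the
contract is the fixed point, and the implementation is verified against a
naive full-sweep reference under randomly permuted schedules.

The reverse process, **retention**, starts with all nodes active; a
q-fraction is pinned (threshold 0) and every other active node is repeatedly
deactivated while it lacks an active neighbour with $\ge m$ active
neighbours. This is the greatest fixed point of the same support predicate
with the pinned set held active, and every growth steady state is stable
under it.

The order parameter is the giant component of the final active subgraph:
the largest connected component (GCC) when undirected; when directed, the
largest strongly connected component (GSCC) and the giant out-component
GOUT, taken bow-tie style as the GSCC plus all active nodes reachable from
it. This definition is consistent with the worked toy example in which a
5-node GSCC sits inside a 6-node GOUT.

## Mean-field theory

The solvers assume an infinite, locally tree-like network — a configuration
model with given $P(k)$ (undirected) or $P(k_{\mathrm{in}},
k_{\mathrm{out}})$ (directed, uncorrelated product form in this package).

**Directed, stage 1.** For a random link $i \to j$, let $x$ be the
probability that $i$ is active and $y$ the probability that $i$ can induce
$j$. With edge-end degree weights $w(k_{\mathrm{in}}) = \sum_{k_\mathrm{out}}
k_{\mathrm{out}} P(k_{\mathrm{in}}, k_{\mathrm{out}})/\langle k\rangle$,
$$x = q + (1-q)\sum_{k} w(k)\,[1 - (1-y)^{k}],$$
$$y = \sum_{k} w(k) \sum_{s \ge m} \binom{k}{s} x^s (1-x)^{k-s}
\Bigl[\,q + (1-q)\bigl(1 - (1 - y/x)^s\bigr)\Bigr],$$
and the active fraction is $P_a = q + (1-q)\sum_k P_{\mathrm{in}}(k)[1 -
(1-y)^k]$.

**Directed, stage 2.** With $(x, y)$ frozen, the GOUT messages $x_\infty$
(the link connects $j$ onward to the GOUT) and $y_\infty$ (it also induces)
satisfy fixed-point equations built from the kernel
$$H(y, x_\infty, y_\infty; k) = 1 - (1-y)^k - (1-x_\infty)^k +
(1 - y - x_\infty + y_\infty)^k,$$
which is the closed form of the explicit sum over the number $t \ge 1$ of
inducing links with conditional connection probabilities $y_\infty/y$ and
$(x_\infty - y_\infty)/(1-y)$. `h_closed()` is tested against that
enumeration for all $k \le 12$.

**Undirected.** The cavity pair $(\tilde x, \tilde y)$ plays the role of
$(x, y)$ with $k-1$ conditioning neighbours, and the giant-component triple
$(\alpha, \beta, \gamma)$ — connection, connection∧active,
connection∧inducing — replaces $(x_\infty, y_\infty)$, with the downstream
factor $D = 1 - (\alpha-\beta)/(1-\tilde x)$ accounting for neighbours the
node can itself induce. The per-degree terms were derived by summing the
binomial series of the explicit $t$-sums, giving, for $s$ supporting
neighbours,
$$1 - (1-\tilde y/\tilde x)^s - \Bigl[(1-\beta/\tilde x)^s -
\bigl(\tfrac{\tilde x - \tilde y - \beta + \gamma}{\tilde x}\bigr)^s\Bigr]
D^{k-1-s}.$$
The derivation was carried out independently and each closed form is
verified against its brute-force $t$-sum on randomized feasible arguments;
the assembled update is additionally verified against a triple-loop
reference, and the end-to-end $P_\infty$ against Monte-Carlo simulation.
(An alternative per-term variant containing an extra factor
$(\tilde y/\tilde x)^{k-s}$ is inconsistent with the series summation and
with simulation, and is not used.)

**Evaluation strategy.** Every inner binomial sum collapses to the closed
form $\sum_s \binom{n}{s} x^s (1-x)^{n-s} u^s v^{n-s} = (xu + (1-x)v)^n$
minus at most $m$ explicit leading terms, so one fixed-point sweep costs
$O(\#\text{degrees} \times m)$ regardless of the cutoff degree. The sweeps
themselves run in compiled code; a pure-R reference iteration (used for
trajectory traces and cross-checked against the compiled path) defines the
semantics.

## Branches, hysteresis, and the retention theory

The stage-1 map is monotone, so iterating from the **activation floor**
$(q, 0)$ converges to the least fixed point — the growth steady state
("lower branch") — while iterating from $(1, 1)$ converges to the greatest
fixed point ("upper branch"). Where the two differ the system is bistable;
the fold at which the upper branch collapses is the spinodal $k^*$ reported
by `classify_transition(find_spinodal = TRUE)`. (The point marked between
the onset and the jump in phase-diagram plots is interpreted here as this
fold; that interpretation is a package choice.)

For **directed** networks the upper branch also describes the retention
process: on a locally tree-like directed graph reciprocal links are
vanishingly rare, so an active node cannot contribute to its own support.
For **undirected** networks it does not. In the retention dynamics an
active $i$ counts toward its neighbour $j$'s induction tally, so pairs and
larger motifs of active nodes sustain each other — *mutual support* — and
the retention steady state strictly dominates the greatest fixed point of
the growth equations, whose $k-1$ convention excludes the focal node. The
discrepancy is large: at $\langle k\rangle = 2.6$, $m = 3$, $q = 0.19$ the
simulated retention process retains 87% of nodes while the upper branch
gives 20%. `hysteresis_loop()` therefore offers two reverse-branch methods:
`"upper"` (analytic; default for directed specs) and `"simulation"`
(runs `run_retention()` on sampled networks; default for undirected specs).
With the simulated reverse branch the hysteresis loop of the sparse
undirected ER setting ($m = 3$, $q = 0.19$) is strongly asymmetric: growth
is hybrid (onset then jump near $\langle k\rangle \approx 3.43$) while
retention declines continuously to zero near $\langle k\rangle \approx 1.05$.

Simulated reverse branches are classified at grid resolution. A steep
continuous onset can masquerade as a jump at coarse spacing, so the loop
refines the grid around any candidate jump (up to three halvings): genuine
discontinuities survive refinement, continuous rises do not. The default
simulated-jump threshold (0.1) is far above the sampling noise of the
default network size ($n = 2\times 10^4$, noise $\sim 5\times 10^{-3}$).

## Phase classification

`classify_transition()` scans the lower branch on a coarse grid
(cold-started solves, so every point is the deterministic least fixed
point), then

* locates the largest adjacent discontinuity by bisection on the mid-height
  threshold, refined to `bisection_tol` ($10^{-6}$); a candidate whose
  refined gap falls below `jump_delta` ($10^{-3}$) is a continuous rise,
  not a jump;
* locates the continuous onset $k_c^{I}$ by bisection on
  $P_\infty >$ `onset_eps` ($10^{-6}$);
* labels the transition **continuous** (onset, no jump), **hybrid** (onset
  strictly below a jump at $k_c^{II}$, with $P_\infty$ just below the jump
  at least `onset_eps`), or **first-order** ($P_\infty$ jumps from
  numerical zero).

For scale-free scans the exponent $\gamma$ decreases connectivity, so jumps
are sought in the direction of decreasing $\gamma$; reported critical
values are in the original parameter.

Near a fold the fixed-point iteration slows as $(1-\lambda)^{-1}$ with
$\lambda \to 1$; the tight stage-1 tolerance ($10^{-12}$, cap $10^6$
sweeps) keeps bisection brackets meaningful down to the $10^{-6}$
resolution. Stage 2 converges to the nontrivial root from the
feasibility-clipped upper corner $(1, \tilde x, \tilde y)$ (directed:
$(x, y)$); the all-zero root always exists and is reported as
$P_\infty = 0$ when the iteration collapses below $10^{-12}$. Conditional
ratios use the $0/0 \to 0$ convention whenever the conditioning event has
probability below $10^{-14}$. Poisson supports are truncated at tail mass
$10^{-12}$ and renormalized.

**The taxonomy threshold.** Just below a fold the lower branch generically
retains a minute precursor component — active hubs percolating among
themselves — of order $10^{-5}$ to $10^{-3}$ in scale-free networks. In the
strict $n \to \infty$ equations this makes every fold technically "hybrid".
Whether a transition *observably* jumps from zero, however, depends on
whether that precursor is extensive at a realistic system size:
`table2_taxonomy()` draws the hybrid/first-order boundary at
`onset_eps = 10 / n_ref` with reference size $n_{\mathrm{ref}} = 10^5$ — a
predicted giant component holding fewer than ten nodes at the reference
size is not a giant component. With this reading the four families separate
cleanly: ER networks (directed and undirected) show continuous and hybrid
transitions but never first-order (their precursors are $\gtrsim 10^{-3}$),
while scale-free networks with strong hubs additionally show first-order
jumps (precursors $\lesssim 3\times 10^{-5}$). The per-family settings are
fixed battery grids spanning weak to strong hubs
($\gamma \in \{1.3, 1.8, 2.0, 2.5, 3.0\}$, $m \in \{2, 4\}$ for SF;
$q \in \{0.05, 0.1, 0.3\}$, $m \in \{2, 3\}$ for ER).

**Jump scaling.** `jump_height_curve()` records, per $q$, the jump location
$k_c^{II}$ and $P_\infty$ on both sides. The quantity that follows a power
law in $q$ is the lower branch evaluated at the jump point (`P_below`):
for directed ER at $m = 2$ it grows roughly as $q^{2.1}$ with a log–log
$R^2$ of 0.998 over $q \in [0.05, 0.16]$, while $k_c^{II}$ falls
monotonically. Points above the critical seed fraction $q^*$ (where the
jump height vanishes; located by `find_critical_q()` via bisection on jump
existence, $q^* \approx 0.175$ at these settings) have no jump and are
excluded with a warning.

## The synthetic-network generators

The generators define the conditions under which all claims are tested:

* **ER**: independent edges with $p = \langle k\rangle/(n-1)$ per unordered
  (undirected) or ordered (directed) pair, matching the independent-Poisson
  in/out marginals assumed by the ER specialization of the theory.
* **Configuration model**: degrees i.i.d. from the target distribution;
  undirected parity and directed in/out stub-total balance are repaired by
  resampling uniformly chosen nodes' degrees, which preserves the target in
  expectation; uniform stub matching; then simple-graph projection
  (self-loops and parallel edges dropped). Projection biases the realized
  degree distribution downward by $O(\langle k^2\rangle^2 / n)$ — visible
  for scale-free networks with $k_{\max} = 100$ at moderate $n$ — which is
  why theory–simulation acceptance uses $n \ge 2\times 10^4$ and the
  sharpest quantitative comparisons are made on ER networks.

What the generators deliberately do *not* emulate: degree–degree
correlations, clustering and short loops, community structure, weighted or
temporal edges. Passing tests therefore validate the model and its
tree-like theory on uncorrelated random graphs; on real networks with
clustering, mutual support and short loops the theory is an approximation.

## Problem sizes and reproducibility

The test battery uses networks of $2\times 10^4$–$5\times 10^4$ nodes and
5–10 replicates for theory–simulation comparisons (e.g. the sparse
undirected setting $\langle k\rangle = 1.5$, $m = 2$ across five seed
fractions chosen in the supercritical regime, away from the onset near
$q \approx 0.26$ where finite-size smearing dominates at any fixed $n$);
classification grids use 31–41 coarse points with bisection refinement.
All sampling is seeded: identical seeds give identical edge sets, seeds,
and therefore identical cascades; ensemble replicate seeds are derived from
one master seed.

## Known limitations

* The directed theory treats $x_\infty$ exactly as it appears in its
  fixed-point system; its conditional reading (given the downstream node is
  active) is not separately renormalized. Simulation agreement is the
  arbiter, and it holds within sampling error across the tested grid.
* The undirected retention process has no closed-form solver here; the
  reverse hysteresis branch for undirected specs is simulated. An analytic
  treatment would need messages for mutual support, which the growth
  equations' cavity convention excludes by construction.
* Degree-correlated joint distributions, clustered or temporal graphs, and
  critical-exponent extraction are out of scope.
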