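# growthperc

Growth-induced percolation: cascades driven by *indirect* (second-neighbour)
influence on complex networks.

Classical spreading models activate a node when enough of its direct
neighbours are active. Empirically, however, many behaviours — collaboration
habits, affective states, adoption of practices — spread through indirect
contacts: what matters is not only that a neighbour is active, but that the
neighbour is itself strongly backed. Growth-induced percolation captures this
with one rule. Each node starts active with probability *q*. An inactive node
*i* activates when its **induced index**

&nbsp;&nbsp;&nbsp;&nbsp;m<sub>i</sub> = max over active in-neighbours *j* of
(number of active in-neighbours of *j*)

reaches a threshold *m*; equivalently, *i* activates when at least one active
in-neighbour *j* has at least *m* active in-neighbours. A node with no active
in-neighbour cannot activate for any *m*. The process repeats until no state
changes; because the dynamics are monotone, the result is the unique least
fixed point above the initial seeding, independent of update order. The
order parameter is the size of the giant component of the final active
subgraph: the GCC for undirected networks, the giant out-component GOUT
(the largest strongly connected component plus everything reachable from it)
for directed ones.

The package is for researchers in network science, computational social
science, and epidemiological modelling who want to simulate the model,
solve its mean-field theory, and map its phase diagram.

## What it provides

* **Generators** — Erdős–Rényi graphs (`sample_er()`), configuration-model
  graphs with Poisson or bounded power-law degrees
  (`sample_configuration()`, `poisson_degree_distribution()`,
  `powerlaw_degree_distribution()`, `joint_powerlaw_distribution()`),
  plain-text edge-list I/O (`read_edge_list()`, `write_edge_list()`).
* **Dynamics** — event-driven growth and retention cascades (`run_growth()`,
  `run_retention()`), induced index (`induced_index()`), giant components of
  the active subgraph (`components_active()`), replicated ensembles
  (`simulate_ensemble()`).
* **Theory** — two-stage self-consistent mean-field solvers for arbitrary
  degree distributions. For a random directed link *i*→*j*, stage 1 iterates
  the pair (x, y) — *i* is active; *i* can induce *j* — to a fixed point and
  yields the active fraction
  P<sub>a</sub> = q + (1−q) Σ P(k<sub>in</sub>,k<sub>out</sub>)
  [1 − (1−y)<sup>k<sub>in</sub></sup>]; stage 2 iterates the
  giant-component pair (x<sub>∞</sub>, y<sub>∞</sub>) through the kernel
  H(y, x<sub>∞</sub>, y<sub>∞</sub>; k) = 1 − (1−y)<sup>k</sup> −
  (1−x<sub>∞</sub>)<sup>k</sup> + (1−y−x<sub>∞</sub>+y<sub>∞</sub>)<sup>k</sup>
  and yields P<sub>∞</sub>. The undirected solver mirrors this with the
  cavity pair (x̃, ỹ) on k−1 neighbours and the connection triple
  (α, β, γ). Lower-branch initialization (q, 0) gives the growth (least)
  fixed point; upper-branch initialization (1, 1) gives the greatest one.
* **Phase analysis** — parameter scans with continuation
  (`scan_parameter()`), bisection location of the continuous onset kcI and
  the jump point kcII with continuous / hybrid / first-order classification
  (`classify_transition()`), the critical seed fraction q*
  (`find_critical_q()`), jump-height scaling in q (`jump_height_curve()`),
  growth-versus-retention hysteresis loops (`hysteresis_loop()`), and the
  transition-type taxonomy across the four network families
  (`table2_taxonomy()`).
* **CLI** — `run_cli()` plus the `inst/scripts/growthperc` wrapper, with
  `generate`, `simulate`, `solve`, `scan`, `classify` and `hysteresis`
  subcommands.

## Worked example

Undirected Erdős–Rényi network with mean degree 3, seeds q = 0.1,
threshold m = 2:

```r
library(growthperc)

dist <- poisson_degree_distribution(3)
solve_undirected(dist, q = 0.1, m = 2)
#> <undirected_solution> q=0.1 m=2 branch=lower: Pa=0.903841 P_inf=0.897062 (converged, 58 iter)

spec <- model_spec("er", FALSE, q = 0.1, m = 2, mean_degree = 3)
ens <- simulate_ensemble(spec, n = 50000, replicates = 5, seed = 1)
#> simulated Pa   = 0.9024 +/- 0.0009
#> simulated Pinf = 0.8955 +/- 0.0009

classify_transition(spec, "mean_degree", c(0.5, 4))
#> <transition_report> type=hybrid kcI=2.36251 kcII=2.65368 (jump 0.7589)
```

A 10% seeding cascades to 90% activation: the theory predicts
P<sub>a</sub> = 0.904 and a giant active component holding 89.7% of all
nodes, and 5 simulated networks of 50,000 nodes land within about a
tenth of a percent of both. The classifier shows why the regime matters:
at this q the transition in mean degree is *hybrid* — the giant component
appears continuously at ⟨k⟩ ≈ 2.36 (kcI) and then jumps by 0.76 at
⟨k⟩ ≈ 2.65 (kcII). At larger q the jump disappears (continuous
transition); the boundary is the critical point q*. On scale-free networks
with strong enough hubs the jump instead happens straight from zero — a
first-order transition.

The same analyses run from the shell:

```sh
inst/scripts/growthperc scan --family er --undirected --m 2 --q 0.1 \
    --parameter mean_degree --lo 0.5 --hi 6 --points 40 --out scan.csv
```

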