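---
title: "Trap placement as an absorbing Markov chain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trap placement as an absorbing Markov chain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapscape)
```

## The surveillance problem

Genetic control programmes for mosquito-borne disease — gene drives,
*Wolbachia* releases, insecticide-resistance management — need traps placed
so that a mosquito carrying an allele of interest is caught as early as
possible. trapscape treats this as a facility-location problem on a movement
model: given a landscape of discrete population sites and a daily movement
process between them, where should a fixed number of traps go so that the
expected number of days until a mosquito enters any trap is smallest?

## Movement model

The landscape is a metapopulation of $n$ point sites, each optionally
labelled with a resource type (blood-feeding, water/egg-laying, ...). All
sites carry equal population weight. Daily movement is Markovian: the
probability of being at site $j$ tomorrow depends only on the current site
$i$, through a row-stochastic matrix $\tau$ derived from a dispersal kernel
$w(d)$ of inter-site distance:

$$\tau_{ij} = \frac{M_{ij}\, w(d_{ij})}{\sum_k M_{ik}\, w(d_{ik})},$$

where $M$ is an optional resource-type masking term (below). Three kernel
families are built in:

* **exponential**, $w(d) = e^{-d/m}$, with $m$ the mean dispersal distance
  — suited to relatively far-ranging dispersers;
* **zero-inflated exponential**: the diagonal of $\tau$ is pinned exactly
  at a staying probability $z$ and the remaining mass $1-z$ is spread over
  other sites $\propto e^{-d/m}$ — capturing the tendency of local
  dispersers to dwell and make short flights. $m$ is the mean dispersal
  distance *conditional upon movement*;
* **long-tailed**, a Lomax (shifted power-law) form
  $w(d) = \left(1 + \frac{d}{m(b-1)}\right)^{-b}$ with shape $b > 1$. This
  family is often referred to loosely in the field without a fixed
  functional form; we chose the Lomax because it has mean $m$ (directly
  comparable with the exponential at the same parameter), a genuinely
  heavier tail, and converges to the exponential as $b \to \infty$. Users
  who prefer a different form can supply any function of distance as a
  custom kernel.

Distances are planar Euclidean by default; a haversine mode (spherical
radius 6,371,008.8 m) is available for longitude/latitude inputs. Distances
and kernel ranges must share units — metres in the geographic case.

**Diagonal handling.** For the exponential and long-tailed families the
diagonal weight is $w(0)$ and the whole row, diagonal included, is
normalized together; only the zero-inflated family has an explicit staying
parameter. This keeps the plain families one-parameter and reproduces the
stated staying-probability semantics exactly where a staying probability is
actually part of the model.

**Masking.** When sites carry resource types, a masking matrix $M$ indexed
by (current-site type, destination type) multiplies the kernel weights
before normalization — e.g. a recently blood-fed female down-weights
further blood sources and seeks oviposition sites, mimicking the
gonotrophic cycle. The mask is driven by the *current* node's type (the
mosquito's need), the destination type selecting the column. Rows are
renormalized after masking; a row masked to all-zero off-diagonals is an
error for the plain families, while under the zero-inflated family the mask
applies to the off-diagonal weights only, the diagonal stays exactly $z$,
and a site with no reachable destination keeps probability 1 (isolated
site). We renormalize masked rows rather than treating mask entries as
final probabilities because masks express relative preference, not absolute
rates; an all-ones mask is then exactly a no-op, which is the invariant
users can reason with.

## Traps as absorbing states

A trap $k$ at distance $d$ from a site attracts with a raw weight given by
its attractiveness kernel: exponential $A e^{-d/\rho}$ (mean radius of
attractiveness $\rho$) or sigmoidal $A / (1 + e^{s(d - \rho)})$ (inflection
radius $\rho$, steepness $s$). $A \in [0,1]$ is the maximum attractiveness,
interpreted as *odds* against the unit mass of the movement row: the full
chain over $n$ sites and $K$ traps is

$$P = \begin{pmatrix} \tau' & \nu' \\ 0 & I \end{pmatrix},
\qquad
[\tau'_i\ \nu'_i] = \frac{[\tau_i\ \nu_i]}{1 + \sum_k \nu_{ik}},$$

with $\nu_{ik}$ the raw attractiveness of trap $k$ from site $i$. A
co-located trap with $A = 0.5$ therefore captures with daily probability
$0.5/1.5 = 1/3$ — the ratio of trapped to untrapped mosquitoes per day is
$A : 1$. (The alternative reading, a capture *probability* of $A$ at
distance zero, is sometimes stated alongside the ratio semantics in the
literature; the two disagree for any $A > 0$ and we follow the ratio
consistently, which also gives the clean closed form below.) Multiple traps
share the denominator, so nearby traps cannibalize each other's captures —
precisely the trade-off the optimizer must negotiate. Note the sigmoidal
kernel evaluates to $A/(1+e^{-s\rho}) < A$ at $d = 0$: $A$ is a supremum
parameter, not the attained maximum, and we do not clamp it.

A trap kernel may also carry a per-source-resource-type multiplier vector
(default all ones) so that, e.g., an ovitrap preferentially attracts
females currently at food sites; the field describes this interaction
qualitatively, so we expose it as a plain multiplicative weight.

## Expected time to trapping

Trap states are absorbing, so with transient block $Q = \tau'$ the expected
days-to-trapping from each origin is the classic fundamental-matrix
expectation
$$t = (I - Q)^{-1}\mathbf{1},$$
computed as a linear solve of $(I - Q)t = \mathbf{1}$ rather than an
explicit inverse, for numerical stability when capture probabilities are
tiny. Two scalar objectives reduce the profile: the **mean** over origins
(average detection delay for a mosquito of uniform origin) and the
**max** (worst-case origin, the right objective when confinement is
paramount).

Degenerate configurations are handled by sentinel, not exception: an origin
from which absorption is not certain — it can reach a region that cannot
reach any trap — gets $t_i = +\infty$, and both objectives propagate the
sentinel. This matters for the optimizer: continuous-mode chromosomes can
wander into useless regions and must remain rankable rather than crash the
run. Reachability is decided exactly by graph traversal on the support of
$Q$; a reciprocal condition number of $(I-Q)$ below $10^{-12}$ is likewise
reported as the sentinel. A Monte-Carlo oracle (`simulate_walkers()`)
validates the solve empirically by stepping walkers through $P$ and
recording absorption days; tests require agreement within three standard
errors.

## Genetic-algorithm search

A chromosome is the ordered list of movable-trap placements — 0-based node
indices (discrete mode) or coordinate pairs (continuous mode; the search
box is the site bounding box padded 5% per side). Immovable traps live
outside the genome entirely, which is the simplest construction that
guarantees they are never perturbed. Each generation: tournament selection
(size 3, minimizing, ties to the lowest index, drawn without replacement),
two-point crossover on whole genes (coordinate pairs are never split;
children jointly conserve the parental gene multiset), per-gene mutation
(uniform node resampling, or Gaussian coordinate noise with standard
deviation a fraction of the bounding-box diagonal, clipped to the box), and
a size-1 elite re-injected over the current worst. Elitism makes the
best-fitness trace non-increasing, which the tests assert for every run.

Defaults — population 128, tournament 3, crossover probability 0.7,
mutation probability 0.3, per-gene rate 0.5, sigma fraction 0.05 — are
conventional evolutionary-toolbox settings; nothing in the method depends
delicately on them and all are exposed in `ga_control()`. Duplicate
discrete genes (two traps on one node) are allowed: nothing forbids
co-location and the shared-denominator renormalization handles it
naturally. Runs are exactly reproducible given the seed; repetition $r$
seeds the RNG with `seed + r - 1`, and independent repetitions retain all
traces. Discrete-mode fitness evaluations are memoized by genotype, which
is purely a speed optimization.

Two oracles check the GA: `brute_force_traps()` enumerates all placement
multisets for small discrete instances (refusing above a configurable cap),
and direct evaluation verifies qualitative optima such as one-trap-per-
cluster splits on symmetric two-cluster landscapes.

`sweep_trap_count()` optimizes over an increasing trap budget,
warm-starting each run with the previous optimum extended by a random extra
placement. Because adding a trap can never increase any origin's expected
time (every $\nu$ entry is non-negative), the warm start plus elitism makes
the swept fitness provably non-increasing in the budget — the
diminishing-returns curve that informs cost-effectiveness decisions.

## Synthetic landscapes and what they do (and do not) show

`make_landscape()` generates grids, uniform-random fields, clustered and
two-cluster layouts, and a fixed six-node hexagon with alternating resource
types used throughout the examples. `make_scenario()` bundles two study
designs at deliberately small sizes:

* **suburb_small** — 60 household-like sites uniform in a 1 km square,
  zero-inflated exponential movement with daily staying probability 0.72
  and conditional mean dispersal 54 m, and eight traps of two types: four
  exponential ($A = 0.5$, mean radius 15.88 m) and four sigmoidal
  ($A = 0.5$, inflection 16 m, shape 0.25). This emulates a suburban
  *Aedes*-style problem where households provide all resources.
* **island_small** — 30 village-like sites in five clusters on a 2 km ×
  4 km extent, exponential movement with $m$ = 300 m, a single exponential
  trap kernel ($A = 0.5$, radius 24 m), and two immovable traps pinned at
  the northernmost and southernmost sites. The real island-scale problem
  derives its movement matrix from a resistance-landscape simulation that
  is out of scope here; the plain exponential kernel is this package's own
  stand-in at the scaled-down extent.

The sizes (60 and 30 sites) were chosen once so that exhaustive
enumeration and 100,000-walker Monte-Carlo cross-checks complete in
seconds; the default test and acceptance problem sizes state the same
choices. What passing tests show is that the chain algebra, the solver, the
operators and the optimizer are correct *on landscapes with this
statistical structure*. They do not show that the dispersal parameters fit
any particular field population, that equal site weights are realistic, or
that household-scale OpenStreetMap geometry behaves like uniform-random
points; real deployments should re-derive kernels from mark-release-
recapture data and use real coordinates.

## Numerical choices and limitations

* Row sums of $\tau$ and $[Q\,|\,R]$ are exact to $10^{-12}$ by
  construction; tests enforce this across randomized instances.
* The linear solve is dense LAPACK; landscapes beyond a few thousand sites
  would need sparse methods, which we have not implemented.
* Time is discrete in days; sub-daily behaviour (e.g. diel activity) is out
  of scope, as are trap saturation, finite capacity, unequal site
  populations, and sex-specific joint optimization (run one landscape per
  sex instead).
* Haversine mode treats the Earth as a sphere; for the sub-kilometre
  extents typical here the error is negligible.
* The GA is a metaheuristic: on large instances it yields good, not
  certified-optimal, placements. The brute-force oracle certifies only
  small discrete instances; continuous-mode results are checked by
  convergence agreement with discrete mode on the same landscape
  (the two modes land within ~10% of each other's mean-objective optimum
  on the suburb scenario, echoing how node-restricted and free placements
  approach the same geometry from different sides).
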