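---
title: "Heatmap centrality: model, simulators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heatmap centrality: model, simulators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatnet)
```

## The problem and the measure

Given a simple, undirected, unweighted, connected network, which nodes are
the *super-spreaders* — the nodes whose infection (or activation) maximises
downstream spread? Hubs (high-degree nodes) are an obvious first guess but
can be locally trapped; betweenness finds global bottlenecks but is the most
expensive classical measure; closeness compresses the whole distance
distribution into a reciprocal that varies over a narrow range.

The heatmap centrality takes a third view. Let the farness of node $v$ be
$F(v) = \sum_j s(v, v_j)$, the sum of shortest-path hop distances to all
other nodes. Then

$$C_{HM}(v) \;=\; F(v) \;-\; \frac{1}{\deg(v)} \sum_{u \in \mathrm{adj}(v)} F(u).$$

A node whose farness is below the average of its neighbours' — $C_{HM} < 0$
— is a "hot spot" of its neighbourhood: shortest paths between pairs
elsewhere in the network tend to pass *through* it rather than through any
of its neighbours. The more negative the value, the more influential the
node. The measure uses global information (farness) but localises the
comparison (the neighbour average), which is what lets it separate a
genuine spreading centre from a node that merely sits next to one.

Two structural facts, both asserted as invariants in the test suite, are
useful for intuition and validation:

* **Leaf law.** A degree-1 node $v$ with neighbour $u$ has
  $F(v) = F(u) + N - 2$ (every path from $v$ goes through $u$, one hop
  longer, except the edge to $u$ itself), so $C_{HM}(v) = N - 2$ exactly.
  Leaves are always maximally *non*-influential, regardless of where they
  attach.
* **Degree-weighted zero sum.** $\sum_v \deg(v)\, C_{HM}(v) = 0$ on every
  graph: each product $\deg(v) C_{HM}(v)$ is $\deg(v) F(v)$ minus the sum of
  neighbour farness, and each edge contributes each endpoint's farness once
  to each sum. Heat deficits and surpluses balance exactly when weighted by
  degree.

## Reference centralities and their conventions

The four classical measures are implemented with the conventions that the
package's worked-example tables assume; each choice is forced by at least
one table cell on the bundled toy network.

* **Degree**: neighbour count.
* **Eigenvector**: dominant eigenvector of the adjacency matrix, rescaled so
  its maximum entry is exactly 1 (not unit Euclidean norm — the hub of the
  toy network must score exactly 1). Computed by power iteration from a
  uniform positive start vector, max-norm convergence tolerance `1e-12`,
  cap 10 000 iterations. The iteration actually runs on $A + I$: the shift
  leaves the dominant eigenvector unchanged but guarantees convergence on
  bipartite graphs, where $\pm\lambda_{max}$ are both eigenvalues of $A$ and
  plain power iteration oscillates. The reported $\lambda_{max}$ is the
  Rayleigh quotient of the converged vector under $A$, and the residual
  $\|Ae - \lambda e\|_\infty \le 10^{-8}$ is asserted in tests.
* **Closeness**: the plain reciprocal of farness, $1/F(v)$, with no
  $(N-1)$ normalisation (the toy network's top node must score
  $1/28 \approx 0.036$).
* **Betweenness**: Brandes' two-phase algorithm (per-source augmented BFS
  counting shortest paths, then reverse-order dependency accumulation).
  Each unordered pair is counted once and endpoints are excluded; summing
  both source directions and halving implements this. Disconnected inputs
  are allowed — unreachable pairs contribute nothing. The implementation is
  checked against explicit enumeration of all shortest paths on small random
  graphs and against an independent library implementation on larger ones.

`all_centralities()` computes all five measures with a single all-pairs BFS
sweep shared between closeness and heatmap, which is also how the heatmap
measure attains its $O(N(N+M))$ whole-graph cost.

## Ranking and rank correlations

Nodes are ranked in decreasing order of influence — decreasing score, or
*increasing* score for the heatmap measure. Two tie rules are provided:

* `"id"` (default): ties go to the smaller node label, and these tentative
  ranks are final. The worked correlation example that the package
  reproduces uses this rule throughout (its eight zero-betweenness nodes
  occupy eight distinct ranks), so it is the default despite the mid-rank
  rule being the textbook prescription.
* `"average"`: tied groups share the mean of their tentative ranks
  (mid-ranks), the standard statistical convention.

Spearman's $\rho$ is computed by the rank-difference formula
$\rho = 1 - 6\sum d_i^2 / (N(N^2-1))$ on final ranks. Kendall's coefficient
is the *decided-pairs* form $\tau = (N_C - N_D)/(N_C + N_D)$, where pairs
tied in either ranking are excluded from both counts; this is neither
$\tau_a$ (which divides by all pairs) nor $\tau_b$ (which corrects the
denominator for ties symmetrically), so standard $\tau_b$ is exposed
separately as `kendall_tau_b()` and is never the default. With `"id"` ties
all three coincide. No significance tests are attached to either
coefficient; the package compares rankings, it does not test hypotheses
about them.

## The modified SI spreading model

The spreading simulator scores seed sets, not nodes in isolation: the top-k
nodes of a measure collectively start infected, and the cumulative infection
count $F(t)$ (mean ± sd over replicates) measures the seed set's spreading
capability. The dynamics are a deliberately restrained variant of SI: at
each time step, **each infected node selects one susceptible neighbour
uniformly at random (if it has any) and infects it with probability
$\beta$** (default 1). A hub therefore cannot flood its whole neighbourhood
in one step, which is precisely the modelling point — real contact processes
rarely allow that.

Three contract details are fixed by the implementation and documented here
because the verbal description leaves them open:

* **Synchronous updates with one-step latency.** Only nodes infected at the
  start of a step transmit during it. This makes the step outcome
  independent of the order in which infectors are processed; allowing
  same-step chaining would not.
* **Collisions.** Two infectors may select the same susceptible target; the
  target simply becomes infected once. Forced by the binary S/I state.
* **Wasted attempts.** An infector whose neighbours are all infected does
  nothing that step; selection is among susceptible neighbours at the start
  of the step.

With $\beta = 1$ on a connected graph every run terminates in at most
$N - |\mathrm{seeds}|$ steps; the stabilisation time $t_c$ — the first step
at which no replicate has susceptible nodes left — is an *output* of the
simulation. Replicate $r$ runs on its own RNG stream seeded `rng_seed + r`,
so single replicates are reproducible in isolation and the whole curve is
bit-reproducible given the seed. The default of 100 replicates matches the
standard experiment design; the examples and tests in this package use
10–25 replicates, which is ample for the small graphs they run on.

## The Barabási–Albert generator

The evaluation test bed is the linear preferential-attachment model grown
from a *single* node ($m_0 = 1$): each arriving node connects to
$\min(m, \text{existing nodes})$ **distinct** existing nodes, drawn without
replacement with probability proportional to current degree (sequential
draws with renormalisation — which is exactly what R's weighted
`sample.int(..., replace = FALSE)` implements), falling back to uniform only
at the very first attachment, when every candidate still has degree 0. The
arriving node is never a candidate for its own edges, so the graph is simple
and connected by construction, and the edge count is deterministic:

$$M = m (N-1) - \frac{m(m-1)}{2} \quad (N - 1 \ge m),$$

because the first $m$ arrivals can only connect to fewer than $m$ existing
nodes. The mean degree $2M/N$ is therefore *seed-independent* — e.g.
$19.89$ at $(N, m) = (1000, 10)$ and $99.49$ at $(5000, 50)$ — and this
"distinct targets" semantics is the only attachment scheme consistent with
those zero-variance ensemble means; a multigraph-then-collapse scheme would
produce a random edge count. With $m = 1$ the generator yields a
preferential-attachment tree: clustering exactly 0.

Ensemble summaries report mean ± sd of the average degree, clustering
coefficient and diameter over replicates (replicate $i$ seeded
`rng_seed + i`). The clustering coefficient defaults to the **global**
(transitivity) definition, $3 \times \text{triangles} / \text{connected
triples}$; the mean-local variant (nodes of degree < 2 contributing 0) is
also available since ensemble tables elsewhere rarely say which was used —
on preferential-attachment ensembles the two are close, and the only cell
used for exact validation (the $m = 1$ tree) is 0 under both. A density
target $d$ maps to the attachment parameter via $m = \mathrm{round}(dN/2)$,
from $d \approx 2m/N$.

The degree-distribution diagnostic is the descriptive log–log regression
$\log P(k) \sim -\gamma \log k$ over degrees with non-zero empirical
frequency, with $\gamma$ the negated slope and the regression $R^2$ as
goodness of fit. This is deliberately *not* a maximum-likelihood tail fit
(Clauset-style): the package uses the regression only to check the
scale-free character ($\gamma > 1$) of its test beds, not to estimate tail
exponents rigorously. At least 3 support points are required; a regular
graph has no fit.

## Preprocessing raw networks

Real edge lists arrive directed, with repeats, loops and isolated nodes.
`preprocess_network()` applies, in order: treat edges as undirected →
remove loops and collapse duplicates → keep the largest connected component
(ties to the component containing the smallest label). Removal counts are
reported, and the pipeline is idempotent. Doing component selection *last*
is the safe order: simplification can only remove edges, so taking the
component first could leave a graph that is no longer connected after a
hypothetical later step; on typical data (where the removed nodes are
isolated) the orders coincide. Farness — and hence closeness and the
heatmap measure — is deliberately an *error* on disconnected input rather
than infinity: the measure is meaningless there, and the preprocessing
pipeline is the sanctioned route to a connected graph.

## Numerical and degenerate-input choices

* Node labels are preserved as given; canonical order (used for
  deterministic iteration and all tie-breaking) is numeric when every label
  parses as a number, lexicographic otherwise.
* Table reproduction rounds half away from zero (`round_half_away()`), the
  convention of printed tables, not banker's rounding.
* Single-node graphs: connected by definition; closeness, heatmap and
  density are domain errors.
* `rank_nodes()` requires at least two decided pairs for Kendall's
  coefficient; an all-tied comparison is an error, not `NaN`.
* Seeds derived from a base seed are reduced modulo $2^{31} - 1$ before use.

## What the synthetic test beds do and do not show

The generator produces connected, simple, power-law-ish networks with the
small diameters and low clustering of preferential attachment. Real
networks differ in ways the test suite cannot certify: degree correlations,
community structure, high clustering (e.g. co-occurrence networks),
heavy-tailed but non-power-law distributions. Passing tests demonstrate
correctness of the algorithms and reproducibility of the documented
ensemble statistics — they do not by themselves establish that the heatmap
ranking is superior on any particular real network; for that, the package
provides the experiment recipes (`rank_compare()`, `topk_table()`,
`spreading_capability()`) to run on user-supplied data after
`preprocess_network()`.

Problem sizes used in the bundled checks — the 15-node toy network,
ensembles of 10 replicates at $N = 1000$, single realisations at
$N = 5000$ — were chosen as the smallest sizes at which the documented
quantities (edge-count law, diameter stability, tree clustering) are
informative; all of them run in seconds on a laptop.

## Known limitations

* Undirected, unweighted graphs only; no directed or weighted shortest
  paths.
* Betweenness is exact, never sampled/approximate; at $N \gg 10^4$ the
  all-pairs sweeps become the bottleneck (the in-memory representation is
  not built for streaming-scale graphs).
* The SI simulator has no recovery compartment, heterogeneous $\beta$, or
  continuous-time variant.
* The power-law fit is descriptive (see above).
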