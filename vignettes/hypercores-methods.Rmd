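---
title: "Methods: hyper-core decomposition, null models and higher-order dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyper-core decomposition, null models and higher-order dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercores)
```

This vignette documents the models implemented by `hypercores`, the
assumptions and numerical choices behind them, and the study conditions
used by the test suite and the acceptance script.  It states no result
that those runs do not themselves compute.

## Hypergraphs

A hypergraph is a node set plus a set of hyperedges, each a set of at
least two distinct nodes.  Hyperedges carry **no multiplicity**: duplicate
input lines are merged and singleton candidates dropped (with logged
counts), because the decomposition is defined on distinct group
interactions and starts at size `m = 2`.  Node labels are opaque strings,
preserved verbatim; internally every computation runs on a dense integer
index with the label map kept in `H$nodes`.

Three ingest routes exist beyond the plain hyperedge list:

* **Bipartite projections** (`bipartite_to_hypergraph()`): each node of
  one side contributes the set of its neighbours on the other side as a
  candidate hyperedge — e.g. all insect species pollinating one plant.
* **Contact streams** (`contacts_to_hypergraph()`): timestamped pairwise
  contacts are aggregated over fixed, non-overlapping, half-open windows
  anchored at the first timestamp (default 900 s).  Within each window,
  maximal cliques of the contact graph (enumerated by igraph's pivoting
  Bron–Kerbosch implementation) are promoted to hyperedges.  Whether
  aggregation windows should overlap, and where they should be anchored,
  is genuinely open; fixed windows anchored at the first event are the
  simplest reproducible choice and are invariant to event order within a
  window, which the tests verify against an exhaustive subset-maximality
  clique search.
* **Directionality is discarded** everywhere (an email's sender and
  receivers form one undirected group).

## The (k,m)-hyper-core peeling

The (k,m)-hyper-core is the maximum subhypergraph, with hyperedges of
size at least `m`, in which every node belongs to at least `k` hyperedges
of size at least `m` within the subhypergraph.  The peeling
implementation discards hyperedges smaller than `m`, then repeatedly
removes nodes with fewer than `k` qualifying hyperedges; each removal
shrinks the hyperedges containing the node by one member, and a shrunk
hyperedge is deleted when it falls below size `m` **or collides with any
hyperedge currently present** — set semantics are enforced uniformly
among current (possibly already shrunk) hyperedges, including collisions
between two shrunk hyperedges.

Numerical/determinism choices:

* Within a peeling round, nodes are removed in ascending internal index.
  The result is removal-order invariant (the surviving set is the unique
  maximal valid subset, and the tests check invariance under node
  relabelling); the fixed order only stabilizes logs.
* `hc_decompose()` computes each size `m` once, iterating `k` upward and
  reusing the surviving subhypergraph at `k` as the start of the peeling
  at `k + 1`.  This is valid because the cores are nested and every node
  removed at threshold `k` would also be removed at `k + 1`; the suite
  additionally verifies every profile cell against independent
  `km_core()` calls, and `km_core()` itself against an exhaustive
  maximal-subset oracle on hundreds of small random hypergraphs.
* The induced hyperedge sets of a core are internal to the peeling and
  not exported: only node sets are reported, since shrunk hyperedges need
  not be hyperedges of the input and all downstream quantities depend on
  node sets alone.

## Hypercoreness

The g-hypercoreness is `R_g(i) = sum_m g(m) C_m(i) / k_max^m`, where
`C_m(i)` is the deepest `k` with `i` in the (k,m)-core and `k_max^m` the
deepest non-empty shell at size `m`.  Two conventions matter:

* When `k_max^m = 0` (no (1,m)-core at that size) the m-term is defined
  as 0 rather than 0/0, keeping `R_g` finite and consistent with
  `C_m(i) = 0` for excluded nodes.
* Nodes absent from every hyperedge of size `>= m` simply carry
  `C_m = 0` and still appear in all score tables, so output schemas are
  stable across sizes.

`g = 1` gives the size-independent hypercoreness `R` (at most `M - 1`);
`g = Psi(m)`, the fraction of hyperedges of size `m`, gives the
frequency-based hypercoreness `R_w` (at most 1).  For baselines the
package computes the s-coreness of the weighted pairwise projection
(edge weight = number of distinct hyperedges containing both endpoints)
by recursive removal through successive minimum-strength thresholds —
weights are positive integers, so integer thresholds lose nothing — and
the unweighted k-coreness via igraph.

## Degree-preserving null model

`hg_shuffle()` repeatedly selects two distinct hyperedges of the same
size and exchanges one uniformly chosen node between them.  A proposal is
rejected when the incoming node already belongs to the target hyperedge
(sets cannot hold repeated nodes) or when either resulting hyperedge
duplicates an existing one.  This preserves exactly: the node set, the
number of hyperedges of every size, and every node's full degree vector
`d(i)`.  Sizes with fewer than 4 hyperedges are not shuffled — with 3 or
fewer same-size sets, any accepted swap would be undone or create a
duplicate, so such sizes are structurally rigid.

* The loop counts **accepted** swaps, with a proposal cap of 100x the
  target so rigid instances terminate; the cap is logged when hit.
* `z_profile()` standardizes the empirical relative core size n_(k,m)
  against the shuffle ensemble.  The **sample** standard deviation
  (denominator n−1) is used — the ensemble is a finite sample, and with
  population normalization small ensembles would overstate significance.
  Cells with zero null deviation are flagged `defined = FALSE` and
  rendered non-significant; `null_max` is exported so that cells whose
  null distribution is degenerate can still be assessed nonparametrically
  (an empirical value exceeding all 100 realizations has empirical
  p < 0.01).  The default 10^5 swaps and 10^3 realizations suit
  empirical-scale data; the tests and acceptance script use hundreds of
  swaps and 100 realizations on hypergraphs of 30–100 nodes, where the
  swap chain mixes in a few hundred accepted swaps per size.

A practical caveat found while calibrating the suite: hyper-core
emergence in sparse random ensembles is discontinuous, so at a deeply
planted cell the null distribution is typically degenerate at zero (z
undefined) or strongly bimodal (z small despite an obvious signal).  The
signal test therefore uses the nonparametric comparison above, while the
parametric |z| >= 1.96 band is reserved for the calibration check that
a structureless hypergraph triggers it in at most a small fraction of
defined cells.

## Higher-order nonlinear contagion

In a hyperedge `e` with `i_e` infectious members, each susceptible member
is infected in one discrete step with probability `1 - exp(-lambda *
i_e^nu)`, independently across hyperedges, so a susceptible node `j` is
infected with probability `1 - prod_{e ∋ j} exp(-lambda * i_e^nu)`.
`nu = 1` recovers linear contagion (on pairwise hyperedges, exactly the
classical discrete-time SIS probability); `nu > 1` reinforces group
exposure.  Infectious nodes recover with probability `mu` per step, to S
(SIS) or R (SIR).

* **Updates are synchronous on start-of-step states**, and a node
  infected in a step cannot recover in that same step.  The discrete-time
  dynamics does not dictate an ordering; this choice makes the two-node
  closed forms exact — the pair SIR final size is
  `1 + q / (1 - (1-q)(1-mu))` with `q = 1 - exp(-lambda)` — and those
  closed forms (plus an exact conditional-occupancy Markov oracle for the
  pair SIS) are what the suite checks to three standard errors.
* **SIS steady state**: there is no principled online detector of "steady
  state reached", so a configurable burn-in (default 10^3 steps) precedes
  the observation window `T` (default 10^3).  `tau(j)` counts the steps,
  at window-step starts, that `j` spends infectious.  Runs whose
  infection dies out at any point before the window completes are flagged
  extinct and excluded from localization averages; the intended parameter
  regimes are those where extinction is rare.
* **Seeds**: the SIS seed is resampled uniformly per run; SIR measures
  spreading power per fixed seed, averaged over `n_runs` (default 300)
  independent runs.
* One master seed drives sequential per-run streams, so every result is
  bit-reproducible.

The study conditions for the localization check: a planted (3,4)-core of
10 nodes with 20 pairwise-attached periphery nodes, `lambda = 0.05`,
`nu = 1.5`, `mu = 0.1`, burn-in and window of 150 steps each, 8 runs per
replicate.  The size-4 core edges sustain the infection
(`lambda * 3^1.5 ≈ 0.26` per step against `mu = 0.1`) while pairwise
periphery transmission (`lambda = 0.05`) is subcritical, which is the
regime the per-core averages are designed to resolve.

## Naming game with committed minorities

Each node holds a dictionary, a non-empty subset of {A, B}.  Per step a
hyperedge is chosen uniformly (no size weighting — the deduplicated
hyperedge set is the sample space), a speaker uniformly within it, and
the speaker utters a uniformly chosen name from its dictionary.
Agreement is *possible* under the union rule if at least one listener
holds the name, under the unanimity rule if all group members including
the speaker hold it — the asymmetry between the two rules is deliberate
and preserved.  A possible agreement is *effective* with probability
`beta`: all non-committed group members (speaker included) collapse to
the uttered name; otherwise all non-committed listeners add the name.
Committed nodes hold {A} forever; they can speak (always uttering A) but
never update.  On a failed agreement the speaker's dictionary is left
unchanged — it already contains the uttered name, so there is nothing to
add.

`n_A` counts nodes whose dictionary is exactly {A}, committed included.
A run stops at absorption (`n_A = 1`) or `t_max` (default 5x10^5); when
not absorbed, the stationary `n_A*` averages 100 samples evenly spaced
over the last `window` steps (default 5x10^4).  Scans report the median
`n_A*` over `n_runs` (default 200) realizations per cell, re-drawing the
committed set each run; `critical_mass()` walks an ascending grid of
committed fractions and returns the first whose median reaches 1.

Exact consequences used as tests: with `p = 1` the system starts
absorbed; with `p = 0` the name A can never be created; with `beta = 0`
no agreement is ever effective, so `n_A* = N_p / N` exactly; and the
two-node chain with one committed node at `beta = 1` absorbs in mean
time 10/3, from the fundamental matrix of its 3-state chain.

The seeding comparison runs on a planted (3,4)-core of 10 nodes with 50
periphery nodes (N = 60), union rule, `beta = 0.4` — a value inside the
takeover band of this fixture, where seeding placement matters —
committed fractions on the grid {1, 2, 4, 8, 12, 18}/60, 11 runs per
cell, `t_max = 6000`, window 1500.  At these scales a full critical-mass
pair estimate takes a few seconds, letting the suite repeat it 20 times.

## Ranking comparisons

Top-fraction selections take the `ceiling(f * N)` highest-scoring nodes;
coreness-type scores are heavily tied, and the tie policy is uniform
random resolution within the boundary class under a caller-supplied
seed, so repeated comparisons average over the tied class rather than
freezing an arbitrary order.  Jaccard overlaps, top-fraction averages
and Pearson/Kendall correlations (tie-adjusted tau_b, via `stats::cor`)
are computed over the common node universe; constant vectors yield `NA`
coefficients rather than errors.  Significance testing of the
correlations is out of scope — they are descriptive summaries here.

## Synthetic generators: what they emulate, and what not

`random_hypergraph()` draws distinct uniformly random m-subsets per size,
matching a prescribed size histogram — the maximum-entropy reference for
a given `Psi(m)`.  `planted_core_hypergraph()` embeds a known
(k_core, m_core)-core by covering `n_core` nodes with distinct size-m
hyperedges until every planted node reaches the target within-core
degree, then attaches a sparse pairwise periphery (optionally with decoy
size-m hyperedges among the periphery, without which a same-size shuffle
has nothing to mix the core with).  These fixtures reproduce the
*structural* contrast the methods are designed to detect — a deep,
size-m-reinforced core against a shallow periphery — but not the
heavy-tailed degree and size distributions, degree–size correlations or
community structure of empirical data.  Passing the directional tests on
them shows the machinery resolves planted structure under controlled
conditions, not that any particular empirical system behaves likewise.

The built-in `toy_hypergraph()` (13 nodes) is a hand-built example whose
full decomposition was verified against the exhaustive subset oracle and
frozen into the suite; it exhibits non-trivial nesting, a pairwise-only
triangle entering the (2,2)- but no size-3 core, a (1,3)-core splitting
into two disjoint subhypergraphs, and a node excluded from the
(2,3)-core despite `D_3 = 2`.

## Known limitations

* Hyperedge-level (rather than node-level) coreness, streaming or
  approximate core maintenance, and directed/temporal hypergraph
  semantics are out of scope.
* The peeling is the straightforward `O(M (N + |E| log |E|))`-style
  procedure, implemented in plain R; it is comfortable for the
  hundreds-of-nodes scale of the generators and tests, not tuned for
  millions of hyperedges.
* The null model is the swap chain described above, not an exact uniform
  sampler of the degree-constrained ensemble.
* Naming-game dictionaries are capped at two conventions, as in the
  minimal model.
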