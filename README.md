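# hypercores

Hyper-core decomposition, hypercoreness centralities and higher-order
dynamics on hypergraphs.

Many social, ecological and communication systems are built from *group*
interactions — emails with several recipients, committees, insect species
pollinating the same plant — and are naturally represented as hypergraphs:
nodes plus hyperedges, where a hyperedge is a set of two or more nodes.
Standard coreness tools see only pairwise edges and miss the sizes of the
groups.  This package decomposes a hypergraph into its
**(k,m)-hyper-cores**, compares the resulting profile against a
degree-preserving null model, and measures how the core structure shapes two
families of higher-order dynamics: nonlinear contagion and
convention-formation with committed minorities.

## The decomposition

The (k,m)-hyper-core is the maximum subhypergraph, with hyperedges of size
at least *m*, in which every node belongs to at least *k* hyperedges of
size at least *m* *within the subhypergraph*.  It is computed by discarding
hyperedges smaller than *m* and recursively removing nodes with fewer than
*k* remaining hyperedges; each removal shrinks the hyperedges containing
the node, and a shrunk hyperedge is deleted when it drops below size *m* or
collides with an existing one.  The cores are nested in both *k* and *m*.

The *m*-shell index C_m(i) of node *i* is the deepest *k* such that *i*
belongs to the (k,m)-core, and k_max^m is the deepest non-empty shell at
size *m*.  The **hypercoreness** family of centralities summarizes a node's
position across all sizes:

    R_g(i) = sum_{m=2}^{M} g(m) * C_m(i) / k_max^m

with g an arbitrary non-negative weight.  `g = 1` gives the
size-independent hypercoreness *R* (bounded by M−1); `g = Psi`, the
hyperedge-size frequency, gives the frequency-based hypercoreness *R_w*
(bounded by 1).  For comparison, the package also projects the hypergraph
onto its weighted pairwise graph and computes the classical *s*-coreness
(strength-based, Eidsaa–Almaas recursive removal) and *k*-coreness.

Around the decomposition the package provides:

* **Null model** — `hg_shuffle()` randomizes a hypergraph by same-size
  hyperedge swaps, preserving the hyperedge-size counts and every node's
  full degree vector; `z_profile()` standardizes the empirical core sizes
  n_(k,m) against an ensemble of shuffles.
* **Contagion** — `run_sis()` / `run_sir()` simulate discrete-time
  contagion where a susceptible node in hyperedge *e* with i_e infectious
  members is infected with probability 1 − exp(−λ·i_e^ν); localization is
  measured as the fraction of time τ/T each node spends infectious in the
  SIS steady state, spreading power as the mean SIR final size R_∞ per
  seed, both averageable over every (k,m)-core (`aggregate_by_core()`).
* **Naming game** — `run_ng()`, `phase_scan()` and `critical_mass()`
  simulate convention formation in groups (union / unanimity agreement
  rules, agreement probability β) with a committed minority seeded at
  random or on the top-scoring nodes of any centrality.
* **Evaluation** — top-fraction Jaccard overlaps, top-fraction averages and
  Pearson/Kendall correlations for comparing centrality rankings against
  dynamical importance.
* **I/O and generators** — hyperedge-list and JSON readers/writers,
  bipartite projections, 15-minute-window maximal-clique aggregation of
  timestamped contact streams, and random / planted-core synthetic
  hypergraph generators.

## Worked example

```r
library(hypercores)

H <- toy_hypergraph()        # 13 nodes, 7 pairs + 6 triangles
p <- hc_decompose(H)
p
#> Hyper-core profile: N = 13 , sizes m = 2.. 3
#>   k_max^m: m=2:3 m=3:3
head(p$n_km, 4)
#>   m k core_size      n_km
#> 1 2 1        13 1.0000000
#> 2 2 2         8 0.6153846
#> 3 2 3         4 0.3076923
#> 4 3 1         8 0.6153846

ct <- centrality_table(H, p)
ct[order(-ct$R), ][1:6, ]
#>   node         R       R_w s_coreness k_coreness
#> 1   a1 2.0000000 1.0000000          6          3
#> 2   a2 2.0000000 1.0000000          6          3
#> 3   a3 2.0000000 1.0000000          6          3
#> 4   a4 2.0000000 1.0000000          6          3
#> 5    x 1.0000000 0.5128205          2          2
#> 6   y1 0.6666667 0.3333333          2          2
```

The four `a` nodes form a clique of triangles and sit in the deepest shell
at both sizes (C_2 = C_3 = 3), so they reach the maximum hypercoreness
R = 2 and R_w = 1.  Node `x` belongs to two triangles (D_3 = 2) yet has
C_3 = 1: its triangles share the partner `y1`, and the recursive peeling
with hyperedge downgrading excludes it from the (2,3)-core — exactly the
information that pairwise coreness cannot see.

Contagion localizes on a planted deep core:

```r
fx <- planted_core_hypergraph(10, 3, 4, 20, seed = 1)
s <- run_sis(fx$H, lambda = 0.05, nu = 1.5, mu = 0.1,
             T = 200, burn_in = 200, n_runs = 20, seed = 2)
mean(s$tau_frac[fx$core])       # 0.836
mean(s$tau_frac[fx$periphery])  # 0.279
```

Nodes of the planted (3,4)-core are infectious for 84% of the observation
window against 28% in the pairwise periphery.

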