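#' @name fixtures
#' @title Synthetic hypergraph generators
#'
#' @description
#' Random and structured hypergraphs for testing and benchmarking every
#' part of the toolkit without external data: uniform random hypergraphs
#' with a prescribed hyperedge-size histogram, planted-core hypergraphs
#' with a known deeply connected node set, and a small hand-built toy with
#' a fully worked-out decomposition.
NULL

# internal: n distinct uniformly random m-subsets of 1..N, as a list of
# sorted integer vectors; keys can pre-contain forbidden subsets
sample_distinct_subsets <- function(N, m, n, keys = NULL) {
  if (n > choose(N, m))
    stop("requested ", n, " distinct subsets of size ", m,
         " but only choose(", N, ",", m, ") exist")
  keys <- keys %||% new.env(parent = emptyenv())
  out <- vector("list", n)
  got <- 0L
  while (got < n) {
    e <- sort.int(sample.int(N, m))
    key <- edge_key(e)
    if (exists(key, envir = keys, inherits = FALSE)) next
    assign(key, TRUE, envir = keys)
    got <- got + 1L
    out[[got]] <- e
  }
  out
}

node_labels <- function(N, prefix = "v") {
  sprintf("%s%0*d", prefix, nchar(N), seq_len(N))
}

#' Uniform random hypergraph with a fixed size histogram
#'
#' For each hyperedge size m, draws the requested number of distinct
#' uniformly random m-subsets of the node set (dedup by rejection).
#'
#' @param N number of nodes.
#' @param size_counts named integer vector: `size_counts[["3"]]` hyperedges
#'   of size 3, etc.  Each count must not exceed `choose(N, m)`.
#' @param seed optional integer seed.
#' @return a [hypergraph()] on `N` nodes (isolated nodes kept).
#' @export
#' @examples
#' H <- random_hypergraph(10, c("2" = 8, "3" = 4), seed = 1)
#' table(lengths(H$edges))
random_hypergraph <- function(N, size_counts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ms <- as.integer(names(size_counts))
  if (anyNA(ms) || any(ms < 2)) stop("size_counts must be named by sizes >= 2")
  labels <- node_labels(N)
  edges <- list()
  for (q in seq_along(ms)) {
    if (size_counts[[q]] == 0) next
    edges <- c(edges, sample_distinct_subsets(N, ms[q], size_counts[[q]]))
  }
  hypergraph_from_idx(edges[order(vapply(edges, edge_key, ""))], labels)
}

#' Planted-core hypergraph
#'
#' Builds a hypergraph containing a known densely connected core: `n_core`
#' planted nodes covered by distinct hyperedges of size `m_core` such that
#' every planted node belongs to at least `k_core` of them (so the planted
#' set is contained in the (k_core, m_core)-hyper-core), plus a sparse
#' periphery of `n_periphery` nodes, each attached to a uniformly random
#' core node by one pairwise edge.
#'
#' @param n_core planted core size (>= m_core).
#' @param k_core minimum within-core hyperdegree of planted nodes.
#' @param m_core size of the planted hyperedges (>= 2).
#' @param n_periphery number of periphery nodes.
#' @param extra_core_edges additional random size-`m_core` hyperedges placed
#'   inside the core beyond those needed to reach `k_core`.
#' @param periphery_pairs additional random pairwise edges among periphery
#'   nodes (default 0).
#' @param periphery_m_edges decoy hyperedges of size `m_core` drawn among
#'   the periphery nodes (default 0); with decoys present, a size-preserving
#'   shuffle can disperse the planted structure, which is what the z-score
#'   profile is meant to detect.
#' @param seed optional integer seed.
#' @return list with `H` (the [hypergraph()]), `core` and `periphery`
#'   (label vectors).
#' @export
planted_core_hypergraph <- function(n_core, k_core, m_core, n_periphery,
                                    extra_core_edges = 0, periphery_pairs = 0,
                                    periphery_m_edges = 0, seed = NULL) {
  stopifnot(m_core >= 2, m_core <= n_core, k_core >= 1, n_periphery >= 0)
  if (choose(n_core - 1, m_core - 1) < k_core)
    stop("infeasible planted core: choose(n_core-1, m_core-1) < k_core")
  if (!is.null(seed)) set.seed(seed)
  N <- n_core + n_periphery
  labels <- c(node_labels(n_core, "c"), node_labels(max(1, n_periphery), "p")[
    seq_len(n_periphery)])
  keys <- new.env(parent = emptyenv())
  edges <- list()
  deg <- integer(n_core)
  guard <- 0L
  while (min(deg) < k_core) {
    v <- which.min(deg)
    others <- (1:n_core)[-v]
    e <- sort.int(c(v, others[sample.int(length(others), m_core - 1)]))
    key <- edge_key(e)
    guard <- guard + 1L
    if (guard > 1000 * k_core * n_core) stop("planted core sampling stalled")
    if (exists(key, envir = keys, inherits = FALSE)) next
    assign(key, TRUE, envir = keys)
    edges[[length(edges) + 1L]] <- e
    deg[e] <- deg[e] + 1L
  }
  if (extra_core_edges > 0)
    edges <- c(edges,
               sample_distinct_subsets(n_core, m_core, extra_core_edges, keys))
  for (q in seq_len(n_periphery))
    edges[[length(edges) + 1L]] <- sort.int(c(sample.int(n_core, 1L),
                                              n_core + q))
  if (periphery_m_edges > 0) {
    if (n_periphery < m_core)
      stop("periphery too small for decoy hyperedges of size ", m_core)
    decoys <- sample_distinct_subsets(n_periphery, m_core, periphery_m_edges)
    edges <- c(edges, lapply(decoys, function(e) n_core + e))
  }
  if (periphery_pairs > 0 && n_periphery >= 2) {
    pk <- new.env(parent = emptyenv())
    for (e in edges) if (length(e) == 2) assign(edge_key(e), TRUE, envir = pk)
    got <- 0L
    while (got < periphery_pairs) {
      e <- sort.int(n_core + sample.int(n_periphery, 2L))
      key <- edge_key(e)
      if (exists(key, envir = pk, inherits = FALSE)) next
      assign(key, TRUE, envir = pk)
      edges[[length(edges) + 1L]] <- e
      got <- got + 1L
    }
  }
  list(H = hypergraph_from_idx(edges, labels),
       core = labels[seq_len(n_core)],
       periphery = if (n_periphery) labels[(n_core + 1):N] else character(0))
}

#' Hand-built toy hypergraph with a worked decomposition
#'
#' A 13-node hypergraph exhibiting the characteristic features of the
#' hyper-core decomposition on a small example: non-trivial nesting
#' ((1,2)-core contains the (2,2)-core which contains the (2,3)-core), a
#' (1,3)-core made of two disjoint subhypergraphs once pairwise edges are
#' discarded, a pairwise-only triangle that enters the (2,2)-core but no
#' size-3 core, and a node `x` with D_3(x) = 2 that is nevertheless
#' excluded from the (2,3)-core by the recursive removal and hyperedge
#' downgrading mechanism.
#'
#' @return a [hypergraph()].
#' @export
toy_hypergraph <- function() {
  hypergraph(list(
    # dense 4-clique of triples: the deep core (k_max^3 = 3)
    c("a1", "a2", "a3"), c("a1", "a2", "a4"),
    c("a1", "a3", "a4"), c("a2", "a3", "a4"),
    # gadget: x sits in two triples sharing y1, so D_3(x) = 2 but the
    # (2,3)-peeling removes y2/y3 first and the shrunk pairs are discarded
    c("x", "y1", "y2"), c("x", "y1", "y3"),
    # pairwise-only triangle: in the (2,2)-core, absent from all m >= 3 cores
    c("z1", "z2"), c("z2", "z3"), c("z1", "z3"),
    # periphery leaves and connectors
    c("w1", "a1"), c("w2", "x"), c("a4", "x"), c("z3", "x")),
    quiet = TRUE)
}
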