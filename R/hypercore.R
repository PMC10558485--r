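#' @name hypercore
#' @title (k,m)-hyper-core decomposition
#'
#' @description
#' The (k,m)-hyper-core of a hypergraph is the maximum subhypergraph, with
#' hyperedges of size at least m, in which every node belongs to at least k
#' distinct hyperedges of size at least m *within the subhypergraph*.  It is
#' obtained by first discarding hyperedges of size smaller than m and then
#' recursively removing every node with fewer than k remaining hyperedges of
#' size at least m.  Removing a node shrinks each hyperedge containing it by
#' one member; a shrunk hyperedge is deleted when its size drops below m or
#' when it coincides with a hyperedge already present (hyperedges are sets).
#'
#' The cores are nested: the (k,m)-core contains both the (k+1,m)- and the
#' (k,m+1)-core.  The m-shell index C_m(i) is the largest k such that node i
#' belongs to the (k,m)-core (0 if it is not even in the (1,m)-core), and
#' k_max^m is the largest k with a non-empty (k,m)-core.
NULL

# ---- peeling engine ---------------------------------------------------------
# Mutable peeling state held in an environment: current hyperedges (sorted
# integer vectors), an alive flag per edge, a key->edge-id hash for set
# semantics, per-node incident edge ids and current D_m counts.

peel_init <- function(H, m) {
  edges <- H$edges[lengths(H$edges) >= m]
  st <- new.env(parent = emptyenv())
  st$m <- as.integer(m)
  st$edges <- edges
  st$alive_e <- rep(TRUE, length(edges))
  st$keys <- new.env(parent = emptyenv())
  st$inc <- vector("list", H$N)
  st$deg <- integer(H$N)
  st$alive_v <- rep(TRUE, H$N)
  for (eid in seq_along(edges)) {
    assign(edge_key(edges[[eid]]), eid, envir = st$keys)
    for (v in edges[[eid]]) {
      st$inc[[v]] <- c(st$inc[[v]], eid)
      st$deg[v] <- st$deg[v] + 1L
    }
  }
  st
}

peel_remove_node <- function(st, v) {
  st$alive_v[v] <- FALSE
  for (eid in st$inc[[v]]) {
    if (!st$alive_e[eid]) next
    e <- st$edges[[eid]]
    st$alive_e[eid] <- FALSE
    rm(list = edge_key(e), envir = st$keys)
    keep <- e[e != v]
    st$deg[keep] <- st$deg[keep] - 1L
    if (length(keep) >= st$m) {
      key <- edge_key(keep)
      if (!exists(key, envir = st$keys, inherits = FALSE)) {
        nid <- length(st$edges) + 1L
        st$edges[[nid]] <- keep
        st$alive_e[nid] <- TRUE
        assign(key, nid, envir = st$keys)
        for (u in keep) st$inc[[u]] <- c(st$inc[[u]], nid)
        st$deg[keep] <- st$deg[keep] + 1L
      }
    }
  }
  st$inc[[v]] <- integer(0)
  st$deg[v] <- 0L
  invisible(st)
}

# peel to threshold k; removal order within a round is ascending node index
# (pure determinism of logs -- the resulting core is order-invariant)
peel_to <- function(st, k) {
  repeat {
    bad <- which(st$alive_v & st$deg < k)
    if (!length(bad)) break
    for (v in bad) {
      if (st$alive_v[v] && st$deg[v] < k) peel_remove_node(st, v)
    }
  }
  invisible(st)
}

# ---- public operations ------------------------------------------------------

#' Node set of the (k,m)-hyper-core
#'
#' @param H a [hypergraph()].
#' @param k minimum number of hyperedges per node (>= 1).
#' @param m minimum hyperedge size (>= 2).
#' @return character vector of node labels in the (k,m)-hyper-core (empty if
#'   no node survives).
#' @seealso [hc_decompose()] for the full profile.
#' @export
#' @examples
#' H <- hypergraph(list(c("a", "b", "c")))
#' km_core(H, 1, 3)  # all three nodes
#' km_core(H, 2, 2)  # empty
km_core <- function(H, k, m) {
  if (length(k) != 1 || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  if (length(m) != 1 || m < 2 || m != round(m)) stop("m must be an integer >= 2")
  st <- peel_init(H, m)
  peel_to(st, k)
  H$nodes[st$alive_v]
}

#' Full (k,m)-hyper-core decomposition
#'
#' Computes, for every hyperedge size m in 2..M and every connectivity k up
#' to k_max^m, the (k,m)-hyper-core node set, the relative core sizes
#' n_(k,m) = |core|/N, the m-shell indices C_m(i) and the maxima k_max^m.
#' For each m the peeling proceeds by increasing k, reusing the surviving
#' subhypergraph at k as the start of the peeling at k+1 (valid because the
#' cores are nested and the peeling is removal-order invariant).
#'
#' @param H a non-empty [hypergraph()].
#' @return an object of class `hypercore_profile`: a list with
#'   \describe{
#'     \item{nodes, N, M}{copied from `H`;}
#'     \item{psi}{hyperedge-size distribution Psi(m), m = 2..M;}
#'     \item{k_max}{named integer vector, k_max^m for m = 2..M;}
#'     \item{shell}{N x (M-1) integer matrix of shell indices C_m(i);}
#'     \item{cores}{`cores[[as.character(m)]][[k]]` = integer node indices of
#'       the (k,m)-core;}
#'     \item{n_km}{data.frame `(m, k, core_size, n_km)` over all non-empty
#'       cells.}
#'   }
#' @export
hc_decompose <- function(H) {
  if (!length(H$edges)) stop("cannot decompose a hypergraph with no hyperedges")
  ms <- 2:H$M
  shell <- matrix(0L, H$N, length(ms), dimnames = list(H$nodes, ms))
  k_max <- stats::setNames(integer(length(ms)), ms)
  cores <- stats::setNames(vector("list", length(ms)), ms)
  rows <- list()
  for (mi in seq_along(ms)) {
    m <- ms[mi]
    st <- peel_init(H, m)
    klist <- list()
    k <- 1L
    repeat {
      peel_to(st, k)
      surv <- which(st$alive_v)
      if (!length(surv)) break
      klist[[k]] <- surv
      shell[surv, mi] <- k
      rows[[length(rows) + 1L]] <-
        data.frame(m = m, k = k, core_size = length(surv),
                   n_km = length(surv) / H$N)
      k <- k + 1L
    }
    k_max[mi] <- k - 1L
    cores[[mi]] <- klist
  }
  structure(
    list(nodes = H$nodes, N = H$N, M = H$M,
         psi = size_distribution(H), k_max = k_max, shell = shell,
         cores = cores, n_km = do.call(rbind, rows)),
    class = "hypercore_profile")
}

#' @export
print.hypercore_profile <- function(x, ...) {
  cat("Hyper-core profile: N =", x$N, ", sizes m = 2..", x$M, "\n")
  cat("  k_max^m:", paste0("m=", names(x$k_max), ":", x$k_max, collapse = " "), "\n")
  invisible(x)
}

#' Extract a core node set from a profile
#'
#' @param profile a [hc_decompose()] result.
#' @param k,m core indices.
#' @return character vector of node labels (empty when the core is empty).
#' @export
profile_core <- function(profile, k, m) {
  stopifnot(k >= 1, m >= 2)
  if (m > profile$M) return(character(0))
  kl <- profile$cores[[as.character(m)]]
  if (k > length(kl)) return(character(0))
  profile$nodes[kl[[k]]]
}

#' Hypercoreness centralities
#'
#' The g-hypercoreness of node i is
#' \deqn{R_g(i) = \sum_{m=2}^{M} g(m)\, C_m(i) / k_{max}^m,}
#' the sum of its shell indices normalised by the deepest shell at each size,
#' weighted by an arbitrary non-negative function g of the hyperedge size.
#' `g = "uniform"` (g == 1) gives the size-independent hypercoreness R;
#' `g = "frequency"` (g = Psi, the hyperedge-size distribution) gives the
#' frequency-based hypercoreness R_w.  Sizes m with an empty (1,m)-core
#' (k_max^m = 0) contribute 0.
#'
#' @param profile a [hc_decompose()] result.
#' @param g `"uniform"`, `"frequency"`, a numeric vector of weights for
#'   m = 2..M, or a function of m.
#' @return named numeric vector of scores over all nodes.
#' @export
#' @examples
#' H <- hypergraph(list(c("a", "b", "c")))
#' p <- hc_decompose(H)
#' hypercoreness(p, "uniform")    # R  = 2 for every node
#' hypercoreness(p, "frequency")  # R_w = 1 for every node
hypercoreness <- function(profile, g = "uniform") {
  ms <- 2:profile$M
  gv <-
    if (is.function(g)) vapply(ms, g, numeric(1))
    else if (is.character(g)) switch(match.arg(g, c("uniform", "frequency")),
                                     uniform = rep(1, length(ms)),
                                     frequency = as.numeric(profile$psi))
    else as.numeric(g)
  if (length(gv) != length(ms))
    stop("g must provide one weight per size m = 2..M")
  if (any(gv < 0)) stop("weight function g must be non-negative")
  norm <- ifelse(profile$k_max > 0, as.numeric(profile$k_max), Inf)
  scores <- as.numeric(profile$shell %*% (gv / norm))
  stats::setNames(scores, profile$nodes)
}

#' Node centrality table
#'
#' Convenience wrapper computing, for every node, the size-independent
#' hypercoreness R, the frequency-based hypercoreness R_w, and the s- and
#' k-coreness of the weighted pairwise projection.
#'
#' @param H a non-empty [hypergraph()].
#' @param profile optional precomputed [hc_decompose()] result.
#' @return data.frame with columns `node`, `R`, `R_w`, `s_coreness`,
#'   `k_coreness`.
#' @export
centrality_table <- function(H, profile = NULL) {
  profile <- profile %||% hc_decompose(H)
  proj <- project_to_weighted_graph(H)
  data.frame(node = H$nodes,
             R = as.numeric(hypercoreness(profile, "uniform")),
             R_w = as.numeric(hypercoreness(profile, "frequency")),
             s_coreness = proj$table$s_coreness,
             k_coreness = proj$table$k_coreness,
             row.names = NULL)
}
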