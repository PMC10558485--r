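#' Build a hypergraph from a bipartite edge list
#'
#' Each node of one side of a bipartite graph (e.g. a plant in a
#' plant--pollinator network) defines one candidate hyperedge: the set of its
#' neighbours on the other side (e.g. all insect species pollinating that
#' plant).  Candidates with fewer than two members are dropped and duplicates
#' merged, as for any hypergraph ingest.
#'
#' @param path two-column text file (whitespace- or comma-separated), each
#'   line one edge `left right`; `#` lines ignored.
#' @param side which side becomes the node set of the hypergraph:
#'   `"left"` (first column) or `"right"` (second column).
#' @param quiet suppress ingest messages.
#' @return a [hypergraph()] whose nodes are the labels of `side`.
#' @export
bipartite_to_hypergraph <- function(path, side = c("left", "right"), quiet = FALSE) {
  side <- match.arg(side)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("empty bipartite file: ", path)
  lr <- matrix("", length(keep), 2)
  for (q in seq_along(keep)) {
    toks <- strsplit(trimws(lines[[keep[q]]]), "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != 2L)
      stop("malformed line ", keep[q], " in ", path, ": expected 2 columns")
    lr[q, ] <- toks
  }
  if (side == "left") {
    members <- lr[, 1]; groups <- lr[, 2]
  } else {
    members <- lr[, 2]; groups <- lr[, 1]
  }
  edges <- split(members, groups)
  hypergraph(edges, quiet = quiet)
}

#' Read a timestamped contact stream
#'
#' @param path three-column text file `t i j` (whitespace-separated,
#'   `t` integer seconds); `#` lines ignored.
#' @return data.frame with columns `t`, `i`, `j`, sorted by `t`.
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("t", "i", "j"),
                          colClasses = c("numeric", "character", "character"))
  if (any(df$i == df$j)) stop("self-contacts (i == j) are not allowed")
  df[order(df$t), , drop = FALSE]
}

#' Aggregate a contact stream into a hypergraph
#'
#' Pairwise contacts are aggregated over consecutive time windows (default 15
#' minutes).  Within each window the graph of all pairs with at least one
#' event is formed, its maximal cliques are enumerated, and every maximal
#' clique of size >= 2 is promoted to a hyperedge; the union over windows is
#' deduplicated.  Windows are half-open, non-overlapping and anchored at the
#' first timestamp.
#'
#' @param contacts data.frame as returned by [read_contacts()], or a path.
#' @param window_seconds window length in seconds (default 900 = 15 min).
#' @param quiet suppress ingest messages.
#' @return a [hypergraph()].
#' @export
contacts_to_hypergraph <- function(contacts, window_seconds = 900, quiet = FALSE) {
  if (is.character(contacts)) contacts <- read_contacts(contacts)
  stopifnot(nrow(contacts) > 0, window_seconds > 0)
  t0 <- min(contacts$t)
  win <- floor((contacts$t - t0) / window_seconds)
  edges <- list()
  for (w in unique(win)) {
    sub <- contacts[win == w, , drop = FALSE]
    pairs <- unique(cbind(pmin(sub$i, sub$j), pmax(sub$i, sub$j)))
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    cl <- igraph::max_cliques(g, min = 2)
    edges <- c(edges, lapply(cl, function(v) igraph::V(g)$name[v]))
  }
  hypergraph(edges, quiet = quiet)
}

#' Project a hypergraph onto its weighted pairwise graph
#'
#' Every hyperedge is replaced by a clique; the weight of edge (i, j) is the
#' number of distinct hyperedges containing both i and j.  On this weighted
#' graph the s-core decomposition of Eidsaa and Almaas assigns each node its
#' s-coreness S(i) (largest integer strength threshold s such that i survives
#' in the s-core, obtained by recursive removal), and the unweighted k-core
#' decomposition its k-coreness.
#'
#' @param H a non-empty [hypergraph()].
#' @return an object of class `hyperprojection`: a list with `graph` (an
#'   igraph graph with `weight` edge attribute), and a data.frame `table`
#'   with columns `node`, `strength`, `s_coreness`, `k_coreness` (nodes in
#'   `H$nodes` order; isolated nodes have all three equal to 0).
#' @export
project_to_weighted_graph <- function(H) {
  if (!length(H$edges)) stop("cannot project an empty hypergraph")
  pair_i <- integer(0); pair_j <- integer(0)
  for (e in H$edges) {
    cmb <- utils::combn(e, 2L)
    pair_i <- c(pair_i, cmb[1, ]); pair_j <- c(pair_j, cmb[2, ])
  }
  key <- paste(pair_i, pair_j)
  w <- table(key)
  uk <- names(w)
  ij <- do.call(rbind, strsplit(uk, " "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = H$nodes[as.integer(ij[, 1])],
               to = H$nodes[as.integer(ij[, 2])],
               weight = as.integer(w)),
    directed = FALSE,
    vertices = data.frame(name = H$nodes))
  strength <- igraph::strength(g)
  kcore <- igraph::coreness(g)
  score <- s_coreness(g)
  tab <- data.frame(node = H$nodes,
                    strength = as.numeric(strength[H$nodes]),
                    s_coreness = as.numeric(score[H$nodes]),
                    k_coreness = as.numeric(kcore[H$nodes]),
                    row.names = NULL)
  structure(list(graph = g, table = tab), class = "hyperprojection")
}

#' @export
print.hyperprojection <- function(x, ...) {
  cat("Weighted projection:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' s-core decomposition of a weighted graph
#'
#' Recursive-removal s-core sweep for integer edge weights: the s-core is the
#' maximal subgraph in which every node has strength (sum of incident
#' weights) at least s, and S(i) is the largest integer s such that i belongs
#' to the s-core.  Thresholds advance through the successive minimum
#' strengths of the remaining subgraph.
#'
#' @param g an igraph graph with a positive `weight` edge attribute.
#' @return named numeric vector of s-coreness values.
#' @export
s_coreness <- function(g) {
  out <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  while (igraph::vcount(g) > 0) {
    str <- igraph::strength(g)
    s <- min(str)
    # every remaining node is in the s-core; peel all that fail threshold s+1
    repeat {
      str <- igraph::strength(g)
      drop <- which(str <= s)
      if (!length(drop)) break
      out[names(str)[drop]] <- s
      g <- igraph::delete_vertices(g, drop)
      if (igraph::vcount(g) == 0) break
    }
  }
  out
}
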