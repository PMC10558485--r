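#' Construct a hypergraph
#'
#' A hypergraph is a set of nodes together with a set of hyperedges, where
#' each hyperedge is a set of at least two distinct nodes representing one
#' group interaction.  Hyperedges carry no multiplicity: duplicate edges are
#' merged, and hyperedges reduced to a single node are dropped.
#'
#' @param edges list of character (or coercible) vectors, one hyperedge each.
#'   Duplicate node labels within a hyperedge are collapsed; hyperedges with
#'   fewer than two distinct members are dropped with a message.
#' @param nodes optional character vector of node labels.  Nodes appearing in
#'   `edges` but not in `nodes` are added; isolated nodes can be declared here.
#' @param quiet suppress messages about dropped singletons / merged duplicates.
#'
#' @return An object of class `hypergraph` with components:
#'   \describe{
#'     \item{nodes}{character vector of node labels (the label/index map:
#'       internal index `i` is position `i` in this vector);}
#'     \item{edges}{list of sorted integer vectors indexing `nodes`;}
#'     \item{N}{number of nodes;}
#'     \item{M}{largest hyperedge size (0 if no hyperedges).}
#'   }
#' @export
#' @examples
#' H <- hypergraph(list(c("a", "b", "c"), c("a", "b")))
#' H$N  # 3
#' H$M  # 3
hypergraph <- function(edges, nodes = NULL, quiet = FALSE) {
  edges <- lapply(edges, function(e) unique(as.character(e)))
  labels <- unique(c(as.character(nodes %||% character()), unlist(edges)))
  sizes <- lengths(edges)
  n_singleton <- sum(sizes < 2L)
  edges <- edges[sizes >= 2L]
  idx <- unname(lapply(edges, function(e) sort.int(match(e, labels))))
  keys <- vapply(idx, paste, "", collapse = " ")
  n_dup <- sum(duplicated(keys))
  idx <- idx[!duplicated(keys)]
  if (!quiet && n_singleton > 0L)
    message("dropped ", n_singleton, " hyperedge(s) with fewer than 2 distinct nodes")
  if (!quiet && n_dup > 0L)
    message("merged ", n_dup, " duplicate hyperedge(s)")
  structure(
    list(nodes = labels, edges = idx, N = length(labels),
         M = if (length(idx)) max(lengths(idx)) else 0L),
    class = "hypergraph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hypergraph <- function(x, ...) {
  cat("Hypergraph: ", x$N, " nodes, ", length(x$edges),
      " hyperedges (max size ", x$M, ")\n", sep = "")
  if (length(x$edges)) {
    tab <- table(factor(lengths(x$edges), levels = 2:max(2L, x$M)))
    cat("  sizes:", paste0(names(tab), ":", as.integer(tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Hyperedges as label sets
#'
#' @param H a [hypergraph()].
#' @return list of character vectors, one per hyperedge.
#' @export
hyperedges <- function(H) lapply(H$edges, function(e) H$nodes[e])

#' Size-resolved hyperdegrees
#'
#' `hyperdegree(H, m)` counts, for every node, the distinct hyperedges of
#' exactly size `m` it belongs to (the m-hyper-degree d_m).  `hyperdegree_ge`
#' counts hyperedges of size at least `m` (D_m).  With `m = NULL`,
#' `hyperdegree` returns the full degree-vector matrix with one column per
#' size from 2 to `M`.
#'
#' @param H a [hypergraph()].
#' @param m hyperedge size (>= 2), or `NULL` for the full matrix.
#' @return named integer vector over nodes, or an N x (M-1) matrix.
#' @export
hyperdegree <- function(H, m = NULL) {
  sizes <- lengths(H$edges)
  count_for <- function(mm) {
    d <- integer(H$N)
    sel <- H$edges[sizes == mm]
    if (length(sel)) {
      t <- tabulate(unlist(sel), nbins = H$N)
      d <- d + t
    }
    names(d) <- H$nodes
    d
  }
  if (!is.null(m)) {
    stopifnot(m >= 2)
    return(count_for(as.integer(m)))
  }
  ms <- seq.int(2L, max(2L, H$M))
  mat <- vapply(ms, count_for, integer(H$N))
  dimnames(mat) <- list(H$nodes, ms)
  mat
}

#' @rdname hyperdegree
#' @export
hyperdegree_ge <- function(H, m) {
  stopifnot(m >= 2)
  sizes <- lengths(H$edges)
  sel <- H$edges[sizes >= m]
  d <- if (length(sel)) tabulate(unlist(sel), nbins = H$N) else integer(H$N)
  names(d) <- H$nodes
  d
}

#' Hyperedge-size distribution
#'
#' Fraction Psi(m) of hyperedges of each size m in 2..M.
#'
#' @param H a [hypergraph()].
#' @return named numeric vector over sizes 2..M (empty if no hyperedges).
#' @export
size_distribution <- function(H) {
  if (!length(H$edges)) return(numeric(0))
  tab <- tabulate(lengths(H$edges), nbins = H$M)
  psi <- tab[2:H$M] / length(H$edges)
  names(psi) <- 2:H$M
  psi
}

#' Read a hypergraph from a file
#'
#' Two dialects are supported.  `"edgelist"`: one hyperedge per line, node
#' labels separated by whitespace or commas, lines starting with `#` ignored.
#' `"json"`: an object with fields `"nodes"` (array of labels) and
#' `"hyperedges"` (array of label arrays).
#'
#' Duplicate hyperedges are merged and singletons dropped, with a message
#' giving the counts.  Node labels are preserved verbatim.
#'
#' @param path file path.
#' @param dialect `"edgelist"` or `"json"`.
#' @param quiet suppress ingest messages.
#' @return a [hypergraph()].
#' @export
read_hypergraph <- function(path, dialect = c("edgelist", "json"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(obj$hyperedges)) stop("JSON hypergraph needs a 'hyperedges' field")
    edges <- lapply(obj$hyperedges, function(e) vapply(e, as.character, ""))
    nodes <- if (!is.null(obj$nodes)) vapply(obj$nodes, as.character, "") else NULL
    return(hypergraph(edges, nodes = nodes, quiet = quiet))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("empty hypergraph file: ", path)
  edges <- vector("list", sum(keep))
  j <- 0L
  for (ln in which(keep)) {
    toks <- strsplit(trimws(lines[[ln]]), "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) stop("malformed line ", ln, " in ", path)
    j <- j + 1L
    edges[[j]] <- toks
  }
  hypergraph(edges, quiet = quiet)
}

#' Write a hypergraph to a file
#'
#' Inverse of [read_hypergraph()]; a write/read round trip reproduces the
#' identical node and hyperedge sets.
#'
#' @param H a [hypergraph()].
#' @param path output file path.
#' @param dialect `"edgelist"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_hypergraph <- function(H, path, dialect = c("edgelist", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    jsonlite::write_json(
      list(nodes = H$nodes, hyperedges = hyperedges(H)),
      path, auto_unbox = FALSE)
  } else {
    writeLines(vapply(hyperedges(H), paste, "", collapse = " "), path)
  }
  invisible(path)
}

# internal: canonical string key of a sorted integer hyperedge
edge_key <- function(e) paste(e, collapse = " ")

# internal: hypergraph from a list of sorted integer index vectors (assumed
# deduplicated, sizes >= 2) and a label vector
hypergraph_from_idx <- function(idx, labels) {
  structure(
    list(nodes = labels, edges = idx, N = length(labels),
         M = if (length(idx)) max(lengths(idx)) else 0L),
    class = "hypergraph")
}
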