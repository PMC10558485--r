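#' Degree-preserving hypergraph shuffling
#'
#' Randomizes a hypergraph while preserving the number of nodes, the number
#' of hyperedges of every size, and the full degree vector d(i) of every
#' node.  For each size m with at least 4 hyperedges, `swaps_per_size`
#' accepted swaps are performed: two distinct hyperedges of size m are drawn
#' at random, one random node of each is exchanged between them, and the
#' swap is accepted only if neither resulting hyperedge contains a repeated
#' node or duplicates a hyperedge already present.  Sizes with fewer than 4
#' hyperedges are left untouched (with a message).
#'
#' @param H a [hypergraph()].
#' @param swaps_per_size accepted swaps per hyperedge size (default 1e5, as
#'   used for empirical data; scale down for small hypergraphs).
#' @param seed optional integer seed (sets the RNG).
#' @param reject_cap maximum proposals per size, as a multiple of
#'   `swaps_per_size`, to guarantee termination on rigid instances.
#' @param quiet suppress messages about skipped sizes.
#' @return a shuffled [hypergraph()] with the same nodes.
#' @export
hg_shuffle <- function(H, swaps_per_size = 1e5, seed = NULL,
                       reject_cap = 100, quiet = TRUE) {
  stopifnot(swaps_per_size >= 0)
  if (!is.null(seed)) set.seed(seed)
  edges <- H$edges
  keys <- new.env(parent = emptyenv())
  for (q in seq_along(edges)) assign(edge_key(edges[[q]]), q, envir = keys)
  sizes <- lengths(edges)
  for (m in sort(unique(sizes))) {
    ids <- which(sizes == m)
    if (length(ids) < 4L) {
      if (!quiet) message("size ", m, ": fewer than 4 hyperedges, not shuffled")
      next
    }
    accepted <- 0L
    attempts <- 0L
    cap <- reject_cap * max(1, swaps_per_size)
    while (accepted < swaps_per_size && attempts < cap) {
      attempts <- attempts + 1L
      ab <- ids[sample.int(length(ids), 2L)]
      e <- edges[[ab[1]]]; f <- edges[[ab[2]]]
      i <- e[sample.int(m, 1L)]; j <- f[sample.int(m, 1L)]
      if (i == j) next
      if (j %in% e || i %in% f) next  # would create a repeated node
      e2 <- sort.int(c(e[e != i], j))
      f2 <- sort.int(c(f[f != j], i))
      ke2 <- edge_key(e2); kf2 <- edge_key(f2)
      if (ke2 == kf2) next
      if (exists(ke2, envir = keys, inherits = FALSE) ||
          exists(kf2, envir = keys, inherits = FALSE)) next
      rm(list = c(edge_key(e), edge_key(f)), envir = keys)
      edges[[ab[1]]] <- e2; edges[[ab[2]]] <- f2
      assign(ke2, ab[1], envir = keys)
      assign(kf2, ab[2], envir = keys)
      accepted <- accepted + 1L
    }
    if (!quiet && accepted < swaps_per_size)
      message("size ", m, ": proposal cap reached after ", accepted,
              " accepted swaps")
  }
  hypergraph_from_idx(edges, H$nodes)
}

#' z-score profile of hyper-core sizes against the shuffled null
#'
#' Decomposes the hypergraph and `n_realizations` independent shuffles of it
#' ([hg_shuffle()]), and reports, for every (k,m) cell, the empirical
#' relative core size n_(k,m), the null mean and sample standard deviation
#' (denominator n-1; cells absent in a realization count as 0), and the
#' z-score z_(k,m) = (n_emp - mean)/sd.  Cells with zero null sd carry
#' `defined = FALSE`; `significant` flags defined cells with |z| >= 1.96.
#'
#' @param H a non-empty [hypergraph()].
#' @param n_realizations number of shuffled realizations (>= 2; 1e3 for
#'   empirical-scale runs).
#' @param swaps_per_size accepted swaps per size in each realization.
#' @param seed optional integer master seed; realizations consume one
#'   sequential RNG stream, so the full profile is reproducible.
#' @return data.frame `(m, k, n_emp, null_mean, null_sd, null_max, z,
#'   defined, significant)` over all cells non-empty in the data or in any
#'   realization, with attributes `n_realizations`, `swaps_per_size`.
#'   `null_max` (the largest value over the realizations) supports
#'   nonparametric significance statements for cells whose null
#'   distribution is degenerate.
#' @export
z_profile <- function(H, n_realizations = 1000, swaps_per_size = 1e5,
                      seed = NULL) {
  stopifnot(n_realizations >= 2)
  if (!is.null(seed)) set.seed(seed)
  cell_vec <- function(prof) {
    stats::setNames(prof$n_km$n_km, paste(prof$n_km$m, prof$n_km$k))
  }
  emp <- cell_vec(hc_decompose(H))
  null_vals <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    Hs <- hg_shuffle(H, swaps_per_size = swaps_per_size)
    null_vals[[r]] <- cell_vec(hc_decompose(Hs))
  }
  cells <- unique(c(names(emp), unlist(lapply(null_vals, names))))
  mk <- do.call(rbind, strsplit(cells, " "))
  vals <- vapply(null_vals, function(v) {
    out <- v[cells]
    out[is.na(out)] <- 0
    out
  }, numeric(length(cells)))
  vals <- matrix(vals, nrow = length(cells))
  mu <- rowMeans(vals)
  sd <- apply(vals, 1, stats::sd)
  n_emp <- emp[cells]
  n_emp[is.na(n_emp)] <- 0
  z <- ifelse(sd > 0, (n_emp - mu) / sd, NA_real_)
  out <- data.frame(m = as.integer(mk[, 1]), k = as.integer(mk[, 2]),
                    n_emp = as.numeric(n_emp), null_mean = mu, null_sd = sd,
                    null_max = apply(vals, 1, max),
                    z = z, defined = sd > 0,
                    significant = !is.na(z) & abs(z) >= 1.96,
                    row.names = NULL)
  out <- out[order(out$m, out$k), ]
  rownames(out) <- NULL
  attr(out, "n_realizations") <- n_realizations
  attr(out, "swaps_per_size") <- swaps_per_size
  out
}
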