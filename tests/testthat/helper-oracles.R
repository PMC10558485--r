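# Independent brute-force oracles used to validate the implementation on
# small instances.  All of them enumerate node subsets explicitly (bitmask
# over N <= 8..16 nodes) and never share code with the package internals.

popcount_table <- function(nbits) {
  vapply(0:(2^nbits - 1),
         function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:(nbits - 1))) != 0),
         integer(1))
}

# (k,m)-hyper-core by exhaustive subset search: a node set A is valid when
# every member belongs to >= k *distinct* induced hyperedges (intersections
# with A, deduplicated) of size >= m; the core is the union of all valid
# sets.  Returns a list over m of lists over k of sorted label vectors.
oracle_km_all <- function(H, k_range = 1:3, m_range = 2:4) {
  N <- H$N
  stopifnot(N <= 12)
  pc <- popcount_table(N)
  emask <- vapply(H$edges, function(e) sum(bitwShiftL(1L, e - 1L)), integer(1))
  bitv <- bitwShiftL(1L, 0:(N - 1))
  best <- matrix(0L, max(k_range), max(m_range))
  for (mask in 1:(2^N - 1)) {
    bits <- which(bitwAnd(mask, bitv) != 0)
    for (m in m_range) {
      im <- unique(bitwAnd(emask, mask))
      im <- im[pc[im + 1L] >= m]
      dmin <- if (!length(im)) 0L else
        min(vapply(bits, function(v) sum(bitwAnd(im, bitv[v]) != 0), integer(1)))
      for (k in k_range)
        if (dmin >= k) best[k, m] <- bitwOr(best[k, m], mask)
    }
  }
  out <- list()
  for (m in m_range) for (k in k_range) {
    sel <- which(bitwAnd(best[k, m], bitv) != 0)
    out[[paste(k, m)]] <- sort(H$nodes[sel])
  }
  out
}

# random small hypergraph with feasible hyperedge-size counts
rand_small_hg <- function(n_max = 8, e_max = 12) {
  N <- sample(4:n_max, 1)
  counts <- c("2" = sample(0:6, 1), "3" = sample(0:4, 1), "4" = sample(0:3, 1))
  for (m in names(counts)) counts[m] <- min(counts[m], choose(N, as.integer(m)))
  while (sum(counts) > e_max) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  if (sum(counts) == 0) counts["2"] <- min(1, choose(N, 2))
  random_hypergraph(N, counts)
}

# maximal cliques of a pairwise graph by subset maximality search
oracle_max_cliques <- function(nodes, pairs) {
  N <- length(nodes)
  stopifnot(N <= 10)
  adj <- matrix(FALSE, N, N, dimnames = list(nodes, nodes))
  for (q in seq_len(nrow(pairs))) {
    adj[pairs[q, 1], pairs[q, 2]] <- TRUE
    adj[pairs[q, 2], pairs[q, 1]] <- TRUE
  }
  subsets <- lapply(1:(2^N - 1), function(mask)
    which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1))) != 0))
  is_clique <- vapply(subsets, function(s)
    length(s) >= 2 && all(adj[s, s][upper.tri(diag(length(s)))]), logical(1))
  cl <- subsets[is_clique]
  maximal <- vapply(seq_along(cl), function(q)
    !any(vapply(cl, function(o)
      length(o) > length(cl[[q]]) && all(cl[[q]] %in% o), logical(1))),
    logical(1))
  sort(vapply(cl[maximal], function(s) paste(sort(nodes[s]), collapse = " "), ""))
}

# s-coreness by exhaustive subset search on the weighted projection:
# S(i) = max s such that i lies in some subset whose every member has
# within-subset strength >= s
oracle_s_coreness <- function(H) {
  N <- H$N
  stopifnot(N <= 8)
  W <- matrix(0, N, N)
  for (e in H$edges) for (a in e) for (b in e) if (a < b) {
    W[a, b] <- W[a, b] + 1; W[b, a] <- W[b, a] + 1
  }
  S <- stats::setNames(numeric(N), H$nodes)
  for (mask in 1:(2^N - 1)) {
    A <- which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1))) != 0)
    if (length(A) < 2) next
    smin <- min(rowSums(W[A, A, drop = FALSE]))
    S[A] <- pmax(S[A], smin)
  }
  S
}

# textbook tie-adjusted Kendall tau_b
oracle_tau_b <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(vapply(table(x), function(t) t * (t - 1) / 2, numeric(1)))
  n2 <- sum(vapply(table(y), function(t) t * (t - 1) / 2, numeric(1)))
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Exact two-node SIS oracle on a single pair hyperedge under synchronous
# updates.  States (a,b): 1=SS (absorbing), 2=IS, 3=SI, 4=II.  Returns the
# expected total infectious node-steps accumulated at the starts of the T
# window steps, conditional on the chain not being absorbed after the final
# window step, for a uniformly chosen single seed.
pair_sis_oracle <- function(lambda, nu, mu, burn_in, T) {
  q <- 1 - exp(-lambda * 1^nu)
  P <- rbind(c(1, 0, 0, 0),
             c(mu * (1 - q), (1 - mu) * (1 - q), mu * q, (1 - mu) * q),
             c(mu * (1 - q), mu * q, (1 - mu) * (1 - q), (1 - mu) * q),
             c(mu^2, (1 - mu) * mu, mu * (1 - mu), (1 - mu)^2))
  occ <- c(0, 1, 1, 2)
  pi <- c(0, 0.5, 0.5, 0)
  for (t in seq_len(burn_in)) pi <- as.numeric(pi %*% P)
  f <- numeric(4)
  for (t in seq_len(T)) {
    f <- f + occ * pi
    f <- as.numeric(f %*% P)
    pi <- as.numeric(pi %*% P)
  }
  sum(f[2:4]) / sum(pi[2:4])
}

# Exact mean absorption time of the two-node naming game (edge {a,b}, a
# committed, union rule, beta = 1) from the fundamental matrix of the
# 3-state chain over b's dictionary ({B}, {A,B}, {A} absorbing).
pair_ng_mean_absorption <- function() {
  Q <- rbind(c(1 / 2, 1 / 2),    # {B}: stay, -> {A,B}
             c(0, 1 / 4))        # {A,B}: never back, stay w.p. 1/4
  Nf <- solve(diag(2) - Q)
  sum(Nf[1, ])
}
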