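test_that("single-hyperedge cores and parameter validation", {
  H <- hypergraph(list(c("a", "b", "c")))
  expect_setequal(km_core(H, 1, 3), c("a", "b", "c"))
  expect_length(km_core(H, 2, 2), 0)
  expect_error(km_core(H, 0, 2), "k must be")
  expect_error(km_core(H, 1, 1), "m must be")
  p <- hc_decompose(H)
  expect_equal(unname(p$k_max), c(1L, 1L))
  expect_true(all(p$shell == 1L))
})

test_that("a path of two pairwise edges has a trivial decomposition", {
  H <- hypergraph(list(c("a", "b"), c("b", "c")))
  expect_setequal(km_core(H, 1, 2), c("a", "b", "c"))
  expect_length(km_core(H, 2, 2), 0)
  p <- hc_decompose(H)
  expect_equal(as.vector(p$shell[, "2"]), c(1L, 1L, 1L))
})

test_that("peeling equals the exhaustive subset oracle on random hypergraphs", {
  set.seed(52)
  for (r in 1:25) {
    H <- rand_small_hg()
    oracle <- oracle_km_all(H, 1:3, 2:4)
    for (cell in names(oracle)) {
      km <- as.integer(strsplit(cell, " ")[[1]])
      expect_identical(sort(km_core(H, km[1], km[2])), oracle[[cell]],
                       label = paste("core", cell))
    }
  }
})

test_that("profile cells agree with independent km_core calls", {
  set.seed(53)
  for (r in 1:6) {
    H <- rand_small_hg()
    p <- hc_decompose(H)
    for (m in 2:H$M) {
      kmax <- p$k_max[[as.character(m)]]
      for (k in seq_len(kmax + 1))
        expect_setequal(profile_core(p, k, m), km_core(H, k, m))
    }
  }
})

test_that("nesting and shell-partition invariants hold", {
  set.seed(54)
  fixtures <- c(lapply(1:8, function(i) rand_small_hg()),
                list(toy_hypergraph(),
                     planted_core_hypergraph(6, 2, 3, 6, seed = 5)$H))
  for (H in fixtures) {
    p <- hc_decompose(H)
    for (m in 2:H$M) {
      kmax <- p$k_max[[as.character(m)]]
      for (k in seq_len(kmax)) {
        core <- profile_core(p, k, m)
        expect_true(all(profile_core(p, k + 1, m) %in% core))
        expect_true(all(profile_core(p, k, m + 1) %in% core))
      }
      # shells partition the (1,m)-core
      C <- p$shell[, as.character(m)]
      expect_equal(sum(C > 0), length(profile_core(p, 1, m)))
      for (k in seq_len(kmax))
        expect_equal(sum(C == k),
                     length(profile_core(p, k, m)) -
                       length(profile_core(p, k + 1, m)))
      # n_km non-increasing in k
      sizes <- p$n_km$n_km[p$n_km$m == m]
      expect_true(all(diff(sizes) <= 0))
    }
    # shell index is the deepest core containing the node
    for (m in 2:H$M) {
      C <- p$shell[, as.character(m)]
      for (i in seq_len(H$N)) {
        node <- H$nodes[i]
        if (C[i] > 0) {
          expect_true(node %in% profile_core(p, C[i], m))
          expect_false(node %in% profile_core(p, C[i] + 1, m))
        } else {
          expect_false(node %in% profile_core(p, 1, m))
        }
      }
    }
  }
})

test_that("the decomposition is invariant under node relabelling (peeling order)", {
  set.seed(55)
  H <- rand_small_hg()
  p0 <- hc_decompose(H)
  for (r in 1:10) {
    perm <- sample(H$N)
    Hp <- hypergraph(lapply(hyperedges(H), identity),
                     nodes = H$nodes[perm], quiet = TRUE)
    pp <- hc_decompose(Hp)
    expect_equal(pp$shell[H$nodes, , drop = FALSE],
                 p0$shell[H$nodes, , drop = FALSE])
  }
})

test_that("hypercoreness matches its definition and bounds", {
  H <- hypergraph(list(c("a", "b", "c")))
  p <- hc_decompose(H)
  expect_equal(unname(hypercoreness(p, "uniform")), rep(2, 3))
  expect_equal(unname(hypercoreness(p, "frequency")), rep(1, 3))
  # single-size selector g(m) = delta(m - 3)
  expect_equal(unname(hypercoreness(p, c(0, 1))), rep(1, 3))
  expect_error(hypercoreness(p, c(-1, 1)), "non-negative")

  set.seed(56)
  for (r in 1:6) {
    H <- rand_small_hg()
    p <- hc_decompose(H)
    R <- hypercoreness(p, "uniform")
    Rw <- hypercoreness(p, "frequency")
    expect_true(all(R >= 0 & R <= H$M - 1))
    expect_true(all(Rw >= 0 & Rw <= 1))
    # independent recomputation of R_w from tallied sizes and shell indices
    psi <- as.numeric(table(factor(lengths(hyperedges(H)), levels = 2:H$M))) /
      length(H$edges)
    manual <- numeric(H$N)
    for (mi in seq_along(2:H$M)) {
      m <- (2:H$M)[mi]
      kmax <- p$k_max[[as.character(m)]]
      if (kmax == 0) next
      Cm <- vapply(H$nodes, function(v) {
        k <- 0L
        while (v %in% km_core(H, k + 1L, m)) k <- k + 1L
        k
      }, integer(1))
      manual <- manual + psi[mi] * Cm / kmax
    }
    expect_equal(unname(Rw), unname(manual), tolerance = 1e-12)
    # monotone under pointwise-larger g
    g1 <- runif(H$M - 1); g2 <- g1 + runif(H$M - 1)
    expect_true(all(hypercoreness(p, g2) >= hypercoreness(p, g1) - 1e-12))
  }
})

test_that("planted-core members attain the deepest shell at the planted size", {
  set.seed(57)
  for (r in 1:5) {
    fx <- planted_core_hypergraph(8, 3, 4, 10)
    p <- hc_decompose(fx$H)
    C4 <- p$shell[, "4"]
    expect_true(all(C4[fx$core] == max(C4)))
    expect_true(all(C4[fx$periphery] == 0))
  }
})

test_that("toy hypergraph reproduces its oracle-verified decomposition", {
  H <- toy_hypergraph()
  p <- hc_decompose(H)
  expect_equal(p$k_max, c("2" = 3L, "3" = 3L))
  expected_C2 <- c(a1 = 3L, a2 = 3L, a3 = 3L, a4 = 3L, x = 2L,
                   y1 = 1L, y2 = 1L, y3 = 1L, z1 = 2L, z2 = 2L, z3 = 2L,
                   w1 = 1L, w2 = 1L)
  expected_C3 <- c(a1 = 3L, a2 = 3L, a3 = 3L, a4 = 3L, x = 1L,
                   y1 = 1L, y2 = 1L, y3 = 1L, z1 = 0L, z2 = 0L, z3 = 0L,
                   w1 = 0L, w2 = 0L)
  expect_equal(p$shell[names(expected_C2), "2"], expected_C2)
  expect_equal(p$shell[names(expected_C3), "3"], expected_C3)
  # x is excluded from the (2,3)-core despite D_3(x) = 2
  expect_equal(hyperdegree_ge(H, 3)[["x"]], 2L)
  expect_false("x" %in% km_core(H, 2, 3))
  # nesting chain (1,2) >= (2,2) >= (2,3)
  expect_true(all(km_core(H, 2, 2) %in% km_core(H, 1, 2)))
  expect_true(all(km_core(H, 2, 3) %in% km_core(H, 2, 2)))
  # the (1,3)-core splits into two disjoint subhypergraphs
  core13 <- km_core(H, 1, 3)
  big <- H$edges[lengths(H$edges) >= 3]
  g <- igraph::graph_from_data_frame(
    do.call(rbind, lapply(big, function(e)
      t(utils::combn(H$nodes[e], 2)))) |> as.data.frame(),
    directed = FALSE, vertices = data.frame(name = core13))
  expect_equal(igraph::count_components(g), 2)
})
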