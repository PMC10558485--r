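test_that("infection probability follows the nonlinear group-exposure form", {
  H <- hypergraph(list(c("a", "b")))
  expect_equal(infection_probability(H, "b", character(0), 0.5), 0)
  expect_equal(infection_probability(H, "b", "a", 0.3), 1 - exp(-0.3),
               tolerance = 1e-14)
  # two hyperedges with 2 and 3 infected members, nu = 2
  H2 <- hypergraph(list(c("j", "u", "v"), c("j", "w", "x", "y")))
  expect_equal(
    infection_probability(H2, "j", c("u", "v", "w", "x", "y"), 0.01, nu = 2),
    1 - exp(-0.01 * (2^2 + 3^2)), tolerance = 1e-14)
  expect_error(infection_probability(H, "b", "a", -0.1), "non-negative")
  expect_error(infection_probability(H, "a", "a", 0.1), "already infected")
})

test_that("infection probability composes per-hyperedge factors", {
  set.seed(71)
  for (r in 1:10) {
    H <- rand_small_hg()
    j <- sample(H$nodes, 1)
    others <- setdiff(H$nodes, j)
    infected <- sample(others, sample.int(length(others), 1))
    lambda <- runif(1, 0, 0.9); nu <- runif(1, 0.5, 3)
    p_e <- vapply(hyperedges(H), function(e) {
      if (!(j %in% e)) return(NA_real_)
      1 - exp(-lambda * sum(e %in% infected)^nu)
    }, numeric(1))
    p_e <- p_e[!is.na(p_e)]
    expect_equal(infection_probability(H, j, infected, lambda, nu),
                 1 - prod(1 - p_e), tolerance = 1e-12)
  }
})

test_that("for nu = 1 on pairwise hyperedges the classical SIS probability is recovered", {
  set.seed(72)
  H <- random_hypergraph(8, c("2" = 12), seed = 72)
  infected <- sample(H$nodes, 4)
  j <- setdiff(H$nodes, infected)[1]
  n_inf_neigh <- sum(vapply(hyperedges(H), function(e)
    j %in% e && any(e %in% infected), logical(1)))
  expect_equal(infection_probability(H, j, infected, 0.2, nu = 1),
               1 - exp(-0.2 * n_inf_neigh), tolerance = 1e-12)
})

test_that("SIR degenerate and bounding behaviour", {
  fx <- planted_core_hypergraph(6, 2, 3, 6, seed = 73)
  r0 <- run_sir_seed(fx$H, fx$core[1], lambda = 0, mu = 0.3, n_runs = 40,
                     seed = 1)
  expect_true(all(r0$sizes == 1))
  # reachability bound: final size <= hyperedge-connected component of seed
  comp <- igraph::components(project_to_weighted_graph(fx$H)$graph)
  r1 <- run_sir(fx$H, lambda = 0.5, mu = 0.2, n_runs = 20, seed = 2)
  for (v in names(r1))
    expect_lte(r1[[v]], comp$csize[comp$membership[[v]]])
})

test_that("two-node SIR matches the synchronous-update closed form", {
  H <- hypergraph(list(c("a", "b")))
  lambda <- 0.4; mu <- 0.5
  q <- 1 - exp(-lambda)
  expected <- 1 + q / (1 - (1 - q) * (1 - mu))
  rs <- run_sir_seed(H, "a", lambda = lambda, mu = mu, n_runs = 4000, seed = 3)
  se <- stats::sd(rs$sizes) / sqrt(length(rs$sizes))
  expect_lt(abs(rs$mean - expected), 3 * se)
})

test_that("mean SIR final size is non-decreasing in lambda", {
  fx <- planted_core_hypergraph(8, 3, 4, 8, seed = 74)
  means <- vapply(c(0.02, 0.1, 0.4), function(l)
    mean(run_sir(fx$H, lambda = l, mu = 0.2, n_runs = 60,
                 seeds = fx$core[1:4], seed = 99)),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("SIS degenerate limits behave as the dynamics dictates", {
  H <- hypergraph(list(c("a", "b"), c("b", "c")))
  # mu = 1, lambda = 0: the seed recovers immediately, every run extinct
  s <- run_sis(H, lambda = 0, mu = 1, T = 10, burn_in = 5, n_runs = 10,
               seed = 4)
  expect_true(all(s$extinct))
  # mu -> 0 on a connected hypergraph: absorbing all-infected state
  fx <- planted_core_hypergraph(6, 2, 3, 6, seed = 75)
  expect_true(igraph::is_connected(project_to_weighted_graph(fx$H)$graph))
  s2 <- run_sis(fx$H, lambda = 1, mu = 1e-9, T = 50, burn_in = 100,
                n_runs = 5, seed = 5)
  expect_true(all(!s2$extinct))
  expect_equal(unname(s2$tau_frac), rep(1, fx$H$N))
  # occupancy bound
  s3 <- run_sis(fx$H, lambda = 0.3, mu = 0.3, T = 40, burn_in = 20,
                n_runs = 10, seed = 6)
  ok <- !s3$extinct
  expect_true(all(rowSums(s3$tau[ok, , drop = FALSE]) <= fx$H$N * s3$T))
})

test_that("two-node SIS occupancy matches the exact Markov-chain oracle", {
  H <- hypergraph(list(c("a", "b")))
  lambda <- 0.8; mu <- 0.15; burn_in <- 10; Tw <- 40
  s <- run_sis(H, lambda = lambda, nu = 1, mu = mu, T = Tw,
               burn_in = burn_in, n_runs = 1500, seed = 7)
  ok <- !s$extinct
  tot <- rowSums(s$tau[ok, , drop = FALSE])
  expected <- pair_sis_oracle(lambda, 1, mu, burn_in, Tw)
  se <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("per-core aggregation averages the node field over each core", {
  fx <- planted_core_hypergraph(6, 2, 3, 6, seed = 76)
  p <- hc_decompose(fx$H)
  cst <- stats::setNames(rep(0.42, fx$H$N), fx$H$nodes)
  agg <- aggregate_by_core(cst, p)
  expect_true(all(agg$mean_value == 0.42))
  vals <- stats::setNames(runif(fx$H$N), fx$H$nodes)
  agg2 <- aggregate_by_core(vals, p)
  # the (1,2)-core holds every node here, so its cell is the global mean
  expect_equal(length(km_core(fx$H, 1, 2)), fx$H$N)
  expect_equal(agg2$mean_value[agg2$m == 2 & agg2$k == 1], mean(vals))
  expect_error(aggregate_by_core(vals[-1], p), "named")
})
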