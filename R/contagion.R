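#' @name contagion
#' @title Higher-order nonlinear contagion (SIS / SIR)
#'
#' @description
#' Discrete-time contagion on a hypergraph in which group interactions
#' reinforce transmission: in a hyperedge e containing `i_e` infectious
#' members, each susceptible member is infected in one time step with
#' probability `1 - exp(-lambda * i_e^nu)`, independently across hyperedges,
#' so the per-step infection probability of a susceptible node j is
#' \deqn{p_j = 1 - \prod_{e \ni j} e^{-\lambda i_e^\nu}.}
#' `nu = 1` recovers linear contagion; `nu > 1` strengthens the group
#' reinforcement.  Every infectious node recovers with probability `mu` per
#' step (to S in SIS, to R in SIR).  Updates are synchronous on
#' start-of-step states, and a node infected in a step cannot recover in
#' that same step.
NULL

# internal: sparse node x hyperedge incidence matrix
incidence_matrix <- function(H) {
  if (!length(H$edges)) stop("hypergraph has no hyperedges")
  Matrix::sparseMatrix(
    i = unlist(H$edges),
    j = rep(seq_along(H$edges), lengths(H$edges)),
    x = 1, dims = c(H$N, length(H$edges)))
}

#' Per-step infection probability of a susceptible node
#'
#' Direct evaluation of the nonlinear higher-order infection probability for
#' one node, given the current infectious set.
#'
#' @param H a [hypergraph()].
#' @param j node label (must not be in `infected`).
#' @param infected character vector of infectious node labels.
#' @param lambda infection scale, in `[0, 1]`.
#' @param nu nonlinearity exponent (> 0).
#' @return probability that `j` becomes infectious this step.
#' @export
infection_probability <- function(H, j, infected, lambda, nu = 1) {
  if (lambda < 0) stop("lambda must be non-negative")
  ji <- match(j, H$nodes)
  if (is.na(ji)) stop("unknown node: ", j)
  inf_idx <- match(infected, H$nodes)
  if (ji %in% inf_idx) stop("node ", j, " is already infected")
  prod_term <- 1
  for (e in H$edges) {
    if (!(ji %in% e)) next
    i_e <- sum(e %in% inf_idx)
    if (i_e > 0) prod_term <- prod_term * exp(-lambda * i_e^nu)
  }
  1 - prod_term
}

# one synchronous step; inf/immune logical vectors, B incidence
contagion_step <- function(inf, immune, B, lambda, nu, mu) {
  N <- length(inf)
  ie <- as.numeric(Matrix::crossprod(B, inf))
  force_on <- as.numeric(B %*% ie^nu)
  p <- 1 - exp(-lambda * force_on)
  new_inf <- !inf & !immune & (stats::runif(N) < p)
  recov <- inf & (stats::runif(N) < mu)
  list(inf = (inf & !recov) | new_inf, recovered = recov)
}

#' Simulate SIS contagion and measure steady-state localization
#'
#' Each run starts from a single uniformly random infectious seed.  After
#' `burn_in` steps, the number of steps each node spends infectious is
#' accumulated over an observation window of `T` steps (states are counted
#' at the start of each window step).  Runs in which the infection dies out
#' at any time before the window completes are flagged extinct and excluded
#' from the per-node averages.
#'
#' @param H a non-empty [hypergraph()].
#' @param lambda,nu,mu contagion parameters (see [contagion]).
#' @param T observation window length in steps.
#' @param burn_in steps before the window (steady-state relaxation).
#' @param n_runs number of independent runs.
#' @param seed optional integer seed.
#' @return an object of class `sis_result`: list with `tau` (n_runs x N
#'   matrix of infectious-step counts, NA rows for extinct runs),
#'   `tau_frac` (named per-node mean of tau/T over non-extinct runs),
#'   `extinct` (logical per run), `T`, and `params`.
#' @export
run_sis <- function(H, lambda, nu = 1, mu, T = 1000, burn_in = 1000,
                    n_runs = 100, seed = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, mu > 0, mu <= 1, nu > 0, T >= 1)
  if (!is.null(seed)) set.seed(seed)
  B <- incidence_matrix(H)
  N <- H$N
  tau <- matrix(NA_real_, n_runs, N, dimnames = list(NULL, H$nodes))
  extinct <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    inf <- logical(N)
    inf[sample.int(N, 1L)] <- TRUE
    immune <- logical(N)
    died <- FALSE
    for (t in seq_len(burn_in)) {
      inf <- contagion_step(inf, immune, B, lambda, nu, mu)$inf
      if (!any(inf)) { died <- TRUE; break }
    }
    if (!died) {
      acc <- numeric(N)
      for (t in seq_len(T)) {
        acc <- acc + inf
        inf <- contagion_step(inf, immune, B, lambda, nu, mu)$inf
        if (!any(inf)) { died <- TRUE; break }
      }
    }
    extinct[r] <- died
    if (!died) tau[r, ] <- acc
  }
  tau_frac <- if (all(extinct)) stats::setNames(rep(NA_real_, N), H$nodes)
              else colMeans(tau[!extinct, , drop = FALSE]) / T
  structure(list(tau = tau, tau_frac = tau_frac, extinct = extinct, T = T,
                 params = list(lambda = lambda, nu = nu, mu = mu,
                               burn_in = burn_in, n_runs = n_runs)),
            class = "sis_result")
}

#' @export
print.sis_result <- function(x, ...) {
  cat("SIS result:", length(x$extinct), "runs,", sum(x$extinct),
      "extinct; mean prevalence",
      signif(mean(x$tau_frac, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Mean SIR final size for a given seed node
#'
#' Starts every run with only `seed_node` infectious and iterates the
#' synchronous dynamics until no infectious node remains; the final size
#' R_inf is the number of recovered nodes at that point (the seed counts).
#'
#' @param H a non-empty [hypergraph()].
#' @param seed_node label of the initially infectious node.
#' @param lambda,nu,mu contagion parameters (see [contagion]).
#' @param n_runs independent runs averaged over (default 300).
#' @param t_cap hard step limit per run (runs hitting it are dropped with a
#'   warning; cannot happen for `mu > 0` except at extreme lengths).
#' @param seed optional integer seed.
#' @return list with `mean` (mean final size), `sizes` (per-run final
#'   sizes), `seed_node`.
#' @export
run_sir_seed <- function(H, seed_node, lambda, nu = 1, mu, n_runs = 300,
                         t_cap = 1e6, seed = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, mu > 0, mu <= 1, nu > 0)
  if (!is.null(seed)) set.seed(seed)
  s0 <- match(seed_node, H$nodes)
  if (is.na(s0)) stop("unknown seed node: ", seed_node)
  B <- incidence_matrix(H)
  N <- H$N
  sizes <- rep(NA_real_, n_runs)
  for (r in seq_len(n_runs)) {
    inf <- logical(N); inf[s0] <- TRUE
    rec <- logical(N)
    t <- 0L
    while (any(inf) && t < t_cap) {
      st <- contagion_step(inf, rec, B, lambda, nu, mu)
      rec <- rec | (inf & st$recovered)
      inf <- st$inf
      t <- t + 1L
    }
    if (any(inf)) next  # t_cap hit: flagged by leaving NA
    sizes[r] <- sum(rec)
  }
  if (anyNA(sizes)) warning(sum(is.na(sizes)), " run(s) hit t_cap and were dropped")
  list(mean = mean(sizes, na.rm = TRUE), sizes = sizes, seed_node = seed_node)
}

#' Per-node SIR spreading power
#'
#' Runs [run_sir_seed()] for every node (or a subset) and collects the mean
#' final sizes, i.e. each node's spreading power R_inf(j).
#'
#' @inheritParams run_sir_seed
#' @param seeds node labels to use as seeds (default: all nodes).
#' @return named numeric vector of mean final sizes.
#' @export
run_sir <- function(H, lambda, nu = 1, mu, n_runs = 300, seeds = H$nodes,
                    t_cap = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seeds, function(s)
    run_sir_seed(H, s, lambda = lambda, nu = nu, mu = mu, n_runs = n_runs,
                 t_cap = t_cap)$mean,
    numeric(1))
}

#' Average a per-node quantity over every (k,m)-hyper-core
#'
#' @param values named numeric vector over nodes (e.g. `tau_frac` from
#'   [run_sis()] or the result of [run_sir()]).
#' @param profile a [hc_decompose()] result for the same hypergraph.
#' @return data.frame `(m, k, core_size, mean_value)` over all non-empty
#'   cores.
#' @export
aggregate_by_core <- function(values, profile) {
  if (!all(profile$nodes %in% names(values)))
    stop("values must be named with the profile's node labels")
  v <- values[profile$nodes]
  out <- profile$n_km[c("m", "k", "core_size")]
  out$mean_value <- mapply(function(m, k) {
    mean(v[profile$cores[[as.character(m)]][[k]]])
  }, out$m, out$k)
  out
}
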