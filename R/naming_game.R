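#' @name naming_game
#' @title Higher-order naming game with committed minorities
#'
#' @description
#' Convention-formation dynamics on a hypergraph.  Every node holds a
#' dictionary, a non-empty subset of the two names \{A, B\}.  Per time step
#' a hyperedge is chosen uniformly at random, a speaker is chosen uniformly
#' within it, and the speaker utters a uniformly random name from its
#' dictionary.  Agreement on the uttered name is *possible* under the
#' `union` rule if at least one listener holds the name, and under the
#' `unanimity` rule if all group members (speaker included) hold it.  A
#' possible agreement becomes *effective* with probability `beta`, in which
#' case the dictionary of every non-committed group member collapses to the
#' uttered name; otherwise every non-committed listener adds the name to its
#' dictionary.  Committed nodes hold the fixed dictionary \{A\} that is never
#' updated (they can still speak, always uttering A).  All other nodes start
#' from \{B\}.
NULL

#' Select a committed minority
#'
#' @param H a [hypergraph()].
#' @param n_p number of committed nodes (0..N).
#' @param scores optional named numeric vector over all nodes: committed
#'   nodes are the `n_p` top-scoring ones, with boundary ties resolved
#'   uniformly at random.  `NULL` selects uniformly at random.
#' @param seed optional integer seed.
#' @return character vector of `n_p` node labels.
#' @export
select_committed <- function(H, n_p, scores = NULL, seed = NULL) {
  if (n_p > H$N || n_p < 0) stop("n_p must be between 0 and N")
  if (!is.null(seed)) set.seed(seed)
  if (n_p == 0) return(character(0))
  if (is.null(scores)) return(sample(H$nodes, n_p))
  if (!all(H$nodes %in% names(scores)))
    stop("scores must be named with all node labels")
  top_f_nodes(scores[H$nodes], n_p / H$N)
}

#' Run one naming-game realization
#'
#' @param H a [hypergraph()] with at least one hyperedge.
#' @param committed character vector of committed node labels.
#' @param beta agreement probability in `[0, 1]`.
#' @param rule `"union"` or `"unanimity"` (see [naming_game]).
#' @param t_max maximum number of steps (default 5e5).
#' @param window averaging span for the stationary fraction when the run is
#'   not absorbed (default 5e4, must be <= t_max).
#' @param n_sample number of evenly spaced samples of n_A taken in the last
#'   `window` steps (default 100).
#' @param seed optional integer seed.
#' @param record_trajectory also record a sampled trajectory of n_A(t).
#' @param traj_points approximate number of trajectory points.
#' @param stop_at_absorption stop as soon as n_A = 1 (default); with `FALSE`
#'   the dynamics keeps running to `t_max` (the absorbing state cannot be
#'   left, which this option makes testable).
#' @return an object of class `ng_result`: list with `n_A_star` (1 if
#'   absorbed, else the mean of the `n_sample` window samples), `absorbed`,
#'   `t_absorbed` (NA if not absorbed), `committed`, `dictionaries` (final
#'   per-node dictionaries, `"A"`, `"B"` or `"AB"`), and optionally
#'   `trajectory` (data.frame `t`, `n_A`).
#' @export
run_ng <- function(H, committed, beta, rule = c("union", "unanimity"),
                   t_max = 5e5, window = 5e4, n_sample = 100, seed = NULL,
                   record_trajectory = FALSE, traj_points = 500,
                   stop_at_absorption = TRUE) {
  rule <- match.arg(rule)
  stopifnot(beta >= 0, beta <= 1, t_max >= 1)
  if (!length(H$edges)) stop("naming game needs at least one hyperedge")
  if (!is.null(seed)) set.seed(seed)
  window <- min(window, t_max)
  N <- H$N
  comm <- H$nodes %in% committed
  if (length(committed) != sum(comm)) stop("unknown committed node label(s)")
  edges <- H$edges
  nE <- length(edges)
  # dictionaries: 1 = {A}, 2 = {B}, 3 = {A,B}
  dict <- ifelse(comm, 1L, 2L)
  count_A <- sum(comm)
  sample_at <- unique(round(seq(t_max - window + window / n_sample, t_max,
                                length.out = n_sample)))
  samples <- numeric(0)
  traj_at <- if (record_trajectory)
    unique(c(0L, round(seq(1, t_max, length.out = traj_points)))) else integer(0)
  traj <- list()
  if (record_trajectory) traj[[1]] <- c(0, count_A / N)
  absorbed <- FALSE
  t_abs <- NA_real_
  for (t in seq_len(t_max)) {
    e <- edges[[sample.int(nE, 1L)]]
    len <- length(e)
    sp_pos <- sample.int(len, 1L)
    sp <- e[sp_pos]
    d <- dict[sp]
    name <- if (d == 3L) sample.int(2L, 1L) else d
    listeners <- e[-sp_pos]
    holds <- dict == name | dict == 3L
    possible <- if (rule == "union") any(holds[listeners]) else all(holds[e])
    if (possible && stats::runif(1) < beta) {
      nc <- e[!comm[e]]
      old <- dict[nc]
      dict[nc] <- name
      count_A <- count_A +
        if (name == 1L) sum(old != 1L) else -sum(old == 1L)
    } else {
      ln <- listeners[!comm[listeners]]
      upd <- ln[dict[ln] != name & dict[ln] != 3L]
      if (length(upd)) {
        count_A <- count_A - sum(dict[upd] == 1L)
        dict[upd] <- 3L
      }
    }
    if (record_trajectory && t %in% traj_at)
      traj[[length(traj) + 1L]] <- c(t, count_A / N)
    if (t %in% sample_at) samples <- c(samples, count_A / N)
    if (count_A == N && !absorbed) {
      absorbed <- TRUE
      t_abs <- t
      if (stop_at_absorption) break
    }
  }
  out <- list(
    n_A_star = if (absorbed) 1 else mean(samples),
    absorbed = absorbed, t_absorbed = t_abs,
    committed = H$nodes[comm],
    dictionaries = stats::setNames(c("A", "B", "AB")[dict], H$nodes),
    params = list(beta = beta, rule = rule, t_max = t_max, window = window))
  if (record_trajectory) {
    tm <- do.call(rbind, traj)
    out$trajectory <- data.frame(t = tm[, 1], n_A = tm[, 2])
  }
  structure(out, class = "ng_result")
}

#' @export
print.ng_result <- function(x, ...) {
  cat("Naming game:", if (x$absorbed)
    paste0("absorbed at t = ", x$t_absorbed) else "not absorbed",
    "; n_A* =", signif(x$n_A_star, 4), "\n")
  invisible(x)
}

# internal: median stationary fraction over n_runs realizations at one
# (beta, p) cell; committed re-drawn per run (random strategy and tie
# resolution both consume the RNG stream)
ng_cell <- function(H, beta, n_p, rule, scores, n_runs, t_max, window) {
  vals <- numeric(n_runs)
  nabs <- 0L
  for (r in seq_len(n_runs)) {
    com <- select_committed(H, n_p, scores = scores)
    res <- run_ng(H, com, beta, rule = rule, t_max = t_max, window = window)
    vals[r] <- res$n_A_star
    nabs <- nabs + res$absorbed
  }
  c(median = stats::median(vals), absorbed_fraction = nabs / n_runs)
}

#' Phase scan over agreement probability and committed fraction
#'
#' For every (beta, p) cell, runs `n_runs` independent naming-game
#' realizations (re-selecting the committed set each run) and reports the
#' median stationary fraction n_A*.
#'
#' @param H a [hypergraph()].
#' @param beta_grid,p_grid numeric grids; p is the committed fraction, and
#'   the committed count is `round(p * N)`.
#' @param rule `"union"` or `"unanimity"`.
#' @param scores optional named scores for centrality-based seeding
#'   (see [select_committed()]); `NULL` for random seeding.
#' @param n_runs realizations per cell (default 200).
#' @param t_max,window passed to [run_ng()].
#' @param seed optional integer seed.
#' @return data.frame `(beta, p, median_nA_star, absorbed_fraction)` with
#'   attribute `takeover_fraction`, the fraction of cells with median
#'   n_A* = 1.
#' @export
phase_scan <- function(H, beta_grid, p_grid, rule = c("union", "unanimity"),
                       scores = NULL, n_runs = 200, t_max = 5e5,
                       window = 5e4, seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(beta_grid) > 0, length(p_grid) > 0)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(beta = beta_grid, p = p_grid)
  res <- t(mapply(function(b, p)
    ng_cell(H, b, round(p * H$N), rule, scores, n_runs, t_max, window),
    grid$beta, grid$p))
  out <- data.frame(beta = grid$beta, p = grid$p,
                    median_nA_star = res[, "median"],
                    absorbed_fraction = res[, "absorbed_fraction"])
  attr(out, "takeover_fraction") <- mean(out$median_nA_star == 1)
  out
}

#' Critical committed mass at fixed agreement probability
#'
#' Scans an ascending grid of committed fractions p and returns the smallest
#' one whose median stationary fraction equals 1 (population-wide takeover).
#'
#' @inheritParams phase_scan
#' @param beta agreement probability.
#' @param p_grid ascending grid of committed fractions.
#' @return the critical mass p_c, or `NA_real_` if no grid value achieves
#'   takeover.
#' @export
critical_mass <- function(H, beta, p_grid, rule = c("union", "unanimity"),
                          scores = NULL, n_runs = 200, t_max = 5e5,
                          window = 5e4, seed = NULL) {
  rule <- match.arg(rule)
  if (is.unsorted(p_grid)) stop("p_grid must be ascending")
  if (!is.null(seed)) set.seed(seed)
  for (p in p_grid) {
    cell <- ng_cell(H, beta, round(p * H$N), rule, scores, n_runs, t_max,
                    window)
    if (cell[["median"]] == 1) return(p)
  }
  NA_real_
}
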