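#' Top-fraction node selection
#'
#' Selects the `ceiling(f * N)` top-ranked nodes of a score vector.  Nodes
#' strictly above the boundary value always enter; ties at the boundary are
#' resolved uniformly at random (seed-controlled), so repeated calls with
#' tied scores sample the tied class uniformly.
#'
#' @param scores named numeric vector.
#' @param f top fraction in `(0, 1]`.
#' @param seed optional integer seed for the tie draw.
#' @return character vector of selected node labels.
#' @export
top_f_nodes <- function(scores, f, seed = NULL) {
  stopifnot(f > 0, f <= 1, length(scores) > 0)
  if (is.null(names(scores))) stop("scores must be named")
  if (!is.null(seed)) set.seed(seed)
  n_top <- ceiling(f * length(scores))
  cut <- sort(scores, decreasing = TRUE)[n_top]
  sure <- names(scores)[scores > cut]
  ties <- names(scores)[scores == cut]
  need <- n_top - length(sure)
  c(sure, if (need < length(ties)) sample(ties, need) else ties)
}

#' Jaccard overlap of two top-fraction node sets
#'
#' Compares the top `ceiling(f * N)` nodes of two rankings over the same
#' node universe: J = |A intersect B| / |A union B|.  Averaging J over
#' simulation replicates yields the mean overlap between a centrality
#' ranking and a dynamical ranking (e.g. by tau/T or R_inf).
#'
#' @param score_a,score_b named numeric vectors over the same node set.
#' @param f top fraction in `(0, 1]`.
#' @param seed optional integer seed for boundary-tie resolution.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard_top_f <- function(score_a, score_b, f, seed = NULL) {
  if (!setequal(names(score_a), names(score_b)))
    stop("score_a and score_b must cover the same node set")
  if (!is.null(seed)) set.seed(seed)
  a <- top_f_nodes(score_a, f)
  b <- top_f_nodes(score_b, f)
  length(intersect(a, b)) / length(union(a, b))
}

#' Average of a metric over the top-fraction nodes of a ranking
#'
#' @param scores named numeric ranking vector.
#' @param metric named numeric vector over the same nodes.
#' @param f top fraction in `(0, 1]`.
#' @param seed optional integer seed for boundary-tie resolution.
#' @return mean of `metric` over the top `ceiling(f * N)` nodes of `scores`.
#' @export
top_f_average <- function(scores, metric, f, seed = NULL) {
  if (!setequal(names(scores), names(metric)))
    stop("scores and metric must cover the same node set")
  top <- top_f_nodes(scores, f, seed = seed)
  if (!length(top)) stop("empty top selection")
  mean(metric[top])
}

#' Pearson and Kendall correlation between two score vectors
#'
#' Standard product-moment correlation and tie-adjusted Kendall rank
#' correlation over the common node set.  A constant vector leaves the
#' affected coefficient `NA`.
#'
#' @param score_a,score_b named numeric vectors (>= 3 common nodes).
#' @return list with elements `pearson` and `kendall`.
#' @export
rank_correlations <- function(score_a, score_b) {
  common <- intersect(names(score_a), names(score_b))
  if (length(common) < 3) stop("need at least 3 common nodes")
  a <- score_a[common]; b <- score_b[common]
  const <- stats::sd(a) == 0 || stats::sd(b) == 0
  list(
    pearson = if (const) NA_real_ else stats::cor(a, b, method = "pearson"),
    kendall = if (const) NA_real_ else stats::cor(a, b, method = "kendall"))
}
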