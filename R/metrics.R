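#' Global clustering coefficient (transitivity)
#'
#' Fraction of connected node triples that are closed:
#' `3 * triangles / connected triples`. Returns 0 for graphs with no
#' connected triple.
#'
#' @param g Undirected `igraph` graph.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  val <- igraph::transitivity(g, type = "global")
  if (is.nan(val)) 0 else val
}

#' Global efficiency
#'
#' Mean of the inverse shortest-path lengths over all ordered node pairs,
#' `E = (1/(n(n-1))) * sum_{i != j} 1/d(i,j)`; disconnected pairs
#' contribute 0.
#'
#' @param g Undirected `igraph` graph with at least 2 vertices.
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  if (igraph::vcount(g) < 2) stop_invalid("efficiency needs n >= 2")
  igraph::global_efficiency(g)
}

#' Normalised degree variance
#'
#' Degree-distribution heterogeneity
#' `V = sum_i (k_i - <k>)^2 / (n m (1 - P))` with `P = 2m/(n(n-1))` the
#' density. The normalisation bounds V by 1 so that networks of different
#' size and density are comparable; V is 0 for any regular graph and
#' undefined for empty or complete graphs.
#'
#' @param g Undirected `igraph` graph.
#' @return V in `[0, 1]`.
#' @export
degree_variance <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  P <- 2 * m / (n * (n - 1))
  if (m == 0 || P >= 1)
    stop_undefined("degree variance is undefined for empty or complete graphs")
  k <- igraph::degree(g)
  sum((k - mean(k))^2) / (n * m * (1 - P))
}

#' Louvain-optimised modularity
#'
#' Runs the Louvain community-detection heuristic `restarts` times (its
#' local moving phase is randomised) and returns the best Newman
#' modularity `Q = sum_c [e_c/m - (d_c/(2m))^2]` together with the
#' partition achieving it.
#'
#' @param g Undirected `igraph` graph with at least one edge.
#' @param restarts Number of independent Louvain runs (best-of).
#' @param seed Integer seed for the restart sequence.
#' @return A list with `Q` (numeric) and `membership` (integer vector of
#'   community labels).
#' @export
modularity_louvain <- function(g, restarts = 10, seed = NULL) {
  if (igraph::ecount(g) == 0)
    stop_undefined("modularity is undefined for empty graphs")
  with_seed_if(seed, {
    best_q <- -Inf
    best_mem <- NULL
    for (i in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        best_mem <- igraph::membership(cl)
      }
    }
    list(Q = best_q, membership = as.integer(best_mem))
  })
}

#' Degree assortativity
#'
#' Pearson correlation of endpoint degrees over the edge list with each
#' link counted in both directions:
#' `r = sum_t (k_t1 - <k>_E)(k_t2 - <k>_E) / sum_t (k_t1 - <k>_E)^2`,
#' where `<k>_E` is the mean degree over edge endpoints (node i counted
#' `k_i` times). Undefined (NA) for regular graphs, whose endpoint degree
#' variance is zero.
#'
#' @param g Undirected `igraph` graph.
#' @return r in `[-1, 1]`, or `NA` when undefined.
#' @export
degree_assortativity <- function(g) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  k <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  k1 <- c(k[el[, 1]], k[el[, 2]])
  k2 <- c(k[el[, 2]], k[el[, 1]])
  mu <- mean(k1)
  den <- sum((k1 - mu)^2)
  if (den == 0) return(NA_real_)
  sum((k1 - mu) * (k2 - mu)) / den
}

#' The five-metric topology vector
#'
#' Bundles the five normalised topology metrics used to compare a model
#' against an observed network: clustering coefficient C, global
#' efficiency E, normalised degree variance V, Louvain modularity Q and
#' degree assortativity r. Metrics that are undefined on the input
#' (V on complete graphs, r on regular graphs) are returned as `NA` and
#' later excluded pairwise from the RMSE.
#'
#' @param g Undirected `igraph` graph.
#' @param restarts Louvain restarts for Q.
#' @param seed Integer seed for the Louvain runs.
#' @return Named numeric vector `c(C, E, V, Q, r)`, possibly with `NA`s.
#' @export
metric_vector <- function(g, restarts = 10, seed = NULL) {
  V <- tryCatch(degree_variance(g), error = function(e) NA_real_)
  Q <- tryCatch(modularity_louvain(g, restarts, seed)$Q,
                error = function(e) NA_real_)
  c(C = clustering_coefficient(g),
    E = global_efficiency(g),
    V = V,
    Q = Q,
    r = degree_assortativity(g))
}

#' RMSE between two metric vectors
#'
#' Root-mean-squared error over the `T` components that are defined in
#' both vectors (normally all five). This is the objective minimised by
#' the grid-search fit.
#'
#' @param observed,model Named numeric vectors as from [metric_vector()].
#' @return Non-negative RMSE.
#' @export
metric_rmse <- function(observed, model) {
  shared <- intersect(names(observed), names(model))
  if (length(shared) == 0) stop_invalid("metric vectors share no components")
  o <- observed[shared]
  mo <- model[shared]
  ok <- !is.na(o) & !is.na(mo)
  if (!any(ok)) stop_invalid("metric vectors share no defined components")
  sqrt(mean((o[ok] - mo[ok])^2))
}

#' Two-sample Kolmogorov-Smirnov comparison of degree samples
#'
#' Computes the KS statistic `D` (sup-distance of empirical CDFs), the
#' z-statistic `z = D * sqrt(n1 n2 / (n1 + n2))`, the normalised effect
#' size `z / sqrt(n/2)` for equal sample sizes (which algebraically
#' equals D), and the asymptotic two-sided p-value. For unequal sizes the
#' effect size falls back to `z / sqrt(n1 n2 / (n1 + n2))` with a warning.
#'
#' @param deg1,deg2 Non-empty numeric samples (typically degree sequences).
#' @return A list with `D`, `z`, `effect_size`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(deg1, deg2) {
  if (length(deg1) == 0 || length(deg2) == 0)
    stop_invalid("both samples must be non-empty")
  n1 <- length(deg1)
  n2 <- length(deg2)
  kt <- suppressWarnings(stats::ks.test(deg1, deg2, exact = FALSE))
  D <- unname(kt$statistic)
  z <- D * sqrt(n1 * n2 / (n1 + n2))
  if (n1 == n2) {
    effect <- z / sqrt(n1 / 2)
  } else {
    warning("unequal sample sizes: effect size normalised by sqrt(n1*n2/(n1+n2))")
    effect <- z / sqrt(n1 * n2 / (n1 + n2))
  }
  list(D = D, z = z, effect_size = effect, p_value = unname(kt$p.value),
       n1 = n1, n2 = n2)
}

#' Classify a KS effect size
#'
#' Bands: `<= 0.2` "no noticeable", `(0.2, 0.5]` "small", above "large".
#'
#' @param effect_size Numeric effect size.
#' @return Character label.
#' @export
effect_size_band <- function(effect_size) {
  ifelse(effect_size <= 0.2, "no noticeable",
         ifelse(effect_size <= 0.5, "small", "large"))
}

#' Sample skewness
#'
#' Moment-based skewness `g1 = m3 / m2^(3/2)` with central sample moments
#' `m2`, `m3`. This is the objective driven to zero by the surface
#' inversion: symmetric samples score 0.
#'
#' @param values Numeric vector with at least 3 values and positive
#'   variance.
#' @return Sample skewness.
#' @export
sample_skewness <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 3) stop_invalid("skewness needs at least 3 values")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) stop_undefined("skewness is undefined for zero-variance samples")
  mean((x - mu)^3) / m2^1.5
}
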