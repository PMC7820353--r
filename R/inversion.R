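#' Rank-matched log-normal fitness estimate
#'
#' Builds an estimated fitness vector for the nodes of a weighted network
#' under the assumption that the ranks of the hidden fitness values align
#' with the ranks of the weighted degrees (the surface factor's effect on
#' degrees is linear, so ranks are preserved). With `mode = "quantile"`
#' (the default) the values are the LN(0, sigma) quantiles at plotting
#' positions `(i - 0.5)/n` — deterministic expected order statistics.
#' With `mode = "random"` they are sorted random LN(0, sigma) draws.
#'
#' @param weighted_degrees Numeric vector of weighted degrees.
#' @param sigma Log-normal shape (> 0).
#' @param mode `"quantile"` or `"random"`.
#' @param seed Integer seed (used by `mode = "random"`).
#' @return An `sd_fitness` vector whose ranks equal the ranks of
#'   `weighted_degrees` (ties kept in first-occurrence order).
#' @export
rank_matched_fitness <- function(weighted_degrees, sigma,
                                 mode = c("quantile", "random"), seed = NULL) {
  mode <- match.arg(mode)
  if (sigma <= 0) stop_invalid("sigma must be positive, got ", sigma)
  n <- length(weighted_degrees)
  sorted_vals <- switch(mode,
    quantile = stats::qlnorm((seq_len(n) - 0.5) / n, meanlog = 0, sdlog = sigma),
    random = with_seed_if(seed, sort(stats::rlnorm(n, meanlog = 0, sdlog = sigma))))
  r <- rank(weighted_degrees, ties.method = "first")
  new_fitness(sorted_vals[r], family = "lognormal", mu = 0, sigma = sigma,
              seed = seed)
}

#' Invert a surface factor out of a weighted network
#'
#' Divides each positive weight by the pairwise surface factor:
#' `D_ij = W_ij / (s_i + s_j)` for `W_ij > 0` and 0 elsewhere. If the
#' weights really were built as depth times surface and the true fitness
#' is supplied, the true depth factor is recovered exactly on the extant
#' links.
#'
#' @param W Symmetric non-negative weight matrix (zero diagonal), or a
#'   `weighted_network` object.
#' @param fitness Positive fitness vector of matching length.
#' @return Symmetric depth-estimate matrix, zero exactly where `W` is zero.
#' @export
invert_surface <- function(W, fitness) {
  w <- weight_matrix(W)
  s <- as.numeric(fitness)
  if (length(s) != nrow(w)) stop_invalid("fitness length must match the matrix size")
  if (any(s <= 0)) stop_invalid("fitness values must be positive")
  D <- w / outer(s, s, "+")
  D[w == 0] <- 0
  D
}

#' Estimate the surface shape parameter by skewness minimisation
#'
#' The core of depth-factor recovery. Euclidean distances in a
#' higher-dimensional latent space are approximately normally distributed
#' (hence nearly unskewed), while observed network weights are strongly
#' right-skewed; the skew is attributed to the log-normal surface factor.
#' For each sigma on a coarse-to-fine grid, a rank-matched LN(0, sigma)
#' fitness is inverted out of the weights and the sample skewness of the
#' surviving (positive) inverted weights is recorded; the estimate
#' `sigma_star` is the grid point with smallest absolute skewness,
#' resolved to two decimal places.
#'
#' @param W Symmetric non-negative weight matrix or `weighted_network`.
#' @param sigma_max Upper end of the sigma grid (default 2).
#' @param coarse_step,fine_step Grid steps for the two passes (defaults
#'   0.05 and 0.01; the fine pass covers +/- `coarse_step` around the
#'   coarse optimum).
#' @param mode Fitness construction mode, see [rank_matched_fitness()];
#'   `"random"` averages the skewness over `random_draws` draws per sigma.
#' @param random_draws Draws per sigma for `mode = "random"` (default 10).
#' @param seed Integer seed (only used by `mode = "random"`).
#' @return An object of class `sd_inversion`: list with `sigma_star`,
#'   `skew_trace` (data frame sigma/skewness), `depth_estimate` (matrix),
#'   `fitness_estimate`, and `raw_skewness` of the untouched weights.
#' @export
estimate_surface_sigma <- function(W, sigma_max = 2, coarse_step = 0.05,
                                   fine_step = 0.01,
                                   mode = c("quantile", "random"),
                                   random_draws = 10, seed = NULL) {
  mode <- match.arg(mode)
  w <- weight_matrix(W)
  nz <- upper.tri(w) & w > 0
  if (length(unique(w[nz])) < 3)
    stop_undefined("weight matrix needs at least 3 distinct positive weights")
  wdeg <- rowSums(w)

  skew_at <- function(sigma) {
    one <- function(s_seed) {
      s <- rank_matched_fitness(wdeg, sigma, mode = mode, seed = s_seed)
      d <- w[nz] / (outer(s, s, "+")[nz])
      sample_skewness(d)
    }
    if (mode == "quantile") one(NULL)
    else mean(vapply(seq_len(random_draws), function(i)
      one(derive_seed(seed, round(sigma * 1000), i)), numeric(1)))
  }

  coarse <- round(seq(coarse_step, sigma_max, by = coarse_step), 10)
  sk1 <- vapply(coarse, skew_at, numeric(1))
  s1 <- coarse[which.min(abs(sk1))]

  fine <- round(seq(max(fine_step, s1 - coarse_step),
                    min(sigma_max, s1 + coarse_step), by = fine_step), 2)
  fine <- setdiff(fine, coarse)
  sk2 <- vapply(fine, skew_at, numeric(1))

  trace <- data.frame(sigma = c(coarse, fine), skewness = c(sk1, sk2))
  trace <- trace[order(trace$sigma), ]
  rownames(trace) <- NULL
  sigma_star <- round(trace$sigma[which.min(abs(trace$skewness))], 2)

  fit_star <- rank_matched_fitness(wdeg, sigma_star, mode = mode,
                                   seed = if (mode == "random")
                                     derive_seed(seed, round(sigma_star * 1000), 1)
                                   else NULL)
  structure(list(
    sigma_star = sigma_star,
    skew_trace = trace,
    depth_estimate = invert_surface(w, fit_star),
    fitness_estimate = fit_star,
    raw_skewness = sample_skewness(w[nz]),
    mode = mode
  ), class = "sd_inversion")
}

#' @export
print.sd_inversion <- function(x, ...) {
  cat("Surface inversion (", x$mode, " fitness)\n", sep = "")
  cat("  sigma* =", format(x$sigma_star, nsmall = 2),
      "  |skewness| at optimum =",
      format(min(abs(x$skew_trace$skewness)), digits = 4),
      "  raw weight skewness =", format(x$raw_skewness, digits = 4), "\n")
  invisible(x)
}

#' Weighted-degree inversion baseline
#'
#' The model-free baseline for surface removal: each weight is divided by
#' the mean weighted degree of its endpoints,
#' `H_ij = 2 W_ij / (sum_k W_ik + sum_k W_jk)`. Invariant under global
#' rescaling of `W`.
#'
#' @param W Symmetric non-negative weight matrix or `weighted_network`;
#'   every node must have positive weighted degree.
#' @return Symmetric matrix `H`.
#' @export
weighted_degree_inversion <- function(W) {
  w <- weight_matrix(W)
  wdeg <- rowSums(w)
  if (any(wdeg == 0))
    stop_invalid("node(s) with zero weighted degree: ",
                 paste(which(wdeg == 0), collapse = ", "))
  H <- 2 * w / outer(wdeg, wdeg, "+")
  diag(H) <- 0
  H
}

#' Geometric-congruence assessment of a K-nearest-neighbour graph
#'
#' Builds the KNN graph of a candidate weight matrix (typically a
#' recovered depth factor) and measures how geometrically congruent it
#' is. Reported statistics, each computed only when its inputs are
#' supplied:
#' \itemize{
#'   \item `link_overlap`: fraction of the candidate KNN links also
#'     present in the KNN graph of the coordinate geometry (needs `coords`).
#'   \item `nmi`: normalised mutual information between the Louvain
#'     modules of the candidate KNN graph and of the coordinate KNN graph
#'     (needs `coords`).
#'   \item `pair_symmetry`: fraction of supplied homologous node pairs
#'     (e.g. mirrored brain regions) whose members fall in the same
#'     module (needs `pairs`).
#'   \item `mean_max_module_distance`: average over modules of the
#'     largest within-module coordinate distance (needs `coords`).
#'   \item `same_label_fraction`: fraction of KNN links whose endpoints
#'     share a label (needs `labels`).
#'   \item `hub_occupancy`: fraction of the `n * K` directed NN slots
#'     occupied by the `hubs` nodes of largest reference weighted degree,
#'     with the analytic uniform-chance expectation `hubs / n` reported
#'     alongside.
#' }
#'
#' @param candidate Symmetric non-negative weight matrix to assess.
#' @param reference Weight matrix whose weighted degrees define the hubs
#'   (defaults to `candidate`).
#' @param k Neighbours per node (default 5).
#' @param coords Optional `n x d` coordinate matrix.
#' @param labels Optional length-n label vector.
#' @param pairs Optional two-column matrix/data frame of homologous node
#'   index pairs.
#' @param hubs Number of top-weighted-degree nodes treated as hubs
#'   (default 5).
#' @param louvain_restarts Louvain restarts for module detection.
#' @param seed Integer seed for the Louvain runs.
#' @return A list of class `sd_congruence` with the statistics above
#'   (absent inputs give `NULL` entries), plus `k`, `n`, and `membership`
#'   of the candidate KNN graph.
#' @export
assess_depth_recovery <- function(candidate, reference = candidate, k = 5,
                                  coords = NULL, labels = NULL, pairs = NULL,
                                  hubs = 5, louvain_restarts = 10, seed = 1) {
  w <- weight_matrix(candidate)
  n <- nrow(w)
  g <- knn_graph(w, k)
  mem <- modularity_louvain(g, restarts = louvain_restarts,
                            seed = derive_seed(seed, 1))$membership

  out <- list(k = k, n = n, membership = mem)

  sel <- knn_selections(w, k)
  ref <- weight_matrix(reference)
  hub_ids <- order(rowSums(ref), decreasing = TRUE)[seq_len(hubs)]
  slots <- unlist(sel)
  out$hub_occupancy <- mean(slots %in% hub_ids)
  out$hub_occupancy_expected <- hubs / n

  if (!is.null(coords)) {
    cd <- as.matrix(stats::dist(as.matrix(coords)))
    geo_w <- exp(-cd)
    diag(geo_w) <- 0
    g_geo <- knn_graph(geo_w, k)
    ec <- igraph::as_edgelist(g, names = FALSE)
    eg <- igraph::as_edgelist(g_geo, names = FALSE)
    key <- function(e) (pmin(e[, 1], e[, 2]) - 1) * n + pmax(e[, 1], e[, 2])
    out$link_overlap <- mean(key(ec) %in% key(eg))
    mem_geo <- modularity_louvain(g_geo, restarts = louvain_restarts,
                                  seed = derive_seed(seed, 2))$membership
    out$nmi <- igraph::compare(mem, mem_geo, method = "nmi")
    out$mean_max_module_distance <- mean(vapply(
      split(seq_len(n), mem),
      function(ix) if (length(ix) < 2) 0 else max(cd[ix, ix]),
      numeric(1)))
  }

  if (!is.null(labels)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    out$same_label_fraction <- mean(labels[el[, 1]] == labels[el[, 2]])
  }

  if (!is.null(pairs)) {
    p <- as.matrix(pairs)
    out$pair_symmetry <- mean(mem[p[, 1]] == mem[p[, 2]])
  }

  class(out) <- "sd_congruence"
  out
}

#' Write a congruence report to JSON
#'
#' @param report An `sd_congruence` list from [assess_depth_recovery()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_congruence_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
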