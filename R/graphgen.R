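#' Binarise a weight matrix into a graph with exactly m links
#'
#' Selects `m` links from the pairwise weights. With
#' `ensure_min_degree = TRUE` (the default, matching how models are built
#' for real networks) the selection proceeds in two steps: first the
#' nearest neighbour of every node (its single maximum-weight incident
#' pair) is included, so no node is isolated; the remaining budget is then
#' filled with the globally heaviest weights not yet chosen. With
#' `ensure_min_degree = FALSE` the `m` heaviest pairs are taken outright.
#'
#' Ties in weight are broken by (smaller node id, larger node id) for
#' reproducibility; with continuous weights ties have measure zero.
#'
#' @param weights Symmetric non-negative `n x n` matrix (zero diagonal).
#' @param m Number of links, `1 <= m <= n(n-1)/2`.
#' @param ensure_min_degree Guarantee minimum degree 1 (see Details).
#' @return An undirected `igraph` graph with exactly `n` vertices and `m`
#'   edges.
#' @export
binarize_top_m <- function(weights, m, ensure_min_degree = TRUE) {
  w <- as.matrix(weights)
  n <- nrow(w)
  mmax <- n * (n - 1) / 2
  if (m < 1 || m > mmax)
    stop_invalid("m must be in [1, ", mmax, "], got ", m)

  ut <- upper.tri(w)
  pi_ <- row(w)[ut]
  pj <- col(w)[ut]
  wv <- w[ut]
  ord <- order(-wv, pi_, pj)
  key_sorted <- (pi_[ord] - 1) * n + pj[ord]

  if (ensure_min_degree) {
    ww <- w
    diag(ww) <- -Inf
    nn <- max.col(ww, ties.method = "first")
    a <- pmin(seq_len(n), nn)
    b <- pmax(seq_len(n), nn)
    nn_keys <- unique((a - 1) * n + b)
    u <- length(nn_keys)
    if (m < u)
      stop_invalid("m = ", m, " is below the ", u,
                   " links needed for minimum degree 1; smallest feasible m is ", u)
    rest <- key_sorted[!(key_sorted %in% nn_keys)]
    chosen <- c(nn_keys, rest[seq_len(m - u)])
  } else {
    chosen <- key_sorted[seq_len(m)]
  }

  ei <- (chosen - 1) %/% n + 1
  ej <- (chosen - 1) %% n + 1
  o <- order(ei, ej)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, rbind(ei[o], ej[o]))
}

#' Generate a surface-depth model network
#'
#' End-to-end generation: sample latent coordinates, compute the depth
#' factor, sample node fitness, compute the surface factor, combine them
#' into link weights `w_ij = d_ij (s_i + s_j)`, and keep the `m` heaviest
#' weights subject to minimum degree 1. The model has two free parameters:
#' the latent dimension `q` and the fitness shape (`sigma` for log-normal
#' fitness, `gamma` for the power-law comparator).
#'
#' @param n Number of nodes.
#' @param m Number of links.
#' @param q Latent-space dimension (>= 2 for spherical geometry).
#' @param sigma Log-normal shape parameter (used when
#'   `surface_family = "lognormal"`).
#' @param gamma Power-law exponent (used when `surface_family = "powerlaw"`).
#' @param surface_family `"lognormal"` (the proposed theory) or
#'   `"powerlaw"` (scale-free fitness comparator).
#' @param geometry `"hypercube"` (Euclidean depth factor) or `"sphere"`
#'   (spherical-surface comparator).
#' @param mu Log-normal location, default 0 (a pure scale factor).
#' @param seed Integer master seed; coordinate and fitness draws use
#'   child seeds derived from it.
#' @return An undirected `igraph` graph with `n` vertices, `m` edges and
#'   minimum degree 1, carrying a `sd_params` graph attribute recording
#'   the generating parameters.
#' @export
generate_surface_depth <- function(n, m, q, sigma = NULL, gamma = NULL,
                                   surface_family = c("lognormal", "powerlaw"),
                                   geometry = c("hypercube", "sphere"),
                                   mu = 0, seed = NULL) {
  surface_family <- match.arg(surface_family)
  geometry <- match.arg(geometry)
  cseed <- if (is.null(seed)) NULL else derive_seed(seed, 11)
  fseed <- if (is.null(seed)) NULL else derive_seed(seed, 12)

  coords <- switch(geometry,
    hypercube = sample_hypercube_coords(n, q, cseed),
    sphere = sample_sphere_coords(n, q, cseed))
  depth <- switch(geometry,
    hypercube = euclidean_depth(coords),
    sphere = spherical_depth(coords))
  fitness <- switch(surface_family,
    lognormal = {
      if (is.null(sigma)) stop_invalid("lognormal surface family needs `sigma`")
      sample_lognormal_fitness(n, sigma = sigma, mu = mu, seed = fseed)
    },
    powerlaw = {
      if (is.null(gamma)) stop_invalid("powerlaw surface family needs `gamma`")
      sample_powerlaw_fitness(n, gamma = gamma, seed = fseed)
    })
  w <- combine_factors(depth, surface_pair_matrix(fitness))
  g <- binarize_top_m(w, m, ensure_min_degree = TRUE)
  igraph::graph_attr(g, "sd_params") <- list(
    n = n, m = m, q = q, sigma = sigma, gamma = gamma,
    surface_family = surface_family, geometry = geometry,
    mu = mu, seed = seed)
  g
}

# Per-node top-K neighbour selections from a weight matrix: a list of K
# (or fewer, if a node has fewer positive weights) neighbour indices per
# node, heaviest first. Zero-weight pairs are never selected.
knn_selections <- function(w, k) {
  n <- nrow(w)
  lapply(seq_len(n), function(i) {
    wi <- w[i, ]
    wi[i] <- 0
    pos <- which(wi > 0)
    if (length(pos) == 0) return(integer(0))
    pos[order(-wi[pos], pos)][seq_len(min(k, length(pos)))]
  })
}

#' K-nearest-neighbour graph of a weight matrix
#'
#' Each node contributes links to its `K` largest-weight neighbours; the
#' union over nodes is taken (a link exists if either endpoint selects
#' it). Zero-weight pairs are never selected, so nodes with fewer than `K`
#' positive weights contribute only their positive-weight links. The 5NN
#' graph (`k = 5`) is the standard probe for geometric congruence of
#' recovered depth factors.
#'
#' @param weights Symmetric non-negative `n x n` matrix, zero diagonal.
#' @param k Number of neighbours per node, `1 <= k <= n - 1`.
#' @return An undirected `igraph` graph on `n` vertices.
#' @export
knn_graph <- function(weights, k) {
  w <- as.matrix(weights)
  n <- nrow(w)
  if (k < 1 || k >= n) stop_invalid("k must be in [1, n-1], got ", k)
  sel <- knn_selections(w, k)
  ei <- rep(seq_len(n), lengths(sel))
  ej <- unlist(sel)
  if (length(ej) == 0) return(igraph::make_empty_graph(n, directed = FALSE))
  a <- pmin(ei, ej)
  b <- pmax(ei, ej)
  keys <- unique((a - 1) * n + b)
  i1 <- (keys - 1) %/% n + 1
  j1 <- (keys - 1) %% n + 1
  o <- order(i1, j1)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, rbind(i1[o], j1[o]))
}
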