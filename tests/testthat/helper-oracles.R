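# Independent reference implementations used as oracles, deliberately
# naive: breadth-first search over the adjacency matrix and exhaustive
# triple counting. They never call the package's metric code.

graph_from_edges <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# All-pairs shortest paths by BFS on a 0/1 adjacency matrix.
naive_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1))))
      nxt <- nxt[is.infinite(D[s, nxt])]
      D[s, nxt] <- dist
      frontier <- nxt
    }
  }
  D
}

naive_efficiency <- function(A) {
  n <- nrow(A)
  D <- naive_shortest_paths(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

naive_clustering <- function(A) {
  triangles <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(choose(rowSums(A), 2)) # paths of length 2, centre by centre
  if (triples == 0) return(0)
  3 * triangles / triples
}

# Exhaustive min-degree-1 top-weight m-subset (oracle for binarize_top_m).
brute_force_top_m <- function(w, m) {
  n <- nrow(w)
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  combs <- utils::combn(nrow(pairs), m)
  best <- NULL
  best_w <- -Inf
  for (c_ in seq_len(ncol(combs))) {
    sel <- pairs[combs[, c_], , drop = FALSE]
    deg <- tabulate(c(sel[, 1], sel[, 2]), nbins = n)
    if (any(deg == 0)) next
    tw <- sum(w[sel])
    if (tw > best_w) {
      best_w <- tw
      best <- sel
    }
  }
  list(edges = best, weight = best_w)
}

edge_key_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  sort((pmin(el[, 1], el[, 2]) - 1) * n + pmax(el[, 1], el[, 2]))
}

random_weight_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2)
    w + t(w)
  })
}
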