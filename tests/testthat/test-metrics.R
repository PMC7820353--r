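triangle <- function() graph_from_edges(3, c(1,2, 2,3, 3,1))
path3 <- function() graph_from_edges(3, c(1,2, 2,3))
star_graph <- function(n) graph_from_edges(n, rbind(1, 2:n))
two_triangles <- function() graph_from_edges(6, c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4))

test_that("clustering coefficient matches closed forms", {
  expect_equal(clustering_coefficient(triangle()), 1)
  expect_equal(clustering_coefficient(path3()), 0)
  expect_equal(clustering_coefficient(igraph::make_full_graph(4)), 1)
})

test_that("global efficiency matches closed forms", {
  expect_equal(global_efficiency(igraph::make_full_graph(5)), 1)
  expect_equal(global_efficiency(path3()), 5 / 6)
  expect_equal(global_efficiency(graph_from_edges(4, c(1,2, 3,4))), 1 / 3)
})

test_that("degree variance matches its closed forms", {
  expect_equal(degree_variance(igraph::make_ring(8)), 0) # regular
  expect_equal(degree_variance(star_graph(4)), 0.5)
  for (n in c(4, 10, 25, 50)) {
    expect_equal(degree_variance(star_graph(n)), (n - 2) / n)
  }
  expect_error(degree_variance(igraph::make_full_graph(5)),
               class = "surfacedepth_undefined_value")
  expect_error(degree_variance(igraph::make_empty_graph(4, directed = FALSE)),
               class = "surfacedepth_undefined_value")
})

test_that("Louvain modularity finds planted structure", {
  res <- modularity_louvain(two_triangles(), restarts = 5, seed = 1)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  expect_gte(modularity_louvain(igraph::make_full_graph(5), seed = 1)$Q, 0)

  # two 5-cliques joined by one bridge: the cliques are recovered
  g <- igraph::add_edges(
    igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5)),
    c(1, 6))
  hits <- sum(vapply(1:10, function(i) {
    mem <- modularity_louvain(g, restarts = 1, seed = i)$membership
    length(unique(mem)) == 2 &&
      length(unique(mem[1:5])) == 1 && length(unique(mem[6:10])) == 1
  }, logical(1)))
  expect_gte(hits, 9)
})

test_that("modularity is non-decreasing in the number of restarts", {
  g <- generate_surface_depth(80, 300, 3, sigma = 0.6, seed = 2)
  q1 <- modularity_louvain(g, restarts = 1, seed = 7)$Q
  q5 <- modularity_louvain(g, restarts = 5, seed = 7)$Q
  q10 <- modularity_louvain(g, restarts = 10, seed = 7)$Q
  expect_lte(q1, q5 + 1e-12)
  expect_lte(q5, q10 + 1e-12)
})

test_that("assortativity matches hand values and flags regular graphs", {
  expect_equal(degree_assortativity(path3()), -1)
  expect_equal(degree_assortativity(star_graph(4)), -1)
  expect_true(is.na(degree_assortativity(igraph::make_ring(6)))) # 2-regular
})

test_that("assortativity agrees with independent correlation routines", {
  for (seed in 1:5) {
    g <- generate_surface_depth(80, 400, 3, sigma = 0.5, seed = 700 + seed)
    r <- degree_assortativity(g)
    expect_gte(r, -1); expect_lte(r, 1)
    expect_equal(r, igraph::assortativity_degree(g), tolerance = 1e-12)
    k <- igraph::degree(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    expect_equal(r, stats::cor(c(k[el[,1]], k[el[,2]]), c(k[el[,2]], k[el[,1]])),
                 tolerance = 1e-12)
  }
})

test_that("efficiency and clustering agree with naive oracles on the atlas", {
  # every connected graph on at most 6 nodes from the graph atlas
  checked <- 0
  for (i in 1:208) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) < 3 || !igraph::is_connected(g)) next
    A <- adjacency_of(g)
    expect_equal(global_efficiency(g), naive_efficiency(A), tolerance = 1e-12)
    expect_equal(clustering_coefficient(g), naive_clustering(A), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("metric_vector bundles the five metrics with undefined flags", {
  mv <- metric_vector(two_triangles(), restarts = 5, seed = 1)
  expect_named(mv, c("C", "E", "V", "Q", "r"))
  expect_equal(unname(mv["C"]), 1)
  expect_equal(unname(mv["V"]), 0)
  expect_equal(unname(mv["Q"]), 0.5)
  expect_true(is.na(mv["r"])) # 2-regular
  mk <- metric_vector(igraph::make_full_graph(5), seed = 1)
  expect_equal(unname(mk["C"]), 1)
  expect_equal(unname(mk["E"]), 1)
  expect_true(is.na(mk["V"]))
  expect_true(is.na(mk["r"]))
  g <- generate_surface_depth(50, 150, 2, sigma = 0.4, seed = 3)
  expect_identical(metric_vector(g, restarts = 3, seed = 9),
                   metric_vector(g, restarts = 3, seed = 9))
})

test_that("metric RMSE averages over shared defined components", {
  a <- c(C = 1, E = 0.5, V = 0.2, Q = 0.4, r = -0.1)
  expect_equal(metric_rmse(a, a), 0)
  b <- a; b["C"] <- 0
  expect_equal(metric_rmse(a, b), sqrt(1 / 5))
  a2 <- a; b2 <- b
  a2["r"] <- NA; b2["r"] <- NA
  expect_equal(metric_rmse(a2, b2), sqrt(1 / 4)) # T = 4 averaging
  expect_error(metric_rmse(c(C = NA_real_), c(C = NA_real_)),
               class = "surfacedepth_invalid_argument")
})

test_that("KS comparison reproduces identities", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_two_sample(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$effect_size, 0)
  expect_equal(same$p_value, 1)
  disj <- ks_two_sample(1:5, 11:15)
  expect_equal(disj$D, 1)
  expect_equal(disj$effect_size, 1)
  for (seed in 1:5) {
    s <- withr::with_seed(seed, list(a = rpois(40, 8), b = rpois(40, 10)))
    ks <- ks_two_sample(s$a, s$b)
    expect_equal(ks$effect_size, ks$D, tolerance = 1e-12) # equal sizes
  }
  expect_warning(ks_two_sample(1:10, 1:20), "unequal")
})

test_that("sample skewness matches hand values and odd symmetry", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  expect_equal(sample_skewness(c(0, 0, 1)), sqrt(2) / 2)
  x <- withr::with_seed(3, rexp(200))
  expect_equal(sample_skewness(-x), -sample_skewness(x))
  expect_equal(sample_skewness(2 * x + 5), sample_skewness(x), tolerance = 1e-12)
  expect_error(sample_skewness(rep(1, 5)), class = "surfacedepth_undefined_value")
  expect_error(sample_skewness(c(1, 2)), class = "surfacedepth_invalid_argument")
})

test_that("effect size bands follow the reporting convention", {
  expect_equal(effect_size_band(c(0.1, 0.2, 0.35, 0.5, 0.9)),
               c("no noticeable", "no noticeable", "small", "small", "large"))
})
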