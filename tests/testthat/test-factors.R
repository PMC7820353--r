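test_that("coordinate samplers are deterministic and respect their supports", {
  a <- sample_hypercube_coords(3, 2, seed = 17)
  b <- sample_hypercube_coords(3, 2, seed = 17)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), c(3, 2))

  s1 <- sample_sphere_coords(2, 2, seed = 5)
  s2 <- sample_sphere_coords(2, 2, seed = 5)
  expect_identical(unclass(s1), unclass(s2))
  s <- sample_sphere_coords(500, 4, seed = 9)
  expect_true(all(abs(sqrt(rowSums(s^2)) - 1) < 1e-12))

  expect_error(sample_hypercube_coords(1, 2, 1), class = "surfacedepth_invalid_argument")
  expect_error(sample_hypercube_coords(3, 0, 1), class = "surfacedepth_invalid_argument")
  expect_error(sample_sphere_coords(5, 1, 1), class = "surfacedepth_invalid_argument")
})

test_that("coordinate samplers have the right first moments at large n", {
  x <- sample_hypercube_coords(10000, 1, seed = 3)
  expect_lt(abs(mean(x) - 0.5), 0.01)
  s <- sample_sphere_coords(10000, 3, seed = 4)
  expect_true(all(abs(colMeans(s)) < 0.02))
})

test_that("Euclidean depth matches closed forms and stays in (0, 1]", {
  co <- structure(matrix(c(0, 0, 1), ncol = 1), space = "hypercube",
                  class = "sd_coords")
  d <- euclidean_depth(co)
  expect_equal(d[1, 2], 1)              # coincident points
  expect_equal(d[1, 3], exp(-1))
  co2 <- structure(rbind(c(0, 0), c(1, 1)), space = "hypercube",
                   class = "sd_coords")
  expect_equal(euclidean_depth(co2)[1, 2], exp(-sqrt(2)))

  dd <- euclidean_depth(sample_hypercube_coords(40, 3, seed = 1))
  expect_identical(unclass(dd), t(unclass(dd)))
  off <- dd[upper.tri(dd)]
  expect_true(all(off > 0 & off <= 1))
  expect_true(all(diag(dd) == 0))
})

test_that("spherical depth uses the clamped great-circle distance", {
  co <- structure(rbind(c(1, 0), c(1, 0), c(-1, 0), c(0, 1)),
                  space = "sphere", class = "sd_coords")
  d <- spherical_depth(co)
  expect_equal(d[1, 2], 1)              # identical unit vectors
  expect_equal(d[1, 3], exp(-pi))       # antipodal
  expect_equal(d[1, 4], exp(-pi / 2))   # orthogonal
  # rounding just outside [-1, 1] must not produce NaN
  co2 <- structure(rbind(c(1, 1e-16), c(1, -1e-16)) /
                     sqrt(1 + 1e-32), space = "sphere", class = "sd_coords")
  expect_false(anyNA(spherical_depth(co2)))
})

test_that("log-normal fitness sampling matches its distribution", {
  expect_equal(as.numeric(sample_lognormal_fitness(5, sigma = 0, seed = 1)),
               rep(1, 5))
  s <- sample_lognormal_fitness(50000, sigma = 0.5, seed = 2)
  expect_lt(abs(mean(s) / exp(0.125) - 1), 0.02) # mean exp(mu + sigma^2/2)
  expect_gt(sample_skewness(as.numeric(s)), 0)
  expect_error(sample_lognormal_fitness(5, sigma = -1),
               class = "surfacedepth_invalid_argument")
})

test_that("power-law fitness is Pareto with minimum 1", {
  u <- withr::with_seed(11, runif(1000))
  s <- sample_powerlaw_fitness(1000, gamma = 2, seed = 11)
  expect_equal(as.numeric(s), u^(-1)) # inverse CDF at gamma = 2
  expect_true(all(s >= 1))
  s3 <- sample_powerlaw_fitness(100000, gamma = 3, seed = 12)
  expect_lt(abs(mean(s3) / 2 - 1), 0.05) # Pareto mean (gamma-1)/(gamma-2)
  expect_error(sample_powerlaw_fitness(10, gamma = 1),
               class = "surfacedepth_invalid_argument")
  expect_warning(sample_powerlaw_fitness(10, gamma = 3.5, seed = 1),
                 "outside")
})

test_that("surface pair matrix is the pairwise fitness sum", {
  w <- surface_pair_matrix(c(1, 2, 3))
  expect_equal(w[1, 2], 3)
  expect_equal(w[1, 3], 4)
  expect_equal(w[2, 3], 5)
  expect_true(all(diag(w) == 0))
  wc <- surface_pair_matrix(rep(2.5, 4))
  expect_true(all(wc[upper.tri(wc)] == 5))
})

test_that("pair-sum row identity is exactly linear in s_i", {
  for (seed in 1:5) {
    s <- as.numeric(sample_lognormal_fitness(30, sigma = 0.8, seed = seed))
    w <- surface_pair_matrix(s)
    rows <- rowSums(w)
    expected <- (length(s) - 2) * s + sum(s)
    expect_equal(rows, expected, tolerance = 1e-9)
  }
})

test_that("combining factors multiplies entries without normalisation", {
  d <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  s <- surface_pair_matrix(c(1, 3))
  w <- combine_factors(d, s)
  expect_equal(w[1, 2], 2.0)
  ones <- matrix(1, 3, 3); diag(ones) <- 0
  sv <- surface_pair_matrix(c(1, 2, 3))
  expect_equal(combine_factors(ones, sv), sv, ignore_attr = TRUE)
  halves <- surface_pair_matrix(rep(0.5, 3))
  dd <- euclidean_depth(sample_hypercube_coords(3, 2, seed = 1))
  expect_equal(combine_factors(dd, halves), dd, ignore_attr = TRUE)
  expect_error(combine_factors(matrix(0, 2, 2), surface_pair_matrix(1:3)),
               class = "surfacedepth_invalid_argument")
})

test_that("log-normal sum parameters match the moment-matching formulas", {
  p0 <- lognormal_sum_params(0, 0)
  expect_equal(p0$sigma_hat, 0)
  expect_equal(p0$mu_hat, log(2)) # sum of two constants 1 is the constant 2
  p1 <- lognormal_sum_params(0, 1)
  expect_equal(p1$sigma_hat^2, log((exp(1) + 1) / 2), tolerance = 1e-12)
  expect_equal(p1$sigma_hat^2, 0.620114, tolerance = 1e-6)
  expect_equal(p1$mu_hat, 0.883090, tolerance = 1e-6)
})

test_that("sums of log-normals are close to the approximating log-normal", {
  p <- lognormal_sum_params(0, 0.5)
  z <- withr::with_seed(21, rlnorm(1e5, 0, 0.5) + rlnorm(1e5, 0, 0.5))
  ref <- withr::with_seed(22, rlnorm(1e5, p$mu_hat, p$sigma_hat))
  D <- suppressWarnings(stats::ks.test(z, ref)$statistic)
  expect_lt(unname(D), 0.02)
})

test_that("pairwise distance skewness decays with latent dimension", {
  d1 <- as.numeric(dist(unclass(sample_hypercube_coords(2000, 1, seed = 31))))
  d10 <- as.numeric(dist(unclass(sample_hypercube_coords(2000, 10, seed = 31))))
  expect_lt(abs(sample_skewness(d10)), abs(sample_skewness(d1)))
})

test_that("log-normal upper tail straightens on a log-log histogram", {
  x <- withr::with_seed(1, rlnorm(1e6, 0, 1))
  p <- 1 - 10^-seq(1, 4, by = 0.5)
  cuts <- quantile(x, p)
  dens <- diff(p) * 1e6 / diff(cuts)
  mids <- sqrt(head(cuts, -1) * tail(cuts, -1))
  slopes <- diff(log(dens)) / diff(log(mids))
  expect_true(all(diff(slopes) < 0)) # concave: slope steepens monotonically
  frac <- abs(diff(slopes)) / abs((head(slopes, -1) + tail(slopes, -1)) / 2)
  expect_gt(frac[1], frac[length(frac)]) # ...but at a shrinking relative rate
})
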