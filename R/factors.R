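#' Sample latent hypercube coordinates
#'
#' Draws `n` points i.i.d. uniform on the unit hypercube `[0,1]^q`. These
#' are the raw material of the depth factor: nodes that land close together
#' in the latent space are "similar" and more likely to link.
#'
#' @param n Number of nodes (>= 2).
#' @param q Latent dimension (>= 1).
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @return A numeric `n x q` matrix of class `sd_coords` with attributes
#'   `space = "hypercube"` and `seed`.
#' @export
sample_hypercube_coords <- function(n, q, seed = NULL) {
  if (n < 2) stop_invalid("n must be >= 2, got ", n)
  if (q < 1) stop_invalid("q must be >= 1, got ", q)
  pts <- with_seed_if(seed, matrix(stats::runif(n * q), nrow = n, ncol = q))
  new_coords(pts, space = "hypercube", seed = seed)
}

#' Sample latent coordinates uniformly on a sphere surface
#'
#' Draws `n` points uniform on the unit sphere S^(q-1) embedded in `q`
#' coordinates, by normalising `q` independent standard normal samples.
#' Used by the spherical-geometry depth-factor comparator.
#'
#' @inheritParams sample_hypercube_coords
#' @param q Embedding dimension (>= 2); every row has unit Euclidean norm.
#' @return An `n x q` matrix of class `sd_coords`, `space = "sphere"`.
#' @export
sample_sphere_coords <- function(n, q, seed = NULL) {
  if (n < 2) stop_invalid("n must be >= 2, got ", n)
  if (q < 2) stop_invalid("sphere coordinates need q >= 2, got ", q)
  pts <- with_seed_if(seed, matrix(stats::rnorm(n * q), nrow = n, ncol = q))
  pts <- pts / sqrt(rowSums(pts^2))
  new_coords(pts, space = "sphere", seed = seed)
}

new_coords <- function(points, space, seed) {
  structure(points,
            space = space,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
            class = c("sd_coords", class(points)))
}

coord_space <- function(coords) {
  sp <- attr(coords, "space")
  if (is.null(sp)) stop_invalid("coordinates carry no `space` attribute; ",
                                "use sample_hypercube_coords()/sample_sphere_coords()")
  sp
}

#' Euclidean depth factor
#'
#' Pairwise similarity `d_ij = exp(-||x_i - x_j||)` from hypercube latent
#' coordinates: the exponentially inverted Euclidean distance, so closer
#' nodes score higher, with values in (0, 1]. The diagonal is fixed at 0
#' so self-pairs can never be selected as links.
#'
#' @param coords An `sd_coords` matrix with `space = "hypercube"`.
#' @return An `n x n` symmetric matrix of class `sd_pairweights`,
#'   `kind = "depth"`.
#' @export
euclidean_depth <- function(coords) {
  if (coord_space(coords) != "hypercube")
    stop_invalid("euclidean_depth() expects hypercube coordinates")
  d <- exp(-as.matrix(stats::dist(unclass(coords))))
  diag(d) <- 0
  new_pairweights(d, kind = "depth")
}

#' Spherical (great-circle) depth factor
#'
#' Pairwise similarity `d_ij = exp(-arccos(<x_i, x_j>))` from unit-sphere
#' coordinates: the exponentially inverted great-circle distance. Inner
#' products are clamped to [-1, 1] before `arccos` to guard against
#' rounding just outside the domain.
#'
#' @param coords An `sd_coords` matrix with `space = "sphere"`.
#' @return An `n x n` symmetric `sd_pairweights` matrix, `kind = "depth"`.
#' @export
spherical_depth <- function(coords) {
  if (coord_space(coords) != "sphere")
    stop_invalid("spherical_depth() expects sphere coordinates")
  x <- unclass(coords)
  ip <- pmin(pmax(tcrossprod(x), -1), 1)
  d <- exp(-acos(ip))
  diag(d) <- 0
  new_pairweights(d, kind = "depth")
}

#' Sample log-normal node fitness (surface factor)
#'
#' Draws `n` fitness values `s_i = exp(x_i)` with `x_i ~ N(mu, sigma)`.
#' The location `mu` only rescales all fitness values and is fixed at 0 by
#' default; `sigma` is the single shape parameter of the surface factor.
#' `sigma = 0` degenerates to the constant `exp(mu)`.
#'
#' @param n Number of nodes.
#' @param sigma Log-scale standard deviation (>= 0).
#' @param mu Log-scale location, default 0.
#' @param seed Integer seed.
#' @return Numeric vector of class `sd_fitness` with attributes `family`,
#'   `mu`, `sigma`, `seed`.
#' @export
sample_lognormal_fitness <- function(n, sigma, mu = 0, seed = NULL) {
  if (sigma < 0) stop_invalid("sigma must be >= 0, got ", sigma)
  v <- with_seed_if(seed, exp(stats::rnorm(n, mean = mu, sd = sigma)))
  new_fitness(v, family = "lognormal", mu = mu, sigma = sigma, seed = seed)
}

#' Sample power-law node fitness
#'
#' Draws `n` fitness values from a continuous Pareto distribution with
#' exponent `gamma` and minimum 1, by inverse-CDF sampling
#' `s = u^(-1/(gamma-1))`, `u ~ U(0,1)`. This is the scale-free fitness
#' comparator; the minimum of 1 keeps values positive and on a scale
#' comparable to `exp(0)`.
#'
#' @param n Number of nodes.
#' @param gamma Power-law exponent; must exceed 1, with a warning outside
#'   the fitting interval `[2, 3]`.
#' @param seed Integer seed.
#' @return Numeric vector of class `sd_fitness` (`family = "powerlaw"`).
#' @export
sample_powerlaw_fitness <- function(n, gamma, seed = NULL) {
  if (gamma <= 1) stop_invalid("gamma must exceed 1 (non-normalisable), got ", gamma)
  if (gamma < 2 || gamma > 3)
    warning("gamma = ", gamma, " lies outside the usual fitting interval [2, 3]")
  v <- with_seed_if(seed, stats::runif(n)^(-1 / (gamma - 1)))
  new_fitness(v, family = "powerlaw", gamma = gamma, seed = seed)
}

new_fitness <- function(values, family, mu = NA_real_, sigma = NA_real_,
                        gamma = NA_real_, seed = NULL) {
  stopifnot(all(values > 0))
  structure(as.numeric(values),
            family = family, mu = mu, sigma = sigma, gamma = gamma,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
            class = "sd_fitness")
}

#' Pairwise surface factor matrix
#'
#' The surface factor of a node pair is the sum of the endpoint fitness
#' values, `s_i + s_j`. The sum (rather than the product) is used because
#' the row sums it induces are exactly linear in `s_i`, which makes the
#' surface factor's effect on degrees tractable and invertible.
#'
#' @param fitness Positive numeric vector (an `sd_fitness` or plain vector).
#' @return An `n x n` symmetric `sd_pairweights` matrix, `kind = "surface"`,
#'   zero diagonal.
#' @export
surface_pair_matrix <- function(fitness) {
  s <- as.numeric(fitness)
  if (length(s) < 2) stop_invalid("need at least 2 fitness values")
  if (any(s <= 0)) stop_invalid("fitness values must be positive")
  w <- outer(s, s, "+")
  diag(w) <- 0
  new_pairweights(w, kind = "surface")
}

#' Combine depth and surface factors into link weights
#'
#' Entry-wise product `w_ij = d_ij * (s_i + s_j)`: link probability is
#' taken proportional to both the similarity of the pair and its combined
#' fitness. Weights are deliberately not normalised — networks are always
#' modelled at the target's exact node and link count, so only the ranks
#' of the weights matter.
#'
#' @param depth `sd_pairweights` of kind `"depth"` (or any symmetric matrix).
#' @param surface `sd_pairweights` of kind `"surface"` (same dimension).
#' @return An `n x n` symmetric `sd_pairweights` matrix, `kind = "combined"`.
#' @export
combine_factors <- function(depth, surface) {
  d <- unclass(depth); s <- unclass(surface)
  if (!all(dim(d) == dim(s)))
    stop_invalid("depth and surface matrices have mismatched dimensions")
  w <- d * s
  diag(w) <- 0
  new_pairweights(w, kind = "combined")
}

new_pairweights <- function(w, kind) {
  structure(w, kind = kind, class = c("sd_pairweights", class(w)))
}

#' Log-normal parameters of a sum of two i.i.d. log-normals
#'
#' The sum of two independent `LN(mu, sigma)` variables is itself well
#' approximated by a log-normal `LN(mu_hat, sigma_hat)` with
#' `sigma_hat^2 = ln((exp(sigma^2) + 1) / 2)` and
#' `mu_hat = mu + ln(2) + (sigma^2 - sigma_hat^2) / 2`
#' (the Fenton-Wilkinson moment-matching approximation). This underpins
#' treating the pairwise surface factor `s_i + s_j` as log-normal.
#'
#' @param mu Log-scale location of the summands.
#' @param sigma Log-scale standard deviation (>= 0).
#' @return A list with components `mu_hat` and `sigma_hat`.
#' @export
lognormal_sum_params <- function(mu, sigma) {
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  sigma_hat2 <- log((exp(sigma^2) + 1) / 2)
  mu_hat <- mu + log(2) + (sigma^2 - sigma_hat2) / 2
  list(mu_hat = mu_hat, sigma_hat = sqrt(sigma_hat2))
}
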