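#' Compare a network's degree distribution against a fitted family
#'
#' Fits the named distribution family to the degree sequence by maximum
#' likelihood, draws a reference sample of the same size from the fit
#' (rounded to integers, as degrees are), and runs the two-sample KS test
#' between the degrees and the reference. Surface-depth models produce
#' degree distributions whose right tail is power-law-like at low density
#' while the full distribution is log-normal-like at moderate density, so
#' the appropriate `family` depends on the density regime.
#'
#' For `family = "powerlaw"` only the tail above `tail_quantile` is
#' compared: the degree floor `kmin` is the `tail_quantile` quantile of
#' the degrees, the exponent is the continuous MLE
#' `1 + n_tail / sum(log(k / (kmin - 0.5)))`, and the reference sample is
#' a rounded Pareto draw. For `family = "lognormal"` the whole degree
#' sequence is used with `meanlog`/`sdlog` fitted from `log(k)`.
#'
#' @param net Undirected `igraph` graph with minimum degree 1.
#' @param family `"powerlaw"` or `"lognormal"`.
#' @param seed Integer seed for the reference draw.
#' @param tail_quantile Tail cut for the power-law comparison (default
#'   0.5, the upper half of the degree distribution).
#' @return A list with `p_value`, `D`, `effect_size`, `family`, the
#'   fitted parameters (`gamma`/`kmin` or `meanlog`/`sdlog`), and the
#'   compared sample size `n`.
#' @export
degree_regime_test <- function(net, family = c("powerlaw", "lognormal"),
                               seed = 1, tail_quantile = 0.5) {
  family <- match.arg(family)
  k <- igraph::degree(net)
  if (any(k < 1)) stop_invalid("degree regime comparison needs minimum degree 1")
  if (family == "powerlaw") {
    kmin <- max(1, unname(stats::quantile(k, tail_quantile)))
    kt <- k[k >= kmin]
    gamma_hat <- 1 + length(kt) / sum(log(kt / (kmin - 0.5)))
    ref <- with_seed_if(seed,
      round((kmin - 0.5) * stats::runif(length(kt))^(-1 / (gamma_hat - 1))))
    ks <- ks_two_sample(kt, ref)
    c(ks[c("p_value", "D", "effect_size")],
      list(family = family, gamma = gamma_hat, kmin = kmin, n = length(kt)))
  } else {
    lk <- log(k)
    ref <- with_seed_if(seed,
      round(stats::rlnorm(length(k), meanlog = mean(lk), sdlog = stats::sd(lk))))
    ref <- pmax(ref, 1)
    ks <- ks_two_sample(k, ref)
    c(ks[c("p_value", "D", "effect_size")],
      list(family = family, meanlog = mean(lk), sdlog = stats::sd(lk),
           n = length(k)))
  }
}
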