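#' Exact moments of the net-outcome distribution
#'
#' Because the four programs are mutually independent, the net cost
#' \eqn{(C_A - C_a) - (C_B - C_b)} is normal with mean
#' \eqn{\mu_C = \Delta C(A) - \Delta C(B)} and variance the *sum* of the four
#' programs' cost variances,
#' \eqn{\sigma^2_C = \sigma^2_{C_A} + \sigma^2_{C_a} + \sigma^2_{C_B} +
#' \sigma^2_{C_b}}; likewise for effects. The net-outcome correlation pools
#' the within-program correlations:
#' \deqn{\rho_{net} = \frac{\sum_j \rho_j \sigma_{C_j} \sigma_{E_j}}
#'                        {\sigma_{E} \, \sigma_{C}}, \quad j \in \{A,a,B,b\}.}
#' Every program enters the numerator with a positive sign: each difference
#' flips the sign of *both* the cost and the effect deviation, so the
#' cross-products survive unchanged.
#'
#' @param scenario A stochastic [reallocation_scenario()].
#' @return An object of class `dmp_moments`: `mu_effect` (LY), `mu_cost`
#'   (kUSD), `var_effect`, `var_cost`, `rho` (net-outcome correlation; `NA`
#'   with a warning if either axis has zero total variance).
#' @export
#' @examples
#' dmp_moments(demo_scenario("variance_decreasing"))
dmp_moments <- function(scenario) {
  stopifnot(inherits(scenario, "dmp_scenario"))
  if (!scenario$stochastic) {
    stop("`scenario` must hold stochastic programs", call. = FALSE)
  }
  progs <- scenario[c("A", "a", "B", "b")]
  net <- net_outcome(scenario)
  var_cost <- sum(vapply(progs, function(p) p$sd_cost^2, numeric(1)))
  var_effect <- sum(vapply(progs, function(p) p$sd_effect^2, numeric(1)))
  cross <- sum(vapply(progs, function(p) p$rho * p$sd_cost * p$sd_effect,
                      numeric(1)))
  rho <- if (var_cost > 0 && var_effect > 0) {
    cross / sqrt(var_cost * var_effect)
  } else {
    warning("zero total variance on one axis; net-outcome correlation undefined")
    NA_real_
  }
  structure(list(mu_effect = net$net_effect, mu_cost = net$net_cost,
                 var_effect = var_effect, var_cost = var_cost, rho = rho),
            class = "dmp_moments")
}

#' @export
print.dmp_moments <- function(x, ...) {
  cat("Net-outcome distribution on the decision-making plane:\n")
  cat(sprintf("  net effect: mean %.2f LY, SD %.3f\n",
              x$mu_effect, sqrt(x$var_effect)))
  cat(sprintf("  net cost:   mean %.1f kUSD, SD %.1f\n",
              x$mu_cost, sqrt(x$var_cost)))
  cat(sprintf("  correlation rho = %.4f\n", x$rho))
  invisible(x)
}

# 2x2 covariance in (net_effect, net_cost) order.
moments_cov <- function(m) {
  se <- sqrt(m$var_effect)
  sc <- sqrt(m$var_cost)
  matrix(c(m$var_effect, m$rho * se * sc,
           m$rho * se * sc, m$var_cost), 2, 2)
}

#' Standard bivariate normal rectangle probability
#'
#' \eqn{P(X \le h, Y \le k)} for standard normal X, Y with correlation
#' `rho`, computed by reducing the double integral to one-dimensional
#' quadrature of \eqn{\phi(x)\,\Phi\!\big((k - \rho x)/\sqrt{1-\rho^2}\big)}
#' over \eqn{x \le h} with [stats::integrate()]. The degenerate cases
#' \eqn{\rho = \pm 1} use the exact comonotone forms.
#'
#' @param h,k Upper limits (may be infinite).
#' @param rho Correlation in \eqn{[-1, 1]}.
#' @return A probability.
#' @keywords internal
pbvn <- function(h, k, rho) {
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  if (is.infinite(h) && h < 0 || is.infinite(k) && k < 0) return(0)
  if (rho == 1) return(stats::pnorm(min(h, k)))
  if (rho == -1) return(max(0, stats::pnorm(h) - stats::pnorm(-k)))
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
  stats::integrate(f, -Inf, min(h, 8.5), rel.tol = 1e-10,
                   abs.tol = 1e-12)$value
}

#' Analytic quadrant probabilities on the decision-making plane
#'
#' Orthant probabilities of the bivariate-normal net-outcome distribution
#' over the four regions bounded by the plane's axes (net cost = 0 and net
#' effect = 0 on the original scale). After standardizing, the integration
#' limits become \eqn{-\mu_E/\sigma_E} and \eqn{-\mu_C/\sigma_C}, so the
#' quadrant masses depend on where the distribution sits relative to the
#' axes, not only on its shape. These values are the exact counterparts of
#' the Monte-Carlo proportions and serve to validate the simulator.
#'
#' Zero variance on an axis degenerates gracefully: the corresponding
#' indicator collapses to a point mass at the mean and the probabilities are
#' computed from the remaining univariate normal.
#'
#' @param m A `dmp_moments` object (or a stochastic scenario, which is
#'   converted via [dmp_moments()]).
#' @return A `dmp_quadrants` object with `p1`..`p4` and
#'   `source = "analytic"`. The four masses sum to 1 to integration
#'   tolerance (~1e-8).
#' @export
#' @examples
#' quadrant_probabilities(demo_scenario("variance_decreasing"))
quadrant_probabilities <- function(m) {
  if (inherits(m, "dmp_scenario")) m <- dmp_moments(m)
  stopifnot(inherits(m, "dmp_moments"))
  se <- sqrt(m$var_effect)
  sc <- sqrt(m$var_cost)
  # P(net_effect <= 0) and P(net_cost <= 0), handling degenerate axes.
  pe0 <- if (se > 0) stats::pnorm(-m$mu_effect / se) else as.numeric(m$mu_effect <= 0)
  pc0 <- if (sc > 0) stats::pnorm(-m$mu_cost / sc) else as.numeric(m$mu_cost <= 0)
  if (se > 0 && sc > 0) {
    # p2 = P(E <= 0, C <= 0) from the rectangle CDF; others by marginals.
    p2 <- pbvn(-m$mu_effect / se, -m$mu_cost / sc, m$rho)
  } else {
    p2 <- pe0 * pc0  # one axis is a point mass; indicators are independent
  }
  p1 <- pc0 - p2                    # E > 0, C <= 0
  p3 <- pe0 - p2                    # E <= 0, C > 0
  p4 <- 1 - p1 - p2 - p3
  probs <- pmin(pmax(c(p1, p2, p3, p4), 0), 1)
  structure(list(p1 = probs[1], p2 = probs[2], p3 = probs[3], p4 = probs[4],
                 source = "analytic", n = NA_integer_),
            class = "dmp_quadrants")
}
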