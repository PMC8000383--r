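#' Sample correlated cost/effect pairs for one program
#'
#' Draws from the program's bivariate normal using the closed-form 2x2
#' Cholesky transform: with independent standard normals z1, z2,
#' \deqn{C = \mu_C + \sigma_C z_1, \qquad
#'       E = \mu_E + \sigma_E(\rho z_1 + \sqrt{1-\rho^2}\, z_2).}
#' No truncation is applied: negative sampled costs or effects are kept, as
#' the plain-normal model implies.
#'
#' @param p A [program_dist()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers may seed once for a whole simulation).
#' @return A data.frame with columns `cost` and `effect`, `n` rows.
#' @export
#' @examples
#' s <- sample_program(program_dist("A", 100000, 5000, 150, 5, 0.5), 1000, seed = 1)
#' colMeans(s)
sample_program <- function(p, n, seed = NULL) {
  if (!is_stochastic_program(p)) {
    stop("`p` must be a `program_dist()` object", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  data.frame(
    cost = p$mean_cost + p$sd_cost * z1,
    effect = p$mean_effect + p$sd_effect * (p$rho * z1 + sqrt(1 - p$rho^2) * z2)
  )
}

#' Simulate net outcomes on the decision-making plane
#'
#' Draws each of the four programs independently (programs are independent
#' of one another; only within-program cost/effect pairs are correlated),
#' then forms each draw's net cost \eqn{(C_A - C_a) - (C_B - C_b)} and net
#' effect likewise. Per-program draws are retained so that portfolio-level
#' summaries can be computed from the same sample.
#'
#' @param scenario A stochastic [reallocation_scenario()].
#' @param n Number of draws; defaults to 10,000.
#' @param seed Integer seed for reproducibility. Programs are drawn in the
#'   fixed order A, a, B, b from a single stream seeded once.
#' @return An object of class `dmp_samples`: a list with `n`, `net_cost`,
#'   `net_effect`, `quadrant` (factor `I`..`IV`), a `programs` list of
#'   per-program cost/effect data.frames, and the `scenario`.
#' @export
#' @examples
#' s <- sample_dmp(demo_scenario("variance_decreasing"), n = 2000, seed = 7)
#' quadrant_proportions(s)
sample_dmp <- function(scenario, n = 10000, seed = NULL) {
  stopifnot(inherits(scenario, "dmp_scenario"))
  if (!scenario$stochastic) {
    stop("`scenario` must hold stochastic programs; see `program_dist()`",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  progs <- lapply(scenario[c("A", "a", "B", "b")], sample_program, n = n)
  net_cost <- (progs$A$cost - progs$a$cost) - (progs$B$cost - progs$b$cost)
  net_effect <- (progs$A$effect - progs$a$effect) -
    (progs$B$effect - progs$b$effect)
  structure(list(n = as.integer(n),
                 net_cost = net_cost,
                 net_effect = net_effect,
                 quadrant = classify_quadrant(net_cost, net_effect),
                 programs = progs,
                 scenario = scenario),
            class = "dmp_samples")
}

#' @export
print.dmp_samples <- function(x, ...) {
  cat(sprintf("DMP sample set: %d draws\n", x$n))
  cat(sprintf("  mean net cost   %10.1f kUSD (SD %.1f)\n",
              mean(x$net_cost), stats::sd(x$net_cost)))
  cat(sprintf("  mean net effect %10.2f LY   (SD %.2f)\n",
              mean(x$net_effect), stats::sd(x$net_effect)))
  qp <- quadrant_proportions(x)
  cat(sprintf("  quadrants I/II/III/IV: %.1f%% / %.1f%% / %.1f%% / %.1f%%\n",
              100 * qp$p1, 100 * qp$p2, 100 * qp$p3, 100 * qp$p4))
  invisible(x)
}

#' Classify net outcomes into decision-making-plane quadrants
#'
#' The plane has net effects on the horizontal axis and net costs on the
#' vertical axis. Quadrant I (southeast) is a health gain at a cost saving;
#' II (southwest) a health loss at a cost saving; III (northwest) a health
#' loss at extra cost; IV (northeast) a health gain that exceeds available
#' resources. Boundary convention (half-open, measure-zero for continuous
#' outcomes): net effect exactly 0 counts as "no gain" (II/III) and net cost
#' exactly 0 as "saving" (I/II).
#'
#' @param net_cost,net_effect Numeric vectors of equal length (thousand USD,
#'   life years). Must be finite.
#' @return A factor with levels `I`, `II`, `III`, `IV`.
#' @export
#' @examples
#' classify_quadrant(c(-10000, 0, 5), c(40, 0, -5))
classify_quadrant <- function(net_cost, net_effect) {
  if (length(net_cost) != length(net_effect)) {
    stop("`net_cost` and `net_effect` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(net_cost)) || !all(is.finite(net_effect))) {
    stop("net outcomes must be finite", call. = FALSE)
  }
  gain <- net_effect > 0
  saving <- net_cost <= 0
  q <- ifelse(gain,
              ifelse(saving, "I", "IV"),
              ifelse(saving, "II", "III"))
  factor(q, levels = c("I", "II", "III", "IV"))
}

#' Quadrant proportions of a simulated sample
#'
#' The fraction of draws whose net outcome falls in each quadrant; an
#' estimate of the corresponding orthant probabilities of the joint
#' net-outcome distribution. Proportions sum to 1 exactly.
#'
#' @param s A `dmp_samples` object from [sample_dmp()].
#' @return An object of class `dmp_quadrants` with fields `p1`..`p4` and
#'   `source = "simulation"`.
#' @seealso [quadrant_probabilities()] for the analytic counterpart.
#' @export
quadrant_proportions <- function(s) {
  stopifnot(inherits(s, "dmp_samples"))
  if (s$n < 1L) stop("empty sample set", call. = FALSE)
  tab <- table(s$quadrant) / s$n
  structure(list(p1 = unname(tab[["I"]]), p2 = unname(tab[["II"]]),
                 p3 = unname(tab[["III"]]), p4 = unname(tab[["IV"]]),
                 source = "simulation", n = s$n),
            class = "dmp_quadrants")
}

#' @export
print.dmp_quadrants <- function(x, ...) {
  cat(sprintf("Quadrant probabilities (%s):\n", x$source))
  cat(sprintf("  I (SE, gain & saving)  %6.2f%%\n", 100 * x$p1))
  cat(sprintf("  II (SW, loss & saving) %6.2f%%\n", 100 * x$p2))
  cat(sprintf("  III (NW, loss & cost)  %6.2f%%\n", 100 * x$p3))
  cat(sprintf("  IV (NE, gain & cost)   %6.2f%%\n", 100 * x$p4))
  invisible(x)
}

#' Credible ellipse of the joint net-outcome distribution
#'
#' The bivariate-normal density contour enclosing probability mass `level`.
#' For covariance \eqn{\Sigma} with eigenvalues \eqn{\lambda_i}, the
#' semi-axes are \eqn{\sqrt{\lambda_i \, q}} where \eqn{q} is the
#' chi-square(2 df) quantile of `level`, oriented along the eigenvectors.
#'
#' @param moments A `dmp_moments` object from [dmp_moments()].
#' @param level Probability mass in (0, 1), e.g. 0.95.
#' @param n_points Number of polygon vertices for the outline (default 181).
#' @return A list: `center` (net_effect, net_cost), `semi_axes`, `angle`
#'   (radians, orientation of the major axis in the effect–cost plane), and
#'   `outline`, a data.frame of (net_effect, net_cost) boundary points.
#' @export
credible_ellipse <- function(moments, level, n_points = 181) {
  stopifnot(inherits(moments, "dmp_moments"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  sigma <- moments_cov(moments)
  ev <- eigen(sigma, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    stop("covariance is singular; no ellipse exists", call. = FALSE)
  }
  r <- sqrt(ev$values * stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n_points)
  unit <- rbind(cos(theta), sin(theta))
  pts <- ev$vectors %*% (r * unit)
  center <- c(net_effect = moments$mu_effect, net_cost = moments$mu_cost)
  list(center = center,
       semi_axes = r,
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       outline = data.frame(net_effect = center[1] + pts[1, ],
                            net_cost = center[2] + pts[2, ]))
}
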