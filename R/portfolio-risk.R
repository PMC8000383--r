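#' Portfolio costs and effects before or after reallocation
#'
#' The funded portfolio before the reallocation is \{a, B\}; after, it is
#' \{A, b\}. Per draw, the portfolio cost (effect) is the sum of its two
#' member programs' sampled costs (effects).
#'
#' @param s A `dmp_samples` object from [sample_dmp()] (per-program draws
#'   are retained there for this purpose).
#' @param which `"before"` (a + B) or `"after"` (A + b).
#' @return A list of class `dmp_portfolio`: `label`, `members`, and numeric
#'   vectors `costs` (kUSD) and `effects` (LY).
#' @export
#' @examples
#' s <- sample_dmp(demo_scenario("variance_decreasing"), n = 2000, seed = 1)
#' mean(portfolio_samples(s, "before")$costs)
portfolio_samples <- function(s, which = c("before", "after")) {
  stopifnot(inherits(s, "dmp_samples"))
  which <- match.arg(which)
  members <- if (which == "before") c("a", "B") else c("A", "b")
  if (!all(members %in% names(s$programs))) {
    stop("sample set does not retain per-program draws", call. = FALSE)
  }
  p1 <- s$programs[[members[1]]]
  p2 <- s$programs[[members[2]]]
  structure(list(label = which,
                 members = members,
                 costs = p1$cost + p2$cost,
                 effects = p1$effect + p2$effect),
            class = "dmp_portfolio")
}

#' Quartile coefficient of dispersion
#'
#' A skew-robust relative dispersion measure,
#' \deqn{QCD = \frac{Q_3 - Q_1}{Q_3 + Q_1},}
#' built from the first and third quartiles so that tail behaviour and
#' outliers are disregarded (unlike the coefficient of variation). Higher
#' values indicate greater dispersion. Quartiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param values Numeric vector, length >= 4.
#' @return A list of class `dmp_dispersion` with `q1`, `q3`, `qcd`.
#' @export
#' @examples
#' qcd(rnorm(10000, mean = 180000, sd = 18385))$qcd  # ~ 0.6745 * sd/mean
qcd <- function(values) {
  if (inherits(values, "dmp_portfolio")) {
    stop("pass a numeric vector, e.g. `portfolio$costs`", call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.75), type = 7))
  if (q[1] + q[2] == 0) {
    stop("Q1 + Q3 = 0; quartile coefficient of dispersion undefined",
         call. = FALSE)
  }
  structure(list(q1 = q[1], q3 = q[2], qcd = (q[2] - q[1]) / (q[2] + q[1])),
            class = "dmp_dispersion")
}

# Population QCD of a normal distribution: quartiles are mu +/- z75*sigma.
qcd_normal <- function(mean, sd) {
  z <- stats::qnorm(0.75)
  (z * sd) / mean
}

#' Change in portfolio risk from the reallocation
#'
#' Compares the funded portfolio before (a + B) and after (A + b) the
#' reallocation on two levels:
#' \itemize{
#'   \item \emph{Variance verdicts} from the scenario's exact parameters:
#'     the reallocation is cost-variance-decreasing when
#'     \eqn{\sigma^2_{C_A} + \sigma^2_{C_b} < \sigma^2_{C_a} + \sigma^2_{C_B}}
#'     and effect-variance-decreasing under the analogous inequality for
#'     effects.
#'   \item \emph{Descriptive dispersion} from the samples: the quartile
#'     coefficient of dispersion of portfolio costs and effects, before and
#'     after, and the after/before ratios.
#' }
#' The overall verdict is `"variance-decreasing"` when both parameter
#' inequalities hold, `"variance-increasing"` when both are reversed,
#' `"neutral"` when both sides are equal, and `"mixed"` otherwise.
#'
#' @param s A `dmp_samples` object from [sample_dmp()].
#' @return A list of class `dmp_risk`: `verdict`, logical
#'   `cost_variance_decreasing` / `effect_variance_decreasing`, a `qcd`
#'   data.frame (quantity x before/after/ratio), and the parameter variances.
#' @export
#' @examples
#' s <- sample_dmp(demo_scenario("variance_increasing"), n = 5000, seed = 2)
#' risk_change(s)
risk_change <- function(s) {
  stopifnot(inherits(s, "dmp_samples"))
  sc <- s$scenario
  var_cost_after <- sc$A$sd_cost^2 + sc$b$sd_cost^2
  var_cost_before <- sc$a$sd_cost^2 + sc$B$sd_cost^2
  var_effect_after <- sc$A$sd_effect^2 + sc$b$sd_effect^2
  var_effect_before <- sc$a$sd_effect^2 + sc$B$sd_effect^2

  before <- portfolio_samples(s, "before")
  after <- portfolio_samples(s, "after")
  qtab <- data.frame(
    quantity = c("costs", "effects"),
    before = c(qcd(before$costs)$qcd, qcd(before$effects)$qcd),
    after = c(qcd(after$costs)$qcd, qcd(after$effects)$qcd)
  )
  qtab$ratio <- qtab$after / qtab$before

  cost_dec <- var_cost_after < var_cost_before
  eff_dec <- var_effect_after < var_effect_before
  verdict <- if (var_cost_after == var_cost_before &&
                 var_effect_after == var_effect_before) {
    "neutral"
  } else if (cost_dec && eff_dec) {
    "variance-decreasing"
  } else if (!cost_dec && !eff_dec &&
             (var_cost_after > var_cost_before ||
              var_effect_after > var_effect_before)) {
    "variance-increasing"
  } else {
    "mixed"
  }
  structure(list(verdict = verdict,
                 cost_variance_decreasing = cost_dec,
                 effect_variance_decreasing = eff_dec,
                 qcd = qtab,
                 variances = list(cost_before = var_cost_before,
                                  cost_after = var_cost_after,
                                  effect_before = var_effect_before,
                                  effect_after = var_effect_after)),
            class = "dmp_risk")
}

#' @export
print.dmp_risk <- function(x, ...) {
  cat(sprintf("Portfolio risk change: %s\n", x$verdict))
  cat("Quartile coefficients of dispersion (before = a+B, after = A+b):\n")
  tab <- x$qcd
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-8s before %.3f  after %.3f  ratio %.2f\n",
                tab$quantity[i], tab$before[i], tab$after[i], tab$ratio[i]))
  }
  invisible(x)
}
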