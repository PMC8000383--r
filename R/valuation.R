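#' Parameters of the quadrant gain/loss value function
#'
#' The decision maker's valuation of a net outcome on the plane is a pair of
#' quadrant-specific power functions of the rescaled net effect `x` and net
#' cost `y` (see [rescale_outcome()]). The exponents \eqn{\alpha_1} (effects)
#' and \eqn{\alpha_2} (costs) shape the rate at which value accrues away
#' from the origin (\eqn{\alpha > 1}: progressively increasing) and can be
#' read as risk-aversion parameters. The exponents \eqn{\beta_1} (gains) and
#' \eqn{\beta_2} (losses) adjust the valuation for the change in portfolio
#' risk the reallocation causes: a variance-increasing reallocation is
#' penalized with \eqn{\beta_1 < 1 < \beta_2}, a variance-decreasing one
#' rewarded with \eqn{\beta_1 > 1 > \beta_2}, and \eqn{\beta_1 = \beta_2 = 1}
#' recovers the unadjusted value function. The betas compose multiplicatively
#' in the exponent, \eqn{|v|^{\alpha \beta}}. Separate cost/effect betas may
#' be supplied; they default to the shared values.
#'
#' @param alpha1,alpha2 Risk-aversion exponents for effects and costs
#'   (> 0; default 2).
#' @param beta1,beta2 Gain and loss adjustment exponents (> 0; default 1).
#' @param beta1_cost,beta1_effect,beta2_cost,beta2_effect Optional per-axis
#'   overrides; default to `beta1`/`beta2`.
#' @param cost_unit Money per unit of `y`, in thousand USD (default 10,000,
#'   i.e. USD 10 million).
#' @param effect_unit Life years per unit of `x` (default 10).
#' @return An object of class `dmp_value_params`.
#' @export
#' @examples
#' value_function_params(beta1 = 1.1, beta2 = 0.9)
value_function_params <- function(alpha1 = 2, alpha2 = 2,
                                  beta1 = 1, beta2 = 1,
                                  beta1_cost = beta1, beta1_effect = beta1,
                                  beta2_cost = beta2, beta2_effect = beta2,
                                  cost_unit = 10000, effect_unit = 10) {
  exps <- c(alpha1, alpha2, beta1, beta2,
            beta1_cost, beta1_effect, beta2_cost, beta2_effect)
  if (any(!is.finite(exps)) || any(exps <= 0)) {
    stop("all exponents must be finite and positive", call. = FALSE)
  }
  if (cost_unit <= 0 || effect_unit <= 0) {
    stop("rescaling units must be positive", call. = FALSE)
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2,
                 beta1_cost = beta1_cost, beta1_effect = beta1_effect,
                 beta2_cost = beta2_cost, beta2_effect = beta2_effect,
                 cost_unit = cost_unit, effect_unit = effect_unit),
            class = "dmp_value_params")
}

#' Rescale a net outcome to value-function units
#'
#' Net effects and net costs are expressed in common dimensionless units
#' before valuation — by default units of 10 life years and USD 10 million
#' — so that both axes contribute comparably; otherwise the much larger
#' monetary numbers would dominate any power-function value. Rescaling does
#' not move outcomes between quadrants, nor change their ranking.
#'
#' @param net_cost,net_effect Numeric vectors (kUSD, LY).
#' @param params A [value_function_params()].
#' @return A data.frame with columns `x` (rescaled net effect) and `y`
#'   (rescaled net cost).
#' @export
#' @examples
#' rescale_outcome(-10000, 40, value_function_params())  # x = 4, y = -1
rescale_outcome <- function(net_cost, net_effect, params = value_function_params()) {
  stopifnot(inherits(params, "dmp_value_params"))
  data.frame(x = net_effect / params$effect_unit,
             y = net_cost / params$cost_unit)
}

#' Quadrant-specific gain and loss values
#'
#' For a rescaled net outcome (x = net effect, y = net cost) the gain `g`
#' and loss `f` are, by quadrant:
#' \tabular{lll}{
#'   Quadrant \tab gain \tab loss \cr
#'   I (SE) \tab \eqn{|y|^{\alpha_2\beta_1} + |x|^{\alpha_1\beta_1}} \tab 0 \cr
#'   II (SW) \tab \eqn{|y|^{\alpha_2\beta_1}} \tab \eqn{|x|^{\alpha_1\beta_2}} \cr
#'   III (NW) \tab 0 \tab \eqn{|y|^{\alpha_2\beta_2} + |x|^{\alpha_1\beta_2}} \cr
#'   IV (NE) \tab \eqn{|x|^{\alpha_1\beta_1}} \tab \eqn{|y|^{\alpha_2\beta_2}}
#' }
#' so cost savings (y <= 0) and health gains (x > 0) are credited as gains,
#' cost overruns and health losses charged as losses, each raised to its
#' risk-adjusted exponent. Both functions are non-negative everywhere;
#' loss vanishes identically in Quadrant I and gain in Quadrant III.
#'
#' @param x,y Rescaled net effect and net cost (equal-length vectors).
#' @param params A [value_function_params()].
#' @return Numeric vector of gains (`gain_value`) or losses (`loss_value`).
#' @export
#' @examples
#' gain_value(4, -1, value_function_params())  # quadrant I: 1 + 16 = 17
gain_value <- function(x, y, params = value_function_params()) {
  stopifnot(inherits(params, "dmp_value_params"))
  q <- classify_quadrant(y, x)  # quadrants are scale-invariant
  cost_term <- abs(y)^(params$alpha2 * params$beta1_cost)
  effect_term <- abs(x)^(params$alpha1 * params$beta1_effect)
  ifelse(q == "I", cost_term + effect_term,
         ifelse(q == "II", cost_term,
                ifelse(q == "IV", effect_term, 0)))
}

#' @rdname gain_value
#' @export
loss_value <- function(x, y, params = value_function_params()) {
  stopifnot(inherits(params, "dmp_value_params"))
  q <- classify_quadrant(y, x)
  cost_term <- abs(y)^(params$alpha2 * params$beta2_cost)
  effect_term <- abs(x)^(params$alpha1 * params$beta2_effect)
  ifelse(q == "III", cost_term + effect_term,
         ifelse(q == "II", effect_term,
                ifelse(q == "IV", cost_term, 0)))
}

#' Expected net gain and net loss over the decision-making plane
#'
#' Applies the quadrant value function to every simulated net outcome and
#' aggregates quadrant by quadrant: each quadrant contributes its
#' conditional mean gain (loss) times the proportion of draws falling in
#' it; the totals are the sums over quadrants, which equal the grand
#' per-draw means. Empty quadrants contribute zero.
#'
#' @param s A `dmp_samples` object from [sample_dmp()].
#' @param params A [value_function_params()].
#' @return An object of class `dmp_valuation`: `net_gain`, `net_loss`
#'   (dimensionless, in value-function units), and a `by_quadrant`
#'   data.frame with per-quadrant proportions, conditional means, and
#'   contributions.
#' @export
#' @examples
#' s <- sample_dmp(demo_scenario("variance_decreasing"), n = 2000, seed = 3)
#' expected_net_gain_loss(s, value_function_params())
expected_net_gain_loss <- function(s, params = value_function_params()) {
  stopifnot(inherits(s, "dmp_samples"))
  r <- rescale_outcome(s$net_cost, s$net_effect, params)
  gains <- gain_value(r$x, r$y, params)
  losses <- loss_value(r$x, r$y, params)
  q <- s$quadrant
  by_q <- data.frame(quadrant = levels(q))
  by_q$proportion <- as.numeric(table(q)) / s$n
  cond_mean <- function(v) {
    vapply(levels(q), function(l) {
      inq <- q == l
      if (any(inq)) mean(v[inq]) else 0
    }, numeric(1))
  }
  by_q$mean_gain <- cond_mean(gains)
  by_q$mean_loss <- cond_mean(losses)
  by_q$gain_contribution <- by_q$proportion * by_q$mean_gain
  by_q$loss_contribution <- by_q$proportion * by_q$mean_loss
  structure(list(net_gain = sum(by_q$gain_contribution),
                 net_loss = sum(by_q$loss_contribution),
                 by_quadrant = by_q,
                 params = params),
            class = "dmp_valuation")
}

#' @export
print.dmp_valuation <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Value over the DMP (alpha = %.3g/%.3g, beta1 = %.3g, beta2 = %.3g):\n",
    p$alpha1, p$alpha2, p$beta1, p$beta2))
  cat(sprintf("  expected net gain %.2f, expected net loss %.2f\n",
              x$net_gain, x$net_loss))
  cat(sprintf("  (units: effects / %g LY, costs / %g kUSD)\n",
              p$effect_unit, p$cost_unit))
  invisible(x)
}
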