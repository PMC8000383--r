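#' Run the full reallocation analysis
#'
#' Chains the analysis stages on one scenario: the deterministic decision
#' rule at the means, the exact net-outcome moments, a Monte-Carlo sample
#' of net outcomes, quadrant probabilities (simulated and analytic), the
#' portfolio-risk comparison, and the gain/loss valuation. Identical
#' `seed`/`n`/parameters give identical reports.
#'
#' @param scenario A [reallocation_scenario()] or a path to a config file
#'   readable by [read_scenario()]. Deterministic scenarios get the rule
#'   verdict and net outcome only.
#' @param n Monte-Carlo draws (default 10,000).
#' @param seed Integer seed (default 1).
#' @param params A [value_function_params()].
#' @return An object of class `dmp_report` with fields `scenario`, `rule`,
#'   and — for stochastic scenarios — `moments`, `samples`,
#'   `quadrants_mc`, `quadrants_analytic`, `risk`, `valuation`, plus the
#'   provenance fields `n` and `seed`.
#' @export
#' @examples
#' rep <- run_full_analysis(demo_scenario("variance_decreasing"),
#'                          n = 2000, seed = 11)
#' rep$quadrants_mc
run_full_analysis <- function(scenario, n = 10000, seed = 1,
                              params = value_function_params()) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "dmp_scenario"))
  out <- list(scenario = scenario,
              rule = check_reallocation_rule(scenario),
              n = as.integer(n), seed = as.integer(seed), params = params)
  if (scenario$stochastic) {
    out$moments <- dmp_moments(scenario)
    out$samples <- sample_dmp(scenario, n = n, seed = seed)
    out$quadrants_mc <- quadrant_proportions(out$samples)
    out$quadrants_analytic <- quadrant_probabilities(out$moments)
    out$risk <- risk_change(out$samples)
    out$valuation <- expected_net_gain_loss(out$samples, params)
  }
  structure(out, class = "dmp_report")
}

#' @export
print.dmp_report <- function(x, ...) {
  cat("== Reallocation analysis ==\n")
  print(x$scenario)
  verdict <- if (x$rule$efficient) "efficient (Quadrant I)" else "not efficient"
  cat(sprintf("Decision rule at the means: %s; net outcome (%.0f kUSD, %+.1f LY)\n",
              verdict, x$rule$net$net_cost, x$rule$net$net_effect))
  if (!is.null(x$moments)) {
    cat(sprintf("\nMonte Carlo: n = %d, seed = %d\n", x$n, x$seed))
    print(x$moments)
    print(x$quadrants_mc)
    print(x$quadrants_analytic)
    print(x$risk)
    print(x$valuation)
  }
  invisible(x)
}

#' Plot net outcomes on the decision-making plane
#'
#' Scatter of simulated net outcomes with credible ellipses of the exact
#' bivariate-normal net-outcome distribution. Net effects run along the
#' horizontal axis (gains to the right), net costs along the vertical
#' (overruns upward), so Quadrant I is the southeast region.
#'
#' @param samples Optional `dmp_samples` to scatter (may be `NULL`).
#' @param moments Optional `dmp_moments` for the ellipses; defaults to the
#'   moments of the sample's scenario.
#' @param levels Credible levels for the ellipses (default
#'   `c(0.05, 0.5, 0.95)`).
#' @return A ggplot object.
#' @export
plot_dmp <- function(samples = NULL, moments = NULL,
                     levels = c(0.05, 0.5, 0.95)) {
  if (is.null(moments) && !is.null(samples)) {
    moments <- dmp_moments(samples$scenario)
  }
  if (is.null(moments) && is.null(samples)) {
    stop("provide `samples`, `moments`, or both", call. = FALSE)
  }
  p <- ggplot2::ggplot()
  if (!is.null(samples)) {
    df <- data.frame(net_effect = samples$net_effect,
                     net_cost = samples$net_cost,
                     quadrant = samples$quadrant)
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = net_effect, y = net_cost,
                   colour = quadrant),
      alpha = 0.3, size = 0.6)
  }
  if (!is.null(moments)) {
    for (lv in levels) {
      ell <- credible_ellipse(moments, lv)
      p <- p + ggplot2::geom_path(
        data = ell$outline,
        ggplot2::aes(x = net_effect, y = net_cost),
        linewidth = 0.4)
    }
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Net effects (life years)",
                  y = "Net costs (thousand USD)",
                  colour = "Quadrant") +
    ggplot2::theme_minimal()
}

#' Plot program portfolios before and after reallocation
#'
#' Credible ellipses of each program's cost/effect distribution, coloured
#' by whether the program belongs to the funded portfolio after the
#' reallocation (A and b) or before it (a and B). Visualizes whether the
#' reallocation tightens or widens the funded portfolio's uncertainty.
#'
#' @param scenario A stochastic [reallocation_scenario()].
#' @param levels Credible levels for the per-program ellipses.
#' @return A ggplot object.
#' @export
plot_portfolios <- function(scenario, levels = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(scenario, "dmp_scenario"), scenario$stochastic)
  outlines <- list()
  for (nm in c("A", "a", "B", "b")) {
    prog <- scenario[[nm]]
    m <- structure(list(mu_effect = prog$mean_effect, mu_cost = prog$mean_cost,
                        var_effect = prog$sd_effect^2,
                        var_cost = prog$sd_cost^2, rho = prog$rho),
                   class = "dmp_moments")
    for (lv in levels) {
      ell <- credible_ellipse(m, lv)$outline
      ell$program <- prog$label
      ell$portfolio <- if (nm %in% c("A", "b")) "after (A + b)" else "before (a + B)"
      ell$level <- lv
      outlines[[length(outlines) + 1L]] <- ell
    }
  }
  df <- do.call(rbind, outlines)
  ggplot2::ggplot(df, ggplot2::aes(x = net_effect, y = net_cost,
                                   colour = portfolio,
                                   group = interaction(program, level))) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c("after (A + b)" = "firebrick",
                                            "before (a + B)" = "steelblue")) +
    ggplot2::labs(x = "Effects (life years)", y = "Costs (thousand USD)",
                  colour = "Portfolio") +
    ggplot2::theme_minimal()
}
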