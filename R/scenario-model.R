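#' Define a healthcare program with known costs and effects
#'
#' A program whose total cost and total health effect are treated as certain.
#' Costs are carried in thousands of monetary units (thousand USD), effects
#' in life years; conversion to display units happens only at reporting time.
#'
#' @param label Short name for the program.
#' @param cost Program cost, in thousand USD. Must be non-negative.
#' @param effect Program effect, in life years. Any finite value.
#'
#' @return An object of class `dmp_program`.
#' @seealso [program_dist()] for the uncertain-program counterpart.
#' @export
#' @examples
#' program("Program A", cost = 100000, effect = 150)
program <- function(label, cost, effect) {
  stopifnot(is.character(label), length(label) == 1L)
  cost <- as.numeric(cost)
  effect <- as.numeric(effect)
  if (length(cost) != 1L || !is.finite(cost) || cost < 0) {
    stop("`cost` must be a single finite non-negative number", call. = FALSE)
  }
  if (length(effect) != 1L || !is.finite(effect)) {
    stop("`effect` must be a single finite number", call. = FALSE)
  }
  structure(list(label = label, cost = cost, effect = effect),
            class = "dmp_program")
}

#' Define a healthcare program with uncertain costs and effects
#'
#' Program cost and effect are modelled as a correlated bivariate normal:
#' means and standard deviations on each axis plus a within-program
#' cost--effect correlation `rho`. A positive `rho` expresses that better
#' health outcomes tend to come with higher costs. Costs and effects are
#' assumed independent *between* programs; `rho` acts within one program only.
#'
#' @param label Short name for the program.
#' @param mean_cost,sd_cost Mean and standard deviation of cost (thousand USD);
#'   `sd_cost >= 0`.
#' @param mean_effect,sd_effect Mean and standard deviation of effect (life
#'   years); `sd_effect >= 0`.
#' @param rho Within-program correlation between cost and effect, in
#'   \eqn{[-1, 1]}. Defaults to 0.5.
#'
#' @return An object of class `dmp_program_dist`.
#' @export
#' @examples
#' program_dist("Program A", 100000, 5000, 150, 5, rho = 0.5)
program_dist <- function(label, mean_cost, sd_cost, mean_effect, sd_effect,
                         rho = 0.5) {
  stopifnot(is.character(label), length(label) == 1L)
  vals <- c(mean_cost = mean_cost, sd_cost = sd_cost,
            mean_effect = mean_effect, sd_effect = sd_effect, rho = rho)
  if (!all(is.finite(vals))) {
    stop("all distribution parameters must be finite", call. = FALSE)
  }
  if (sd_cost < 0 || sd_effect < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (abs(rho) > 1) {
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(label = label,
                 mean_cost = as.numeric(mean_cost),
                 sd_cost = as.numeric(sd_cost),
                 mean_effect = as.numeric(mean_effect),
                 sd_effect = as.numeric(sd_effect),
                 rho = as.numeric(rho)),
            class = "dmp_program_dist")
}

is_stochastic_program <- function(p) inherits(p, "dmp_program_dist")

# Means of a program regardless of representation.
program_means <- function(p) {
  if (is_stochastic_program(p)) {
    c(cost = p$mean_cost, effect = p$mean_effect)
  } else {
    c(cost = p$cost, effect = p$effect)
  }
}

#' Bundle four programs into a reallocation scenario
#'
#' A reallocation replaces the funded portfolio \{a, B\} with \{A, b\}: new
#' program A displaces program a, and program B is cancelled and replaced by
#' program b to release the resources A requires. All four programs must be
#' either deterministic ([program()]) or stochastic ([program_dist()]).
#'
#' @param A,a,B,b The four programs: new (A), displaced (a), cancelled (B),
#'   replacement (b).
#'
#' @return An object of class `dmp_scenario` with a logical attribute-like
#'   field `stochastic`.
#' @export
#' @examples
#' sc <- reallocation_scenario(
#'   A = program("A", 100000, 150), a = program("a", 40000, 90),
#'   B = program("B", 140000, 50), b = program("b", 70000, 30)
#' )
reallocation_scenario <- function(A, a, B, b) {
  progs <- list(A = A, a = a, B = B, b = b)
  stoch <- vapply(progs, is_stochastic_program, logical(1))
  det <- vapply(progs, inherits, logical(1), what = "dmp_program")
  if (!all(stoch | det)) {
    stop("all four programs must be `program()` or `program_dist()` objects",
         call. = FALSE)
  }
  if (any(stoch) && !all(stoch)) {
    stop("programs must be all deterministic or all stochastic", call. = FALSE)
  }
  structure(list(A = A, a = a, B = B, b = b, stochastic = all(stoch)),
            class = "dmp_scenario")
}

#' @export
print.dmp_scenario <- function(x, ...) {
  kind <- if (x$stochastic) "stochastic" else "deterministic"
  cat(sprintf("Reallocation scenario (%s): Pf(a + B) -> Pf(A + b)\n", kind))
  for (nm in c("A", "a", "B", "b")) {
    p <- x[[nm]]
    if (is_stochastic_program(p)) {
      cat(sprintf("  %s: cost %s (SD %s) kUSD, effect %s (SD %s) LY, rho %.2f\n",
                  nm, format(p$mean_cost, big.mark = ",", scientific = FALSE),
                  format(p$sd_cost, big.mark = ",", scientific = FALSE),
                  p$mean_effect, p$sd_effect, p$rho))
    } else {
      cat(sprintf("  %s: cost %s kUSD, effect %s LY\n",
                  nm, format(p$cost, big.mark = ",", scientific = FALSE), p$effect))
    }
  }
  invisible(x)
}

#' Incremental cost and effect of replacing one program with another
#'
#' The increments of funding `new` in place of `old`:
#' \eqn{\Delta C = C_{new} - C_{old}} and \eqn{\Delta E = E_{new} - E_{old}}.
#' Stochastic programs are compared at their means.
#'
#' @param new,old Programs ([program()] or [program_dist()]).
#' @return A list with elements `delta_cost` (thousand USD) and
#'   `delta_effect` (life years).
#' @export
#' @examples
#' incremental_outcomes(program("A", 100000, 150), program("a", 40000, 90))
incremental_outcomes <- function(new, old) {
  mn <- program_means(new)
  mo <- program_means(old)
  list(delta_cost = unname(mn["cost"] - mo["cost"]),
       delta_effect = unname(mn["effect"] - mo["effect"]))
}

#' Net outcome of a reallocation
#'
#' The net cost and net effect after the reallocation, plotted on the
#' decision-making plane:
#' \deqn{C_{net} = \Delta C(A) - \Delta C(B), \quad
#'       E_{net} = \Delta E(A) - \Delta E(B)}
#' where \eqn{\Delta C(A) = C_A - C_a} and \eqn{\Delta C(B) = C_B - C_b}
#' (likewise for effects). For stochastic scenarios this is the mean net
#' outcome, i.e. the centre of the joint net-outcome distribution.
#'
#' @param scenario A [reallocation_scenario()].
#' @return A list with `net_cost` (thousand USD) and `net_effect` (life
#'   years).
#' @export
net_outcome <- function(scenario) {
  stopifnot(inherits(scenario, "dmp_scenario"))
  dA <- incremental_outcomes(scenario$A, scenario$a)
  dB <- incremental_outcomes(scenario$B, scenario$b)
  list(net_cost = dA$delta_cost - dB$delta_cost,
       net_effect = dA$delta_effect - dB$delta_effect)
}

#' Apply the reallocation decision rule under certainty
#'
#' Funding A by displacing a and cancelling B in favour of b is an
#' unambiguous improvement when the resources released cover the additional
#' requirement, \eqn{\Delta C(A) \le \Delta C(B)}, and the health gained
#' exceeds the health forgone, \eqn{\Delta E(A) > \Delta E(B)}. The first
#' inequality is non-strict, the second strict. When both hold the net
#' outcome lands in Quadrant I (southeast) of the decision-making plane.
#'
#' @param scenario A deterministic [reallocation_scenario()] (stochastic
#'   scenarios are evaluated at their means).
#' @return A list: `efficient` (logical verdict), `increment_A`,
#'   `increment_B` (the two increments), and `net` (the [net_outcome()]).
#' @export
#' @examples
#' sc <- demo_scenario("deterministic")
#' check_reallocation_rule(sc)
check_reallocation_rule <- function(scenario) {
  stopifnot(inherits(scenario, "dmp_scenario"))
  dA <- incremental_outcomes(scenario$A, scenario$a)
  dB <- incremental_outcomes(scenario$B, scenario$b)
  list(efficient = dA$delta_cost <= dB$delta_cost &&
         dA$delta_effect > dB$delta_effect,
       increment_A = dA,
       increment_B = dB,
       net = net_outcome(scenario))
}
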