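# Shared fixtures: the worked-example scenarios and a random-scenario
# generator for property-style tests.

scn_det <- function() demo_scenario("deterministic")
scn_dec <- function() demo_scenario("variance_decreasing")
scn_inc <- function() demo_scenario("variance_increasing")

# A random stochastic four-program scenario; draws from the current RNG
# stream so callers seed once per property loop.
random_scenario <- function() {
  rand_prog <- function(nm) {
    program_dist(nm,
                 mean_cost = runif(1, 20000, 150000),
                 sd_cost = runif(1, 1000, 15000),
                 mean_effect = runif(1, 20, 200),
                 sd_effect = runif(1, 1, 15),
                 rho = runif(1, -0.9, 0.9))
  }
  reallocation_scenario(A = rand_prog("A"), a = rand_prog("a"),
                        B = rand_prog("B"), b = rand_prog("b"))
}

# Tolerance for comparing an MC proportion with its exact probability:
# three binomial standard errors plus the half-width of one count (the
# latter covers discreteness when p is within a few counts of zero).
mc_tol <- function(p, n) 3 * sqrt(p * (1 - p) / n) + 1 / n

quadrant_vec <- function(q) c(q$p1, q$p2, q$p3, q$p4)
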