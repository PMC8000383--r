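test_that("net-outcome moments sum variances and pool correlations", {
  for (sc in list(scn_dec(), scn_inc())) {
    m <- dmp_moments(sc)
    expect_equal(m$mu_effect, 40)
    expect_equal(m$mu_cost, -10000)
    expect_equal(m$var_effect, 5^2 + 13^2 + 13^2 + 5^2)  # 388
    expect_equal(m$var_cost, (5000^2 + 13000^2 + 13000^2 + 5000^2))
    expect_equal(m$rho, 0.5)
  }

  # zero within-program correlations give an uncorrelated net outcome
  sc0 <- demo_scenario("variance_decreasing", rho = 0)
  expect_equal(dmp_moments(sc0)$rho, 0)

  # with a single stochastic program the net correlation is that program's
  solo <- reallocation_scenario(
    program_dist("A", 10, 3, 5, 2, rho = -0.4), program_dist("a", 1, 0, 1, 0),
    program_dist("B", 1, 0, 1, 0), program_dist("b", 1, 0, 1, 0))
  expect_equal(dmp_moments(solo)$rho, -0.4)

  all_degen <- reallocation_scenario(
    program_dist("A", 1, 0, 1, 0), program_dist("a", 1, 0, 1, 0),
    program_dist("B", 1, 0, 1, 0), program_dist("b", 1, 0, 1, 0))
  expect_warning(m0 <- dmp_moments(all_degen), "undefined")
  expect_true(is.na(m0$rho))
})

test_that("net correlation is invariant to permuting program labels", {
  set.seed(11)
  sc <- random_scenario()
  base <- dmp_moments(sc)$rho
  progs <- sc[c("A", "a", "B", "b")]
  for (i in 1:5) {
    perm <- sample(4)
    scp <- reallocation_scenario(progs[[perm[1]]], progs[[perm[2]]],
                                 progs[[perm[3]]], progs[[perm[4]]])
    expect_equal(dmp_moments(scp)$rho, base)
  }
})

test_that("the bivariate normal rectangle CDF matches closed forms", {
  # origin orthant: P(X<=0, Y<=0) = 1/4 + asin(rho) / (2*pi)
  for (rho in c(-0.95, -0.5, -0.1, 0, 0.3, 0.5, 0.9)) {
    expect_equal(dmplane:::pbvn(0, 0, rho), 0.25 + asin(rho) / (2 * pi),
                 tolerance = 1e-8)
  }
  # independence factorizes
  expect_equal(dmplane:::pbvn(1.3, -0.7, 0), pnorm(1.3) * pnorm(-0.7))
  # comonotone / antithetic limits
  expect_equal(dmplane:::pbvn(1, 2, 1), pnorm(1))
  expect_equal(dmplane:::pbvn(1, 2, -1), pnorm(1) - pnorm(-2))
  # marginal recovery at +Inf
  expect_equal(dmplane:::pbvn(0.4, Inf, 0.6), pnorm(0.4), tolerance = 1e-8)
})

test_that("analytic quadrant probabilities obey symmetry and marginals", {
  centred <- structure(list(mu_effect = 0, mu_cost = 0, var_effect = 1,
                            var_cost = 1, rho = 0), class = "dmp_moments")
  qp <- quadrant_probabilities(centred)
  expect_equal(quadrant_vec(qp), rep(0.25, 4), tolerance = 1e-9)

  m <- dmp_moments(scn_dec())
  qp <- quadrant_probabilities(m)
  expect_equal(sum(quadrant_vec(qp)), 1, tolerance = 1e-8)
  # marginal consistency: P(net effect > 0) from the orthants
  expect_equal(qp$p1 + qp$p4, pnorm(m$mu_effect / sqrt(m$var_effect)),
               tolerance = 1e-8)
  expect_equal(qp$p1 + qp$p2, pnorm(-m$mu_cost / sqrt(m$var_cost)),
               tolerance = 1e-8)

  # with rho = 0 the orthant masses are products of marginals
  m0 <- dmp_moments(demo_scenario("variance_decreasing", rho = 0))
  qp0 <- quadrant_probabilities(m0)
  pe <- pnorm(40 / sqrt(388))
  pc <- pnorm(10000 / sqrt(388e6))
  expect_equal(qp0$p1, pe * pc, tolerance = 1e-8)
  expect_equal(qp0$p4, pe * (1 - pc), tolerance = 1e-8)
})

test_that("quadrant probabilities are identical across the two worked scenarios", {
  q1 <- quadrant_probabilities(scn_dec())
  q2 <- quadrant_probabilities(scn_inc())
  expect_identical(quadrant_vec(q1), quadrant_vec(q2))
})

test_that("a dominant mean net effect drives the loss quadrants to zero", {
  make_m <- function(mu_e) {
    structure(list(mu_effect = mu_e, mu_cost = -1, var_effect = 1,
                   var_cost = 1, rho = 0.5), class = "dmp_moments")
  }
  loss_mass <- vapply(c(1, 3, 6, 9), function(mu) {
    qp <- quadrant_probabilities(make_m(mu))
    qp$p2 + qp$p3
  }, numeric(1))
  expect_true(all(diff(loss_mass) < 0))
  expect_lt(loss_mass[4], 1e-15)
})

test_that("degenerate axes fall back to univariate probabilities", {
  m <- structure(list(mu_effect = 2, mu_cost = -1, var_effect = 0,
                      var_cost = 4, rho = NA_real_), class = "dmp_moments")
  qp <- quadrant_probabilities(m)
  # net effect is surely +2 (> 0): all mass in quadrants I and IV
  expect_equal(qp$p2 + qp$p3, 0)
  expect_equal(qp$p1, pnorm(1 / 2), tolerance = 1e-12)
  expect_equal(qp$p4, 1 - pnorm(1 / 2), tolerance = 1e-12)
})

test_that("Monte-Carlo proportions converge to the analytic orthants", {
  # oracle equivalence across 50 random scenarios at n = 10,000: in a
  # family of 200 three-sigma comparisons a handful of exceedances are
  # expected by chance, so the family-level statistic is the exceedance
  # count (P(> 5 | 3-sigma) ~ 1e-5), with a hard 5-sigma cap per case.
  set.seed(20260921)
  n <- 10000
  exceed <- 0L
  for (i in 1:50) {
    sc <- random_scenario()
    exact <- quadrant_vec(quadrant_probabilities(sc))
    mc <- quadrant_vec(quadrant_proportions(sample_dmp(sc, n = n)))
    for (j in 1:4) {
      dev <- abs(mc[j] - exact[j])
      if (dev >= mc_tol(exact[j], n)) exceed <- exceed + 1L
      expect_lt(dev, 5 * sqrt(exact[j] * (1 - exact[j]) / n) + 1 / n)
    }
  }
  expect_lte(exceed, 5L)
})
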