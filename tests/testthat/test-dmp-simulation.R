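test_that("sample_program matches its distribution at n = 10,000", {
  p <- program_dist("A", 100000, 5000, 150, 5, rho = 0.5)
  s <- sample_program(p, 10000, seed = 101)
  expect_equal(nrow(s), 10000)
  # means within ~3 standard errors
  expect_lt(abs(mean(s$cost) - 100000), 3 * 5000 / sqrt(10000))
  expect_lt(abs(mean(s$effect) - 150), 3 * 5 / sqrt(10000))
  expect_equal(cor(s$cost, s$effect), 0.5, tolerance = 0.05)
  expect_equal(sd(s$cost), 5000, tolerance = 0.05)
})

test_that("degenerate and perfectly correlated programs sample exactly", {
  p0 <- program_dist("P", 50, 0, 5, 0)
  s0 <- sample_program(p0, 25, seed = 1)
  expect_true(all(s0$cost == 50) && all(s0$effect == 5))

  # rho = 1 with equal SDs: standardized cost equals standardized effect
  p1 <- program_dist("P", 10, 2, 100, 2, rho = 1)
  s1 <- sample_program(p1, 100, seed = 2)
  expect_equal((s1$cost - 10) / 2, (s1$effect - 100) / 2)
})

test_that("sample_dmp propagates per-program draws to net outcomes", {
  s <- sample_dmp(scn_dec(), n = 10000, seed = 7)
  # net identity holds draw by draw
  expect_equal(
    s$net_cost,
    (s$programs$A$cost - s$programs$a$cost) -
      (s$programs$B$cost - s$programs$b$cost))
  expect_equal(
    s$net_effect,
    (s$programs$A$effect - s$programs$a$effect) -
      (s$programs$B$effect - s$programs$b$effect))
  # sample mean near the deterministic net outcome
  expect_lt(abs(mean(s$net_cost) + 10000), 3 * sqrt(388e6 / 10000))
  expect_lt(abs(mean(s$net_effect) - 40), 3 * sqrt(388 / 10000))
  # sample covariance near the exact moments
  expect_equal(var(s$net_cost), 388e6, tolerance = 0.06)
  expect_equal(var(s$net_effect), 388, tolerance = 0.06)
  expect_equal(cor(s$net_effect, s$net_cost), 0.5, tolerance = 0.05)
})

test_that("an all-degenerate scenario reproduces the deterministic outcome", {
  degen <- reallocation_scenario(
    program_dist("A", 100000, 0, 150, 0), program_dist("a", 40000, 0, 90, 0),
    program_dist("B", 140000, 0, 50, 0), program_dist("b", 70000, 0, 30, 0))
  s <- sample_dmp(degen, n = 50, seed = 3)
  expect_true(all(s$net_cost == -10000))
  expect_true(all(s$net_effect == 40))
  expect_equal(quadrant_proportions(s)$p1, 1)
})

test_that("simulation is reproducible under a fixed seed", {
  a <- sample_dmp(scn_dec(), n = 500, seed = 99)
  b <- sample_dmp(scn_dec(), n = 500, seed = 99)
  expect_identical(a, b)
})

test_that("quadrant classification follows the half-open boundary convention", {
  q <- classify_quadrant(net_cost = c(-10000, 0, 5, 3, -2),
                         net_effect = c(40, 0, -5, 10, -1))
  expect_equal(as.character(q), c("I", "II", "III", "IV", "II"))
  expect_error(classify_quadrant(NA_real_, 1), "finite")
  expect_error(classify_quadrant(Inf, 1), "finite")
  expect_error(classify_quadrant(1:2, 1), "equal length")
})

test_that("quadrant proportions sum to one and ignore sample order", {
  s <- sample_dmp(scn_dec(), n = 2000, seed = 5)
  qp <- quadrant_proportions(s)
  expect_identical(qp$p1 + qp$p2 + qp$p3 + qp$p4, 1)
  perm <- sample(seq_len(s$n))
  s2 <- s
  s2$net_cost <- s$net_cost[perm]
  s2$net_effect <- s$net_effect[perm]
  s2$quadrant <- s$quadrant[perm]
  expect_equal(quadrant_proportions(s2)[c("p1", "p2", "p3", "p4")],
               qp[c("p1", "p2", "p3", "p4")])
})

test_that("symmetric centred scenarios split evenly across quadrants", {
  sym <- reallocation_scenario(
    program_dist("A", 100, 10, 10, 2, rho = 0), program_dist("a", 100, 10, 10, 2, rho = 0),
    program_dist("B", 100, 10, 10, 2, rho = 0), program_dist("b", 100, 10, 10, 2, rho = 0))
  qp <- quadrant_proportions(sample_dmp(sym, n = 10000, seed = 8))
  for (p in quadrant_vec(qp)) expect_equal(p, 0.25, tolerance = 0.06)
})

test_that("credible ellipses scale with the chi-square(2) quantile", {
  m <- structure(list(mu_effect = 0, mu_cost = 0, var_effect = 1,
                      var_cost = 1, rho = 0), class = "dmp_moments")
  e95 <- credible_ellipse(m, 0.95)
  expect_equal(unname(e95$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2))
  # radius shrinks to zero as the level does
  e_tiny <- credible_ellipse(m, 1e-10)
  expect_lt(max(e_tiny$semi_axes), 1e-4)
  expect_equal(max(abs(e_tiny$outline$net_effect)), 0, tolerance = 1e-4)

  ell <- credible_ellipse(dmp_moments(scn_dec()), 0.5)
  expect_equal(unname(ell$center), c(40, -10000))
  # outline points all lie on the same density contour
  sig <- solve(matrix(c(388, 0.5 * sqrt(388 * 388e6),
                        0.5 * sqrt(388 * 388e6), 388e6), 2, 2))
  d <- apply(cbind(ell$outline$net_effect - 40, ell$outline$net_cost + 10000),
             1, function(v) drop(v %*% sig %*% v))
  expect_equal(d, rep(qchisq(0.5, 2), length(d)), tolerance = 1e-8)

  sing <- structure(list(mu_effect = 0, mu_cost = 0, var_effect = 0,
                         var_cost = 1, rho = NA_real_), class = "dmp_moments")
  sing$rho <- 0
  expect_error(credible_ellipse(sing, 0.95), "singular")
})

test_that("invalid sampling inputs raise parameter errors", {
  expect_error(sample_program(program("P", 1, 1), 10), "program_dist")
  expect_error(sample_dmp(scn_det(), 10), "stochastic")
  expect_error(sample_program(program_dist("P", 1, 1, 1, 1), 0), "positive")
})
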