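test_that("hierarchy generator honours sizes, seeds and prevalences", {
  d <- simulate_hierarchy(J = 17, units_per_group = 10, seed = 81)
  expect_equal(d$n, 170)
  expect_equal(d$J, 17)
  expect_equal(unname(table(d$group_index)), rep(10L, 17),
               ignore_attr = TRUE)
  expect_equal(colnames(d$X1), c("private", "ppp", "z1_1", "z1_2"))
  d2 <- simulate_hierarchy(J = 17, units_per_group = 10, seed = 81)
  expect_identical(d, d2)
  # exact category counts
  d3 <- simulate_hierarchy(J = 5, units_per_group = 10,
                           factor_prevalence = c(40, 4, 6), seed = 82)
  expect_equal(sum(d3$X1[, "private"]), 4)
  expect_equal(sum(d3$X1[, "ppp"]), 6)
  # quantitative columns are standard normal in distribution
  d4 <- simulate_hierarchy(J = 100, units_per_group = 100, l1 = 1, l2 = 0,
                           factor_prevalence = NULL, seed = 83)
  expect_lt(abs(mean(d4$X1[, 1])), 0.04)
  expect_lt(abs(sd(d4$X1[, 1]) - 1), 0.04)
})

test_that("response generator reproduces the mixture probabilities", {
  dbig <- simulate_hierarchy(J = 10, units_per_group = 10000, l1 = 0,
                             l2 = 0, factor_prevalence = NULL, seed = 84)
  # no endpoint mass when omega is pinned near zero
  p_int <- zoib_params(beta0 = logit(0.78), gamma0 = -30, theta = 1,
                       u = rep(0, 10), precision = 14)
  y <- simulate_zoib(dbig, p_int, seed = 85)
  expect_true(all(y > 0 & y < 1))
  expect_lt(abs(mean(y) - 0.78), 0.003)
  # frontier fraction matches the endpoint probability (3 binomial sd)
  p_fr <- zoib_params(beta0 = 0, gamma0 = logit(0.2), theta = 1,
                      u = rep(0, 10), precision = 2)
  y2 <- simulate_zoib(dbig, p_fr, seed = 86)
  expect_lt(abs(mean(y2 == 1) - 0.2), 0.004)
  expect_equal(sum(y2 == 0), 0)
  # ones and zeros split endpoint mass as omega*theta and omega*(1-theta)
  p_mix <- zoib_params(beta0 = 0, gamma0 = logit(0.3), theta = 0.8,
                       u = rep(0, 10), precision = 2)
  y3 <- simulate_zoib(dbig, p_mix, seed = 87)
  n <- length(y3)
  expect_lt(abs(mean(y3 == 1) - 0.24), 3 * sqrt(0.24 * 0.76 / n))
  expect_lt(abs(mean(y3 == 0) - 0.06), 3 * sqrt(0.06 * 0.94 / n))
  expect_identical(y3, simulate_zoib(dbig, p_mix, seed = 87))
})

test_that("planted production frontiers are recovered by the BCC stage", {
  # all factors one: every unit sits on the concave frontier
  sp <- simulate_production(n = 25, m = 2, s = 2, frontier_prob = 1,
                            seed = 88)
  expect_true(all(sp$factors == 1))
  res <- run_dea(sp$dataset)
  expect_true(all(res$scores$pte > 1 - 1e-7))
  # planted frontier units score exactly one in a mixed dataset
  sp2 <- simulate_production(n = 40, m = 2, s = 1, seed = 89)
  res2 <- run_dea(sp2$dataset)
  expect_true(all(res2$scores$pte[sp2$factors == 1] > 1 - 1e-7))
  expect_true(all(res2$scores$pte >= sp2$factors - 1e-7))
  # a single shrunk unit under a dominating peer at equal input
  pd <- production_dataset(cbind(c(2, 2)), cbind(c(3, 1.5)))
  r <- run_dea(pd)
  expect_equal(r$scores$pte, c(1, 0.5), tolerance = 1e-9)
})

test_that("benchmark scenario has the published-study structure", {
  sc <- scenario_table3(seed = 90)
  expect_equal(sc$design$n, 173)
  expect_equal(sc$design$J, 17)
  expect_equal(sum(sc$design$X1[, "private"]), 12)
  expect_equal(sum(sc$design$X1[, "ppp"]), 14)
  expect_equal(173 - 12 - 14, 147)  # public reference count
  expect_equal(sc$params$theta, 0.97)
  expect_equal(sc$params$precision, 14.27)
  expect_equal(sc$params$sigma_u0, 0.57)
  expect_true(all(sc$y >= 0 & sc$y <= 1))
  sc2 <- scenario_table3(seed = 90)
  expect_identical(sc, sc2)
  expect_false(identical(sc$y, scenario_table3(seed = 91)$y))
})
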