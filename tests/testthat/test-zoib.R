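test_that("logit and inverse logit behave as link functions", {
  expect_equal(logit(0.5), 0)
  expect_equal(inv_logit(0), 0.5)
  expect_equal(logit(0.78), log(0.78 / 0.22), tolerance = 1e-12)
  expect_equal(logit(0.78), 1.2657, tolerance = 1e-4)
  p <- c(0.01, 0.3, 0.5, 0.9, 0.999)
  expect_equal(inv_logit(logit(p)), p, tolerance = 1e-12)
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(inv_logit(x)) > 0))
  expect_error(logit(0), "open interval")
  expect_error(logit(1), "open interval")
})

test_that("beta shapes recover the mean/precision parameterization", {
  expect_equal(unname(beta_shapes(0.5, 2)), cbind(1, 1), ignore_attr = TRUE)
  sh <- beta_shapes(0.78, 14.27)
  expect_equal(unname(sh[, 1]), 11.1306, tolerance = 1e-10)
  expect_equal(unname(sh[, 2]), 3.1394, tolerance = 1e-10)
  set.seed(11)
  mu <- runif(50, 0.01, 0.99)
  prec <- runif(50, 0.1, 60)
  sh <- beta_shapes(mu, prec)
  expect_equal(unname(sh[, 1] / rowSums(sh)), mu, tolerance = 1e-12)
  expect_equal(unname(rowSums(sh)), prec, tolerance = 1e-12)
  expect_error(beta_shapes(0, 1), "strictly inside")
  expect_error(beta_shapes(0.5, 0), "positive")
})

test_that("the mixed log-density handles point masses and interior", {
  expect_equal(zoib_logpdf(1, 0.2, 1, 0.5, 2), log(0.2))
  expect_identical(zoib_logpdf(0, 0.2, 1, 0.5, 2), -Inf)  # no mass at 0
  # Beta(1, 1) is uniform, so the interior density is 1 - omega01
  expect_equal(zoib_logpdf(0.5, 0.2, 1, 0.5, 2), log(0.8))
  expect_error(zoib_logpdf(1.5, 0.2, 0.5, 0.5, 2), "\\[0, 1\\]")
})

test_that("total probability mass is one across the mixture", {
  set.seed(12)
  for (i in 1:30) {
    om <- runif(1, 0.02, 0.9)
    th <- runif(1)
    mu <- runif(1, 0.2, 0.8)
    prec <- runif(1, 2.5, 40)
    cont <- integrate(function(v) exp(zoib_logpdf(v, om, th, mu, prec)),
                      0, 1, rel.tol = 1e-9)$value
    mass <- exp(zoib_logpdf(0, om, th, mu, prec)) +
      exp(zoib_logpdf(1, om, th, mu, prec)) + cont
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("linear predictors broadcast group covariates and random effects", {
  d <- hierarchical_design(group = rep(c("a", "b"), each = 3),
                           X1 = cbind(z = rep(0, 6)),
                           X2 = cbind(w = c(0, 0)))
  p0 <- zoib_params(beta1 = 0, beta2 = 0, gamma1 = 0, gamma2 = 0,
                    u = c(0, 0))
  expect_equal(mu_linpred(p0, d), rep(0.5, 6))
  expect_equal(omega_linpred(p0, d), rep(0.5, 6))
  p1 <- zoib_params(beta0 = 1, beta1 = 0, beta2 = 0, gamma1 = 0,
                    gamma2 = 0, u = c(0, 0))
  expect_equal(mu_linpred(p1, d), rep(inv_logit(1), 6), tolerance = 1e-12)
  expect_equal(unique(round(mu_linpred(p1, d), 4)), 0.7311)
  pu <- zoib_params(beta1 = 0, beta2 = 0, gamma1 = 0, gamma2 = 0,
                    u = c(1, -1))
  expect_equal(mu_linpred(pu, d), rep(inv_logit(c(1, -1)), each = 3),
               tolerance = 1e-12)
  pg <- zoib_params(gamma0 = -3, beta1 = 0, beta2 = 0, gamma1 = 0,
                    gamma2 = 0, u = c(0, 0))
  expect_equal(unique(round(omega_linpred(pg, d), 4)), 0.0474)
  # no random effect in the omega submodel
  expect_equal(omega_linpred(pu, d), rep(0.5, 6))
  # shifting gamma0 by c multiplies the endpoint odds by exp(c)
  pg2 <- zoib_params(gamma0 = -3 + 0.7, beta1 = 0, beta2 = 0, gamma1 = 0,
                     gamma2 = 0, u = c(0, 0))
  o1 <- omega_linpred(pg, d) / (1 - omega_linpred(pg, d))
  o2 <- omega_linpred(pg2, d) / (1 - omega_linpred(pg2, d))
  expect_equal(o2 / o1, rep(exp(0.7), 6), tolerance = 1e-12)
  # level-2 covariates reach every unit of the group
  pl2 <- zoib_params(beta1 = 0, beta2 = 2, gamma1 = 0, gamma2 = 0,
                     u = c(0, 0))
  d2 <- hierarchical_design(group = rep(c("a", "b"), each = 3),
                            X1 = cbind(z = rep(0, 6)),
                            X2 = cbind(w = c(1, -1)))
  expect_equal(mu_linpred(pl2, d2), rep(inv_logit(c(2, -2)), each = 3),
               tolerance = 1e-12)
})

test_that("log-likelihood composes per-unit terms", {
  d0 <- hierarchical_design(group = character(0))
  p <- zoib_params(theta = 0.5, u = numeric())
  expect_equal(zoib_loglik(p, d0, numeric(0)), 0)
  d1 <- hierarchical_design(group = "a")
  p1 <- zoib_params(theta = 0.5, u = 0)
  expect_equal(zoib_loglik(p1, d1, 1), log(0.5 * 0.5), tolerance = 1e-12)
  # three units, hand-summed terms
  d3 <- hierarchical_design(group = rep("a", 3))
  p3 <- zoib_params(beta0 = logit(0.6), gamma0 = logit(0.3), theta = 0.8,
                    precision = 5, u = 0)
  y3 <- c(1, 0.4, 0)
  hand <- log(0.3 * 0.8) +
    (log(0.7) + dbeta(0.4, 0.6 * 5, 0.4 * 5, log = TRUE)) +
    log(0.3 * 0.2)
  expect_equal(zoib_loglik(p3, d3, y3), hand, tolerance = 1e-12)
  # permutation invariance
  set.seed(13)
  d8 <- hierarchical_design(group = rep(c("a", "b"), 4),
                            X1 = cbind(z = rnorm(8)))
  p8 <- zoib_params(beta0 = 0.4, beta1 = 0.3, gamma0 = -1, gamma1 = 0.2,
                    theta = 0.9, precision = 8, u = c(0.2, -0.2))
  y8 <- c(1, runif(6, 0.05, 0.95), 1)
  perm <- sample(8)
  dperm <- hierarchical_design(group = rep(c("a", "b"), 4)[perm],
                               X1 = cbind(z = d8$X1[perm, 1]))
  expect_equal(zoib_loglik(p8, d8, y8),
               zoib_loglik(p8, dperm, y8[perm]), tolerance = 1e-12)
})

test_that("with no endpoint mass the model degenerates to beta regression", {
  set.seed(14)
  d <- hierarchical_design(group = rep("a", 40))
  y <- runif(40, 0.05, 0.95)
  p <- zoib_params(beta0 = logit(0.6), gamma0 = -40, theta = 1,
                   precision = 7, u = 0)
  plain_beta <- sum(dbeta(y, 0.6 * 7, 0.4 * 7, log = TRUE))
  expect_equal(zoib_loglik(p, d, y), plain_beta, tolerance = 1e-9)
})

test_that("endpoint classification snaps LP round-off", {
  cls <- classify_endpoints(c(1 - 1e-9, 0.5, 1e-9, 1, 0))
  expect_equal(cls$y, c(1, 0.5, 0, 1, 0))
  expect_equal(sum(cls$is_one), 2)
  expect_equal(sum(cls$is_zero), 2)
  expect_equal(which(cls$interior), 2L)
  expect_error(classify_endpoints(c(0.5, 1.1)), "\\[0, 1\\]")
})

test_that("priors are flat in the fixed effects and proper elsewhere", {
  pr <- zoib_priors()
  pa <- zoib_params(beta0 = 0, u = c(0.3, -0.1), sigma_u0 = 1,
                    theta = 0.9, precision = 10)
  pb <- pa
  pb$beta0 <- 57.3
  pb$gamma0 <- -12
  expect_equal(zoib_log_prior(pa, pr), zoib_log_prior(pb, pr))
  # half-normal log-density difference in sigma, all else fixed
  pc <- pa
  pc$sigma_u0 <- 2
  diff_expected <- (dnorm(2, 0, 2.5, log = TRUE) -
                      dnorm(1, 0, 2.5, log = TRUE)) +
    sum(dnorm(pa$u, 0, 2, log = TRUE)) - sum(dnorm(pa$u, 0, 1, log = TRUE))
  expect_equal(zoib_log_prior(pc, pr) - zoib_log_prior(pa, pr),
               diff_expected, tolerance = 1e-12)
  # u = 0 maximizes the random-intercept increment for fixed sigma
  pu0 <- pa
  pu0$u <- c(0, 0)
  expect_gt(zoib_log_prior(pu0, pr), zoib_log_prior(pa, pr))
  expect_error(zoib_priors("bogus"))
  # sensitivity configurations are proper alternatives
  for (cfg in c("gamma_sensitivity", "normal_sensitivity")) {
    expect_true(is.finite(zoib_log_prior(pa, zoib_priors(cfg))))
  }
})

test_that("mean efficiency index is a monotone odds transform", {
  expect_equal(mei(0.5), 1)
  mu <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(mei(mu)) > 0))
  expect_equal(mei(mu) * mei(1 - mu), rep(1, length(mu)), tolerance = 1e-12)
  expect_error(mei(1), "strictly inside")
  expect_equal(ratio_from_coefficient(0), 1)
  expect_equal(ratio_from_coefficient(1.45), 4.263, tolerance = 1e-3)
})
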