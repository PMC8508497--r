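test_that("sampling is reproducible and echoes the estimation defaults", {
  # defaults follow the reporting convention: 4 chains, 1000 warmup,
  # 5000 retained updates
  fo <- formals(sample_zoib)
  expect_equal(fo$chains, 4)
  expect_equal(fo$warmup, 1000)
  expect_equal(fo$iter, 5000)
  d <- simulate_hierarchy(J = 3, units_per_group = 10, l1 = 1, l2 = 0,
                          factor_prevalence = NULL, seed = 61)
  p <- zoib_params(beta0 = 0.8, beta1 = 0.3, gamma0 = -1.5, gamma1 = 0,
                   u = rep(0, 3), theta = 0.9, precision = 10)
  y <- simulate_zoib(d, p, seed = 62)
  ch1 <- sample_zoib(d, y, chains = 2, warmup = 50, iter = 80, seed = 63)
  ch2 <- sample_zoib(d, y, chains = 2, warmup = 50, iter = 80, seed = 63)
  expect_identical(ch1$draws, ch2$draws)
  ch3 <- sample_zoib(d, y, chains = 2, warmup = 50, iter = 80, seed = 64)
  expect_false(identical(ch1$draws, ch3$draws))
})

test_that("intercept-only beta regression recovers the true mean", {
  set.seed(65)
  d <- hierarchical_design(group = rep("g1", 200))
  y <- rbeta(200, 0.7 * 15, 0.3 * 15)
  ch <- sample_zoib(d, y, chains = 2, warmup = 400, iter = 800, seed = 66)
  # beta0 and the single random intercept are only jointly identified
  mu_draws <- inv_logit(ch$draws[, , "beta0"] + ch$draws[, , "u[g1]"])
  expect_lt(abs(mean(mu_draws) - 0.7), 3 * sd(mu_draws))
  expect_lt(sd(mu_draws), 0.05)
})

test_that("theta drifts toward one when no zeros are observed", {
  set.seed(67)
  d <- simulate_hierarchy(J = 4, units_per_group = 30, l1 = 0, l2 = 0,
                          factor_prevalence = NULL, seed = 68)
  p <- zoib_params(beta0 = 1.2, gamma0 = -1.5, u = rep(0, 4),
                   theta = 1, precision = 12)
  y <- simulate_zoib(d, p, seed = 69)
  expect_gt(sum(y == 1), 5)
  expect_equal(sum(y == 0), 0)
  ch <- sample_zoib(d, y, chains = 2, warmup = 200, iter = 400, seed = 70)
  th <- as.vector(ch$draws[, , "theta"])
  expect_true(all(th >= 0 & th <= 1))
  expect_gt(mean(th), 0.85)
})

test_that("posterior matches an independent Gibbs implementation", {
  # the mixture factorizes into Bernoulli endpoint, Bernoulli one and beta
  # interior components, all expressible in JAGS: an end-to-end oracle for
  # the likelihood, priors and sampler combined
  suppressPackageStartupMessages(require(rjags, quietly = TRUE))
  set.seed(71)
  J <- 6
  d <- simulate_hierarchy(J = J, units_per_group = 50, l1 = 1, l2 = 0,
                          factor_prevalence = NULL, seed = 21)
  p <- zoib_params(beta0 = 1, beta1 = 0.4, gamma0 = -1.2, gamma1 = 0.5,
                   u = rnorm(J, 0, 0.4), sigma_u0 = 0.4, theta = 0.9,
                   precision = 12)
  y <- simulate_zoib(d, p, seed = 22)
  model <- "
  model {
    for (i in 1:n) {
      end[i] ~ dbern(om[i])
      logit(om[i]) <- g0 + g1 * x[i]
    }
    for (k in 1:n1) { one[k] ~ dbern(theta) }
    for (m in 1:ni) {
      yi[m] ~ dbeta(mu[m] * prec, (1 - mu[m]) * prec)
      logit(mu[m]) <- b0 + u[gint[m]] + b1 * xi[m]
    }
    for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
    b0 ~ dnorm(0, 1e-4); b1 ~ dnorm(0, 1e-4)
    g0 ~ dnorm(0, 1e-4); g1 ~ dnorm(0, 1e-4)
    theta ~ dunif(0, 1)
    sigma_u ~ dnorm(0, 0.16) T(0,)
    tau_u <- 1 / (sigma_u * sigma_u)
    prec ~ dnorm(0, 0.0004) T(0,)
  }"
  end <- as.numeric(y == 0 | y == 1)
  ii <- y > 0 & y < 1
  dat <- list(n = length(y), end = end, x = d$X1[, 1], n1 = sum(end),
              one = c(rep(1, sum(y == 1)), rep(0, sum(y == 0))),
              ni = sum(ii), yi = y[ii], xi = d$X1[ii, 1],
              gint = d$group_index[ii], J = J)
  jm <- rjags::jags.model(textConnection(model), data = dat, n.chains = 2,
                          quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 1))
  update(jm, 1500)
  samp <- rjags::coda.samples(jm, c("b0", "b1", "g0", "g1", "theta",
                                    "sigma_u", "prec"), n.iter = 6000)
  jm_mat <- as.matrix(samp)
  ch <- sample_zoib(d, y, chains = 2, warmup = 800, iter = 3000, seed = 5)
  s <- summarize_posterior(ch)
  rownames(s) <- s$parameter
  map <- c(beta0 = "b0", beta1_z1_1 = "b1", gamma0 = "g0",
           gamma1_z1_1 = "g1", theta = "theta", sigma_u0 = "sigma_u",
           precision = "prec")
  for (ours in names(map)) {
    jm_mean <- mean(jm_mat[, map[[ours]]])
    jm_sd <- sd(jm_mat[, map[[ours]]])
    expect_lt(abs(s[ours, "mean"] - jm_mean), 0.05 + 0.3 * jm_sd)
    expect_lt(abs(s[ours, "sd"] - jm_sd), 0.05 + 0.35 * jm_sd)
  }
})
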