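# Posterior sampling for the multilevel zero-one inflated beta model.
#
# Blocked adaptive Metropolis-within-Gibbs:
#   * scalar adaptive random-walk updates for each fixed effect (both
#     submodels), each random intercept, log(sigma_u0) and log(precision);
#   * an exact conjugate Gibbs draw for theta (its conditional given the
#     endpoint counts is Beta(n1 + 1, n0 + 1) under the uniform prior);
#   * translation moves that shift the mean-submodel intercept (and each
#     level-2 effect) against the random intercepts along the direction the
#     likelihood cannot see, accepted on the random-intercept prior ratio —
#     these break the strong posterior coupling between beta0 / level-2
#     effects and u;
#   * post-warmup joint random-walk proposals for the full beta and gamma
#     blocks, scaled by the empirical covariance of the second half of
#     warmup (fixed after warmup, so the retained chain is Markov).
# Proposal scales adapt toward a 44% acceptance rate during warmup only
# (Robbins-Monro), then freeze. Linear predictors are cached and updated
# incrementally; only the likelihood terms a block touches are recomputed.

.derive_chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) + 104729 * chain) %% 2147483647)
}

#' Sample the posterior of the multilevel zero-one inflated beta model
#'
#' Runs `chains` independent MCMC chains of `warmup + iter` iterations and
#' retains the post-warmup draws. The posterior is proportional to
#' exp(log-likelihood + log-prior) with the likelihood of [zoib_loglik()]
#' and the prior of [zoib_log_prior()]. Runs are reproducible: per-chain
#' seeds are derived deterministically from `seed`.
#'
#' @param design a [hierarchical_design()].
#' @param y response vector in \[0, 1\] (PTE values; endpoints snapped by
#'   [classify_endpoints()]).
#' @param prior a [zoib_priors()] configuration.
#' @param chains number of chains (default 4).
#' @param warmup warmup (adaptation) iterations per chain, discarded
#'   (default 1000).
#' @param iter retained iterations per chain (default 5000).
#' @param seed master integer seed.
#' @param endpoint_tol endpoint snapping tolerance (default 1e-6).
#' @return Object of class `zoib_chains`: list with `draws` (array chains x
#'   iter x parameters, parameter names in `dimnames`), `warmup`, `iter`,
#'   `seed`, `accept` (mean post-warmup acceptance rate per block, averaged
#'   over chains) and `param_names`.
#' @examples
#' d <- simulate_hierarchy(J = 4, units_per_group = 8, l1 = 1, l2 = 0,
#'                         factor_prevalence = NULL, seed = 1)
#' p <- zoib_params(beta0 = 1, beta1 = 0.3, gamma0 = -2, gamma1 = 0,
#'                  u = rep(0, 4), sigma_u0 = 0.3, theta = 0.95,
#'                  precision = 12)
#' y <- simulate_zoib(d, p, seed = 2)
#' ch <- sample_zoib(d, y, chains = 2, warmup = 100, iter = 200, seed = 3)
#' summarize_posterior(ch)
#' @export
sample_zoib <- function(design, y, prior = zoib_priors(), chains = 4,
                        warmup = 1000, iter = 5000, seed = 1,
                        endpoint_tol = 1e-6) {
  stopifnot(inherits(design, "hierarchical_design"), iter >= 1, chains >= 1)
  if (is.character(prior)) prior <- zoib_priors(prior)
  cls <- classify_endpoints(y, endpoint_tol)
  l1 <- ncol(design$X1)
  l2 <- ncol(design$X2)
  J <- design$J
  pnames <- c("beta0",
              if (l1) paste0("beta1_", colnames(design$X1)),
              if (l2) paste0("beta2_", colnames(design$X2)),
              "gamma0",
              if (l1) paste0("gamma1_", colnames(design$X1)),
              if (l2) paste0("gamma2_", colnames(design$X2)),
              paste0("u[", levels(design$group), "]"),
              "sigma_u0", "theta", "precision")
  P <- length(pnames)
  draws <- array(NA_real_, dim = c(chains, iter, P),
                 dimnames = list(NULL, NULL, pnames))
  acc <- vector("list", chains)
  for (c in seq_len(chains)) {
    res <- .zoib_chain(design, cls, prior, warmup, iter,
                       .derive_chain_seed(seed, c))
    draws[c, , ] <- res$draws
    acc[[c]] <- res$accept
  }
  structure(list(draws = draws, warmup = warmup, iter = iter, seed = seed,
                 chains = chains, param_names = pnames,
                 accept = colMeans(do.call(rbind, acc)),
                 prior = prior$config),
            class = "zoib_chains")
}

#' @export
print.zoib_chains <- function(x, ...) {
  cat(sprintf("ZOIB posterior draws: %d chains x %d iterations (%d warmup), %d parameters\n",
              x$chains, x$iter, x$warmup, length(x$param_names)))
  invisible(x)
}

# single chain; returns draws (iter x P) and per-block acceptance rates
.zoib_chain <- function(design, cls, prior, warmup, iter, chain_seed) {
  set.seed(chain_seed)
  y <- cls$y
  int <- which(cls$interior)
  n1 <- sum(cls$is_one)
  n0 <- sum(cls$is_zero)
  n <- design$n
  J <- design$J
  gi <- design$group_index
  # full fixed-effect design matrix (intercept + level-1 + broadcast level-2)
  Xf <- cbind(`(Intercept)` = rep(1, n), design$X1,
              if (ncol(design$X2))
                design$X2[gi, , drop = FALSE])
  p <- ncol(Xf)
  Xint <- Xf[int, , drop = FALSE]
  yint <- y[int]
  gint <- gi[int]
  is_end <- !cls$interior
  # group -> interior member indices (within the interior subset)
  gmembers <- split(seq_along(int), factor(gint, levels = seq_len(J)))

  ll_beta <- function(eta, prec) {
    mu <- stats::plogis(eta)
    sum(stats::dbeta(yint, mu * prec, (1 - mu) * prec, log = TRUE))
  }
  ll_omega <- function(eta_all) {
    sum(stats::plogis(eta_all[is_end], log.p = TRUE)) +
      sum(stats::plogis(-eta_all[!is_end], log.p = TRUE))
  }

  # initialization: fixed effects 0, sigma 1, theta 0.9, precision 10, u 0,
  # jittered per chain; re-draw until the log posterior is finite
  for (try in 1:100) {
    beta <- stats::rnorm(p, 0, 0.1)
    gamma <- stats::rnorm(p, 0, 0.1)
    u <- stats::rnorm(J, 0, 0.1)
    lsig <- log(1) + stats::rnorm(1, 0, 0.1)
    lprec <- log(10) + stats::rnorm(1, 0, 0.1)
    eta_mu <- drop(Xint %*% beta) + u[gint]
    eta_om <- drop(Xf %*% gamma)
    lp0 <- ll_beta(eta_mu, exp(lprec)) + ll_omega(eta_om) +
      sum(stats::dnorm(u, 0, exp(lsig), log = TRUE)) +
      prior$lp_sigma(exp(lsig)) + prior$lp_precision(exp(lprec))
    if (is.finite(lp0)) break
    if (try == 100) stop("initialization failed: non-finite log posterior")
  }

  l2 <- ncol(design$X2)
  # blocks: p beta scalars, p gamma scalars, J u scalars, sigma, precision,
  # 1 + l2 translation moves, 2 post-warmup joint proposals
  nblocks <- 2 * p + J + 2 + 1 + l2 + 2
  ls_prop <- rep(log(0.3), nblocks)   # log proposal sds
  acc_count <- rep(0, nblocks)
  total <- warmup + iter
  draws <- matrix(NA_real_, iter, 2 * p + J + 3)
  # columns of Xf holding level-2 covariates (broadcast): the last l2
  x2cols <- if (l2) (p - l2 + 1):p else integer(0)
  wu_keep <- seq.int(max(1, floor(warmup / 2) + 1), warmup)
  wu_beta <- matrix(NA_real_, length(wu_keep), p)
  wu_gamma <- matrix(NA_real_, length(wu_keep), p)
  chol_beta <- NULL
  chol_gamma <- NULL

  llb <- ll_beta(eta_mu, exp(lprec))
  llo <- ll_omega(eta_om)

  for (t in seq_len(total)) {
    adapt <- t <= warmup
    gam_t <- if (adapt) min(0.5, 3 / sqrt(t)) else 0
    blk <- 0
    # --- mu-submodel fixed effects ---
    for (k in seq_len(p)) {
      blk <- blk + 1
      d <- stats::rnorm(1, 0, exp(ls_prop[blk]))
      eta_new <- eta_mu + d * Xint[, k]
      ll_new <- ll_beta(eta_new, exp(lprec))
      a <- min(1, exp(ll_new - llb))
      if (stats::runif(1) < a) {
        beta[k] <- beta[k] + d
        eta_mu <- eta_new
        llb <- ll_new
        if (!adapt) acc_count[blk] <- acc_count[blk] + 1
      }
      if (adapt) ls_prop[blk] <- ls_prop[blk] + gam_t * (a - 0.44)
    }
    # --- omega-submodel fixed effects ---
    for (k in seq_len(p)) {
      blk <- blk + 1
      d <- stats::rnorm(1, 0, exp(ls_prop[blk]))
      eta_new <- eta_om + d * Xf[, k]
      ll_new <- ll_omega(eta_new)
      a <- min(1, exp(ll_new - llo))
      if (stats::runif(1) < a) {
        gamma[k] <- gamma[k] + d
        eta_om <- eta_new
        llo <- ll_new
        if (!adapt) acc_count[blk] <- acc_count[blk] + 1
      }
      if (adapt) ls_prop[blk] <- ls_prop[blk] + gam_t * (a - 0.44)
    }
    # --- random intercepts (group-local likelihood) ---
    sig <- exp(lsig)
    prec <- exp(lprec)
    for (j in seq_len(J)) {
      blk <- blk + 1
      idx <- gmembers[[j]]
      d <- stats::rnorm(1, 0, exp(ls_prop[blk]))
      lold <- stats::dnorm(u[j], 0, sig, log = TRUE)
      lnew <- stats::dnorm(u[j] + d, 0, sig, log = TRUE)
      if (length(idx)) {
        eo <- eta_mu[idx]
        mu_o <- stats::plogis(eo)
        mu_n <- stats::plogis(eo + d)
        lold <- lold + sum(stats::dbeta(yint[idx], mu_o * prec,
                                        (1 - mu_o) * prec, log = TRUE))
        lnew <- lnew + sum(stats::dbeta(yint[idx], mu_n * prec,
                                        (1 - mu_n) * prec, log = TRUE))
      }
      a <- min(1, exp(lnew - lold))
      if (stats::runif(1) < a) {
        u[j] <- u[j] + d
        if (length(idx)) {
          eta_mu[idx] <- eta_mu[idx] + d
          llb <- ll_beta(eta_mu, prec)
        }
        if (!adapt) acc_count[blk] <- acc_count[blk] + 1
      }
      if (adapt) ls_prop[blk] <- ls_prop[blk] + gam_t * (a - 0.44)
    }
    # --- sigma_u0 on the log scale (prior + random-intercept terms only) ---
    blk <- blk + 1
    d <- stats::rnorm(1, 0, exp(ls_prop[blk]))
    lsig_new <- lsig + d
    lold <- sum(stats::dnorm(u, 0, exp(lsig), log = TRUE)) +
      prior$lp_sigma(exp(lsig)) + lsig
    lnew <- sum(stats::dnorm(u, 0, exp(lsig_new), log = TRUE)) +
      prior$lp_sigma(exp(lsig_new)) + lsig_new
    a <- min(1, exp(lnew - lold))
    if (stats::runif(1) < a) {
      lsig <- lsig_new
      if (!adapt) acc_count[blk] <- acc_count[blk] + 1
    }
    if (adapt) ls_prop[blk] <- ls_prop[blk] + gam_t * (a - 0.44)
    # --- theta: exact conjugate Gibbs draw ---
    theta <- stats::rbeta(1, n1 + 1, n0 + 1)
    # --- precision on the log scale ---
    blk <- blk + 1
    d <- stats::rnorm(1, 0, exp(ls_prop[blk]))
    lprec_new <- lprec + d
    ll_new <- ll_beta(eta_mu, exp(lprec_new))
    lold <- llb + prior$lp_precision(exp(lprec)) + lprec
    lnew <- ll_new + prior$lp_precision(exp(lprec_new)) + lprec_new
    a <- min(1, exp(lnew - lold))
    if (stats::runif(1) < a) {
      lprec <- lprec_new
      llb <- ll_new
      if (!adapt) acc_count[blk] <- acc_count[blk] + 1
    }
    if (adapt) ls_prop[blk] <- ls_prop[blk] + gam_t * (a - 0.44)
    # --- translation moves: shift an intercept-scale direction between the
    #     fixed effects and the random intercepts; the likelihood is exactly
    #     unchanged, so the ratio is the u-prior ratio ---
    sig <- exp(lsig)
    for (tm in 0:l2) {
      blk <- blk + 1
      d <- stats::rnorm(1, 0, exp(ls_prop[blk]))
      u_new <- if (tm == 0) u - d else u - d * design$X2[, tm]
      a <- min(1, exp(sum(stats::dnorm(u_new, 0, sig, log = TRUE)) -
                        sum(stats::dnorm(u, 0, sig, log = TRUE))))
      if (stats::runif(1) < a) {
        if (tm == 0) beta[1] <- beta[1] + d
        else beta[x2cols[tm]] <- beta[x2cols[tm]] + d
        u <- u_new
        if (!adapt) acc_count[blk] <- acc_count[blk] + 1
      }
      if (adapt) ls_prop[blk] <- ls_prop[blk] + gam_t * (a - 0.44)
    }
    # --- post-warmup joint block proposals from the warmup covariance ---
    if (!adapt && !is.null(chol_beta)) {
      blk <- blk + 1
      d <- drop(crossprod(chol_beta, stats::rnorm(p))) * 2.38 / sqrt(p)
      eta_new <- eta_mu + drop(Xint %*% d)
      ll_new <- ll_beta(eta_new, exp(lprec))
      a <- min(1, exp(ll_new - llb))
      if (stats::runif(1) < a) {
        beta <- beta + d
        eta_mu <- eta_new
        llb <- ll_new
        acc_count[blk] <- acc_count[blk] + 1
      }
      blk <- blk + 1
      d <- drop(crossprod(chol_gamma, stats::rnorm(p))) * 2.38 / sqrt(p)
      eta_new <- eta_om + drop(Xf %*% d)
      ll_new <- ll_omega(eta_new)
      a <- min(1, exp(ll_new - llo))
      if (stats::runif(1) < a) {
        gamma <- gamma + d
        eta_om <- eta_new
        llo <- ll_new
        acc_count[blk] <- acc_count[blk] + 1
      }
    }

    if (adapt && t >= wu_keep[1]) {
      wu_beta[t - wu_keep[1] + 1, ] <- beta
      wu_gamma[t - wu_keep[1] + 1, ] <- gamma
    }
    if (t == warmup && length(wu_keep) > 2 * p) {
      eps <- diag(1e-8, p)
      chol_beta <- chol(stats::cov(wu_beta) + eps)
      chol_gamma <- chol(stats::cov(wu_gamma) + eps)
    }

    if (t > warmup)
      draws[t - warmup, ] <- c(beta, gamma, u, exp(lsig), theta, exp(lprec))
  }
  list(draws = draws, accept = acc_count / iter)
}
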