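#' Logit and inverse logit
#'
#' The link function of both submodels of the zero-one inflated beta
#' regression: the beta mean mu and the endpoint-inflation probability
#' omega01 are modelled on the log-odds scale.
#'
#' @param p probability strictly inside (0, 1).
#' @param x real number.
#' @return `logit` returns log(p / (1 - p)); `inv_logit` returns
#'   1 / (1 + exp(-x)).
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("logit is defined on the open interval (0, 1)")
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Beta shape parameters from mean and precision
#'
#' Reparameterizes the beta distribution by its mean mu = a1 / (a1 + a2) and
#' precision a1 + a2 (concentration). Both arguments vectorize.
#'
#' @param mu mean in (0, 1).
#' @param precision concentration > 0.
#' @return A two-column matrix with columns `alpha1`, `alpha2`.
#' @export
beta_shapes <- function(mu, precision) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly inside (0, 1)")
  if (any(precision <= 0)) stop("precision must be positive")
  cbind(alpha1 = mu * precision, alpha2 = (1 - mu) * precision)
}

#' Zero-one inflated beta log-density
#'
#' Mixed density with point masses at the endpoints and a beta density on
#' the interior: mass omega01 * (1 - theta) at 0, mass omega01 * theta at 1,
#' and density (1 - omega01) * Beta(y; a1, a2) for 0 < y < 1, where
#' (a1, a2) come from [beta_shapes()] with the given mean and precision.
#' Zero-probability observations return `-Inf`, not an error.
#'
#' @param y observation in \[0, 1\]; endpoints carry the discrete mass.
#' @param omega01 probability of an endpoint (0 or 1).
#' @param theta conditional probability the endpoint is 1.
#' @param mu beta mean in (0, 1).
#' @param precision beta precision > 0.
#' @return Log-density (vectorized over all arguments).
#' @export
zoib_logpdf <- function(y, omega01, theta, mu, precision) {
  k <- max(length(y), length(omega01), length(theta), length(mu),
           length(precision))
  y <- rep_len(y, k)
  omega01 <- rep_len(omega01, k)
  theta <- rep_len(theta, k)
  mu <- rep_len(mu, k)
  precision <- rep_len(precision, k)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  out <- numeric(k)
  i0 <- y == 0
  i1 <- y == 1
  ii <- !i0 & !i1
  out[i0] <- log(omega01[i0]) + log1p(-theta[i0])
  out[i1] <- log(omega01[i1]) + log(theta[i1])
  if (any(ii)) {
    sh <- beta_shapes(mu[ii], precision[ii])
    out[ii] <- log1p(-omega01[ii]) +
      stats::dbeta(y[ii], sh[, 1], sh[, 2], log = TRUE)
  }
  out
}

#' Two-level design for the second-stage regression
#'
#' Holds the covariates of the multilevel model: level-1 (unit, e.g.
#' hospital) covariates, level-2 (group, e.g. region) covariates, and the
#' unit-to-group mapping. Level-2 covariates are stored once per group and
#' broadcast to the group's units when linear predictors are evaluated.
#'
#' @param group factor/vector of length n mapping each unit to its group.
#' @param X1 numeric matrix n x l1 of level-1 covariates (may have 0
#'   columns). Dummy-coded factor columns must be 0/1.
#' @param X2 numeric matrix J x l2 of level-2 covariates (may have 0
#'   columns), one row per group, rows ordered/named by group level.
#' @param standardized optional character vector naming columns (of either
#'   level) asserted to be standardized; checked to have mean 0 and sd 1
#'   within 1e-9 at their own level.
#' @return Object of class `hierarchical_design` with elements `group`
#'   (factor), `group_index` (integer), `X1`, `X2`, `n`, `J`.
#' @export
hierarchical_design <- function(group, X1 = NULL, X2 = NULL,
                                standardized = character()) {
  group <- as.factor(group)
  n <- length(group)
  J <- nlevels(group)
  if (any(is.na(group))) stop("every unit must map to a group")
  if (is.null(X1)) X1 <- matrix(0, n, 0)
  if (is.null(X2)) X2 <- matrix(0, J, 0)
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  if (nrow(X1) != n) stop("X1 must have one row per unit")
  if (nrow(X2) != J) stop("X2 must have one row per group")
  if (any(!is.finite(X1)) || any(!is.finite(X2)))
    stop("covariates must be finite (no NA/NaN)")
  if (ncol(X1) && is.null(colnames(X1)))
    colnames(X1) <- paste0("x1_", seq_len(ncol(X1)))
  if (ncol(X2) && is.null(colnames(X2)))
    colnames(X2) <- paste0("x2_", seq_len(ncol(X2)))
  if (!is.null(rownames(X2)) && !identical(rownames(X2), levels(group))) {
    if (!all(levels(group) %in% rownames(X2)))
      stop("X2 row names do not cover all group levels")
    X2 <- X2[levels(group), , drop = FALSE]
  }
  for (nm in standardized) {
    v <- if (nm %in% colnames(X1)) X1[, nm]
         else if (nm %in% colnames(X2)) X2[, nm]
         else stop("standardized column not found: ", nm)
    if (abs(mean(v)) > 1e-9 || abs(stats::sd(v) - 1) > 1e-9)
      stop("column ", nm, " declared standardized but is not")
  }
  structure(list(group = group, group_index = as.integer(group),
                 X1 = X1, X2 = X2, n = n, J = J,
                 standardized = standardized),
            class = "hierarchical_design")
}

#' @export
print.hierarchical_design <- function(x, ...) {
  cat("Hierarchical design:", x$n, "units in", x$J, "groups;",
      ncol(x$X1), "level-1 and", ncol(x$X2), "level-2 covariates\n")
  invisible(x)
}

#' Parameters of the multilevel zero-one inflated beta model
#'
#' Collects every parameter of the two-submodel specification: the beta-mean
#' submodel logit(mu_ij) = beta0 + u_0j + X1 beta1 + X2 beta2 with a
#' group-level random intercept u_0j ~ N(0, sigma_u0^2), and the
#' endpoint-inflation submodel logit(omega01_ij) = gamma0 + X1 gamma1 +
#' X2 gamma2 (no random effect). The conditional one-probability theta and
#' the beta precision are constant across units.
#'
#' @param beta0,gamma0 submodel intercepts.
#' @param beta1,gamma1 level-1 coefficient vectors (length l1).
#' @param beta2,gamma2 level-2 coefficient vectors (length l2).
#' @param u random-intercept values, length J.
#' @param sigma_u0 random-intercept standard deviation, > 0.
#' @param theta conditional probability an endpoint equals 1, in \[0, 1\].
#' @param precision beta precision, > 0.
#' @return Object of class `zoib_params`.
#' @export
zoib_params <- function(beta0 = 0, beta1 = numeric(), beta2 = numeric(),
                        u = numeric(), sigma_u0 = 1,
                        gamma0 = 0, gamma1 = numeric(), gamma2 = numeric(),
                        theta = 0.5, precision = 1) {
  if (length(beta1) != length(gamma1) || length(beta2) != length(gamma2))
    stop("mu and omega submodels must use the same covariates")
  if (sigma_u0 <= 0) stop("sigma_u0 must be positive")
  if (precision <= 0) stop("precision must be positive")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, u = u,
                 sigma_u0 = sigma_u0, gamma0 = gamma0, gamma1 = gamma1,
                 gamma2 = gamma2, theta = theta, precision = precision),
            class = "zoib_params")
}

.check_dims <- function(params, design) {
  if (length(params$beta1) != ncol(design$X1))
    stop("length of level-1 coefficients does not match design")
  if (length(params$beta2) != ncol(design$X2))
    stop("length of level-2 coefficients does not match design")
  if (length(params$u) && length(params$u) != design$J)
    stop("random intercept vector must have one entry per group")
}

#' Linear predictors of the two submodels
#'
#' `mu_linpred` returns the per-unit beta mean mu_ij (inverse-logit of
#' intercept + random intercept + level-1 and broadcast level-2 terms);
#' `omega_linpred` returns the per-unit endpoint probability omega01_ij,
#' whose submodel carries no random effect.
#'
#' @param params a [zoib_params()].
#' @param design a [hierarchical_design()].
#' @return Numeric vector of length n, values in (0, 1).
#' @export
mu_linpred <- function(params, design) {
  .check_dims(params, design)
  u <- if (length(params$u)) params$u else rep(0, design$J)
  eta <- params$beta0 + u[design$group_index]
  if (ncol(design$X1)) eta <- eta + drop(design$X1 %*% params$beta1)
  if (ncol(design$X2))
    eta <- eta + drop(design$X2 %*% params$beta2)[design$group_index]
  inv_logit(eta)
}

#' @rdname mu_linpred
#' @export
omega_linpred <- function(params, design) {
  .check_dims(params, design)
  eta <- rep(params$gamma0, design$n)
  if (ncol(design$X1)) eta <- eta + drop(design$X1 %*% params$gamma1)
  if (ncol(design$X2))
    eta <- eta + drop(design$X2 %*% params$gamma2)[design$group_index]
  inv_logit(eta)
}

#' Classify responses into endpoints and interior
#'
#' Efficiency scores within `endpoint_tol` of 0 or 1 are snapped to the
#' exact endpoint so that LP round-off from the first stage cannot leak into
#' the continuous beta component.
#'
#' @param y responses in \[0, 1\] (up to `endpoint_tol` outside).
#' @param endpoint_tol snapping tolerance, default `1e-6`.
#' @return List with `y` (snapped), logical vectors `is_zero`, `is_one`,
#'   `interior`.
#' @export
classify_endpoints <- function(y, endpoint_tol = 1e-6) {
  if (any(y < -endpoint_tol | y > 1 + endpoint_tol))
    stop("responses must lie in [0, 1]")
  y[abs(y) <= endpoint_tol] <- 0
  y[abs(y - 1) <= endpoint_tol] <- 1
  list(y = y, is_zero = y == 0, is_one = y == 1, interior = y > 0 & y < 1)
}

#' Log-likelihood of the multilevel zero-one inflated beta model
#'
#' Sum of [zoib_logpdf()] over units, with unit-specific mu_ij and
#' omega01_ij from the linear predictors and constant theta and precision.
#'
#' @inheritParams mu_linpred
#' @param y response vector of PTE values in \[0, 1\].
#' @param endpoint_tol passed to [classify_endpoints()].
#' @return Scalar log-likelihood (0 for an empty response).
#' @export
zoib_loglik <- function(params, design, y, endpoint_tol = 1e-6) {
  if (length(y) == 0) return(0)
  if (length(y) != design$n) stop("response length does not match design")
  cls <- classify_endpoints(y, endpoint_tol)
  mu <- mu_linpred(params, design)
  om <- omega_linpred(params, design)
  sum(zoib_logpdf(cls$y, om, params$theta, mu, params$precision))
}

#' Prior configuration for the Bayesian fit
#'
#' The default follows the estimation convention of improper flat priors on
#' all fixed effects, a half-normal prior on the random-intercept standard
#' deviation sigma_u0, a uniform(0, 1) prior on theta, and a weak
#' half-normal prior on the beta precision. Two sensitivity configurations
#' swap the sigma_u0/precision priors for gamma or (truncated) normal forms.
#'
#' @param config one of `"default"`, `"gamma_sensitivity"`,
#'   `"normal_sensitivity"`.
#' @param sigma_scale scale of the half-normal prior on sigma_u0 (default
#'   2.5).
#' @param precision_scale scale of the half-normal prior on precision
#'   (default 50).
#' @return Object of class `zoib_priors`: the configuration name plus log
#'   prior density functions `lp_sigma(s)` and `lp_precision(p)`.
#' @export
zoib_priors <- function(config = c("default", "gamma_sensitivity",
                                   "normal_sensitivity"),
                        sigma_scale = 2.5, precision_scale = 50) {
  config <- match.arg(config)
  half_normal <- function(scale) {
    function(v) stats::dnorm(v, 0, scale, log = TRUE) + log(2)
  }
  lp <- switch(config,
    default = list(lp_sigma = half_normal(sigma_scale),
                   lp_precision = half_normal(precision_scale)),
    gamma_sensitivity = list(
      lp_sigma = function(v) stats::dgamma(v, shape = 2, rate = 1,
                                           log = TRUE),
      lp_precision = function(v) stats::dgamma(v, shape = 2, rate = 0.1,
                                               log = TRUE)),
    normal_sensitivity = list(
      # normal truncated to the positive half line
      lp_sigma = function(v) stats::dnorm(v, 1, 1, log = TRUE) -
        stats::pnorm(0, 1, 1, lower.tail = FALSE, log.p = TRUE),
      lp_precision = function(v) stats::dnorm(v, 10, 10, log = TRUE) -
        stats::pnorm(0, 10, 10, lower.tail = FALSE, log.p = TRUE)))
  structure(c(list(config = config, sigma_scale = sigma_scale,
                   precision_scale = precision_scale), lp),
            class = "zoib_priors")
}

#' Log prior density of a parameter set
#'
#' Flat (zero contribution) for all fixed effects; configured priors on
#' sigma_u0 and precision; uniform(0, 1) on theta; and N(0, sigma_u0^2)
#' increments for the random intercepts given sigma_u0.
#'
#' @param params a [zoib_params()].
#' @param prior a [zoib_priors()] configuration (or its name).
#' @return Scalar log prior density (`-Inf` outside the support).
#' @export
zoib_log_prior <- function(params, prior = zoib_priors()) {
  if (is.character(prior)) prior <- zoib_priors(prior)
  if (params$theta < 0 || params$theta > 1) return(-Inf)
  if (params$sigma_u0 <= 0 || params$precision <= 0) return(-Inf)
  lp <- prior$lp_sigma(params$sigma_u0) + prior$lp_precision(params$precision)
  if (length(params$u))
    lp <- lp + sum(stats::dnorm(params$u, 0, params$sigma_u0, log = TRUE))
  lp
}

#' Mean efficiency index and ratio-scale effect measures
#'
#' The mean efficiency index (MEI) of a unit is mu / (1 - mu): values above
#' 1 mean the expected efficiency exceeds the expected inefficiency.
#' Exponentiating a mu-submodel coefficient gives the ratio of MEIs (RMEI)
#' for a one-unit (one standard deviation, for standardized covariates)
#' increase, or versus the reference category for a factor; exponentiating
#' an omega-submodel coefficient gives the odds ratio (OR) of frontier
#' membership. Exponentiating a credible-interval bound gives the bound of
#' the ratio's interval.
#'
#' @param mu beta mean strictly inside (0, 1).
#' @param coef a regression coefficient (log-ratio scale).
#' @return `mei` returns mu / (1 - mu); `ratio_from_coefficient` returns
#'   exp(coef).
#' @export
mei <- function(mu) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly inside (0, 1)")
  mu / (1 - mu)
}

#' @rdname mei
#' @export
ratio_from_coefficient <- function(coef) exp(coef)
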