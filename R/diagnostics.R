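# Rank-normalized split-chain convergence diagnostics.
# Draws for a single parameter are passed as an S x C matrix
# (iterations x chains).

.split_chains <- function(x) {
  S <- nrow(x)
  half <- floor(S / 2)
  if (half < 2) stop("need at least 4 draws per chain to split")
  cbind(x[seq_len(half), , drop = FALSE],
        x[(S - half + 1):S, , drop = FALSE])
}

.rank_normalize <- function(x) {
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                      (length(x) + 1 / 4))
  matrix(z, nrow = nrow(x))
}

# classic potential scale reduction on an already-split matrix
.rhat_basic <- function(x) {
  S <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- S * stats::var(colMeans(x))
  vp <- (S - 1) / S * W + B / S
  sqrt(vp / W)
}

# FFT autocovariance (biased, as used by the combined-chain ESS estimator)
.autocov <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  L <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(v, rep(0, L - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / L
  ac[seq_len(n)] / n
}

# effective sample size of an already-split draw matrix (Geyer initial
# monotone positive sequence on the combined-chain autocorrelation)
.ess_basic <- function(x) {
  S <- nrow(x)
  C <- ncol(x)
  chain_var <- apply(x, 2, stats::var)
  W <- mean(chain_var)
  B <- S * stats::var(colMeans(x))
  vp <- (S - 1) / S * W + B / S
  if (!is.finite(vp) || vp <= 0) return(NaN)
  ac <- sapply(seq_len(C), function(c) .autocov(x[, c]))
  mean_ac <- rowMeans(ac) * S / (S - 1)
  rho <- 1 - (W - mean_ac) / vp        # rho[1] is lag 0 (= 1 up to B/vp term)
  # Geyer: sum successive pairs, truncate at first negative, force monotone
  maxpairs <- floor((S - 1) / 2)
  tau <- 0
  prev <- Inf
  for (k in 0:(maxpairs - 1)) {
    p <- rho[2 * k + 1] + rho[2 * k + 2]
    if (k > 0 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  tau <- max(2 * tau - 1, 1 / log10(S * C + 1))  # tau >= small positive
  ess <- S * C / tau
  min(ess, S * C * log10(S * C))       # cap for antithetic chains
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction computed on rank-normalized, split chains, and
#' also on folded (absolute deviation from the median) rank-normalized split
#' chains; the larger of the two is returned, so both location and scale
#' disagreements between chains are detected. Constant draws yield `NaN`
#' with a warning.
#'
#' @param x numeric matrix of posterior draws, iterations x chains
#'   (at least 2 chains, 4 iterations).
#' @return Scalar R-hat (values near 1 indicate convergence; the usual
#'   acceptance threshold is R-hat < 1.01).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("rhat needs at least 2 chains")
  if (all(x == x[1])) {
    warning("constant draws: R-hat is undefined")
    return(NaN)
  }
  xs <- .split_chains(x)
  bulk <- .rhat_basic(.rank_normalize(xs))
  folded <- .rhat_basic(.rank_normalize(abs(xs - stats::median(xs))))
  max(bulk, folded)
}

#' Bulk and tail effective sample size
#'
#' `ess_bulk` is the effective sample size of the rank-normalized split
#' chains (sensitive to mixing in the body of the distribution). `ess_tail`
#' is the minimum of the effective sample sizes of the 5% and 95% quantile
#' exceedance indicators (sensitive to mixing in the tails). The reporting
#' convention used here requires both to exceed 400.
#'
#' @inheritParams rhat
#' @return Scalar effective sample size (`NaN` for constant draws).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (all(x == x[1])) {
    warning("constant draws: ESS is undefined")
    return(NaN)
  }
  .ess_basic(.rank_normalize(.split_chains(x)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  if (all(x == x[1])) {
    warning("constant draws: ESS is undefined")
    return(NaN)
  }
  xs <- .split_chains(x)
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  ess_q <- function(qv) {
    ind <- (xs <= qv) * 1
    if (all(ind == ind[1])) return(NaN)
    .ess_basic(ind)
  }
  min(ess_q(q[1]), ess_q(q[2]))
}

#' Posterior summary table
#'
#' Pools the post-warmup draws of every parameter across chains and reports
#' the posterior mean, standard deviation, 2.5 and 97.5 percentiles (the 95%
#' credible interval; linear interpolation), the positive and negative
#' coefficient probabilities (PCP counts draws strictly greater than 0;
#' draws exactly 0 count as negative, so PCP + NCP = 1 exactly), per-chain
#' convergence diagnostics ([rhat()], [ess_bulk()], [ess_tail()]), and
#' `ratio = exp(mean)` for regression coefficients (the RMEI / OR scale).
#'
#' @param chains a `zoib_chains` object from [sample_zoib()], or a 3-d array
#'   chains x iterations x parameters with named parameters.
#' @param ratio_params character vector of parameter names for which the
#'   exponentiated mean is reported; defaults to the regression coefficients
#'   (names starting `beta` or `gamma`) when `chains` is a `zoib_chains`
#'   object, else none.
#' @return Data frame of class `posterior_summary`, one row per parameter:
#'   `parameter, mean, sd, p2_5, p97_5, pcp, ncp, rhat, bulk_ess, tail_ess,
#'   ratio`.
#' @export
summarize_posterior <- function(chains, ratio_params = NULL) {
  draws <- if (inherits(chains, "zoib_chains")) chains$draws else chains
  pnames <- dimnames(draws)[[3]]
  if (is.null(pnames)) pnames <- paste0("par_", seq_len(dim(draws)[3]))
  if (is.null(ratio_params))
    ratio_params <- grep("^(beta|gamma)", pnames, value = TRUE)
  out <- lapply(seq_along(pnames), function(p) {
    m <- t(draws[, , p, drop = TRUE])   # iterations x chains
    if (dim(draws)[1] == 1) m <- matrix(draws[1, , p], ncol = 1)
    pooled <- as.vector(m)
    pcp <- mean(pooled > 0)
    data.frame(parameter = pnames[p],
               mean = mean(pooled),
               sd = stats::sd(pooled),
               p2_5 = stats::quantile(pooled, 0.025, names = FALSE),
               p97_5 = stats::quantile(pooled, 0.975, names = FALSE),
               pcp = pcp, ncp = 1 - pcp,
               rhat = if (ncol(m) >= 2) rhat(m) else NA_real_,
               bulk_ess = if (ncol(m) >= 2) ess_bulk(m) else NA_real_,
               tail_ess = if (ncol(m) >= 2) ess_tail(m) else NA_real_,
               ratio = if (pnames[p] %in% ratio_params)
                 exp(mean(pooled)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("posterior_summary", "data.frame")
  res
}

#' Convergence check against reporting thresholds
#'
#' Flags every monitored parameter whose rank-normalized split R-hat exceeds
#' `rhat_max` or whose bulk or tail effective sample size falls below
#' `ess_min`.
#'
#' @param summary a [summarize_posterior()] table.
#' @param rhat_max maximum acceptable R-hat (default 1.01).
#' @param ess_min minimum acceptable bulk and tail ESS (default 400).
#' @return Data frame `parameter, rhat_ok, ess_ok, converged`.
#' @export
convergence_check <- function(summary, rhat_max = 1.01, ess_min = 400) {
  rhat_ok <- is.finite(summary$rhat) & summary$rhat < rhat_max
  ess_ok <- is.finite(summary$bulk_ess) & is.finite(summary$tail_ess) &
    summary$bulk_ess > ess_min & summary$tail_ess > ess_min
  data.frame(parameter = summary$parameter,
             rhat_ok = rhat_ok, ess_ok = ess_ok,
             converged = rhat_ok & ess_ok,
             stringsAsFactors = FALSE)
}
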