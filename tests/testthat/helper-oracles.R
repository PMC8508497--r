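# Independent oracles and fixture generators used across test files.

# Brute-force oracle for the output-oriented BCC program: enumerate every
# candidate basis (support of lambda plus a set of tight input/output
# constraints containing at least one output constraint — at an optimum the
# expansion factor is always blocked by some output), solve the square
# linear system, keep the best feasible phi. Independent of the package's
# simplex path.
dea_oracle_phi <- function(X, Y, j0, tol = 1e-9) {
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  x0 <- X[j0, ]; y0 <- Y[j0, ]
  best <- 1                              # lambda = e_j0, phi = 1
  for (k in seq_len(min(n, m + s))) {
    supports <- utils::combn(n, k, simplify = FALSE)
    tights <- utils::combn(m + s, k, simplify = FALSE)
    for (S in supports) {
      for (T in tights) {
        if (!any(T > m)) next            # need a tight output constraint
        A <- matrix(0, k + 1, k + 1)
        b <- numeric(k + 1)
        A[1, seq_len(k)] <- 1
        b[1] <- 1
        for (ii in seq_along(T)) {
          ci <- T[ii]
          if (ci <= m) {
            A[ii + 1, seq_len(k)] <- X[S, ci]
            b[ii + 1] <- x0[ci]
          } else {
            r <- ci - m
            A[ii + 1, seq_len(k)] <- Y[S, r]
            A[ii + 1, k + 1] <- -y0[r]
          }
        }
        sol <- tryCatch(solve(A, b), error = function(e) NULL)
        if (is.null(sol)) next
        lam <- sol[seq_len(k)]
        phi <- sol[k + 1]
        if (!is.finite(phi) || any(lam < -tol)) next
        lamfull <- numeric(n)
        lamfull[S] <- lam
        if (any(colSums(lamfull * X) > x0 + 1e-8)) next
        if (any(colSums(lamfull * Y) < phi * y0 - 1e-8)) next
        if (phi > best) best <- phi
      }
    }
  }
  best
}

# small random production dataset with positive entries
random_production <- function(n, m, s) {
  production_dataset(matrix(exp(stats::rnorm(n * m, 0, 0.5)), n, m),
                     matrix(exp(stats::rnorm(n * s, 0, 0.5)), n, s))
}

# 3-unit textbook instance: evaluating C against the B vertex gives phi 3/2
toy_abc <- function() {
  production_dataset(cbind(x = c(1, 2, 2)), cbind(y = c(1, 3, 2)),
                     unit_ids = c("A", "B", "C"))
}
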