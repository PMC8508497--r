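# Dense two-phase primal simplex with Bland's anti-cycling rule.
# Sized for the BCC efficiency program: a handful of constraints, up to a few
# hundred variables. Not exported; the DEA front end is the public surface.

# One canonical-form pivot pass. `A` must be canonical w.r.t. `basis`
# (identity on basic columns); pivots keep it so.
.simplex_core <- function(A, b, cost, basis, tol = 1e-9, max_iter = 10000L,
                          allowed = ncol(A)) {
  m <- nrow(A)
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    r <- cost - as.vector(cb %*% A)
    r[basis] <- 0
    enter <- which(r[seq_len(allowed)] < -tol)
    if (!length(enter)) {
      return(list(A = A, b = b, basis = basis,
                  value = sum(cost[basis] * b), status = "optimal"))
    }
    e <- enter[1L]                       # Bland: lowest eligible index
    col <- A[, e]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(A = A, b = b, basis = basis, value = -Inf,
                  status = "unbounded"))
    }
    ratios <- b[pos] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    l <- cand[which.min(basis[cand])]    # Bland tie-break on leaving index
    # pivot at (l, e), eliminating column e from all other rows
    piv <- A[l, e]
    A[l, ] <- A[l, ] / piv
    b[l] <- b[l] / piv
    f <- A[, e]
    f[l] <- 0
    A <- A - outer(f, A[l, ])
    b <- b - f * b[l]
    b[b < 0 & b > -1e-11] <- 0           # absorb round-off on the RHS
    basis[l] <- e
  }
  stop("simplex iteration limit reached")
}

# Solve: optimize obj'x subject to A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0.
.lp_solve <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                      A3 = NULL, b3 = NULL, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  A <- rbind(A1, A2, A3)
  b <- c(b1, b2, b3)
  m <- nrow(A)
  rel <- c(rep(-1L, NROW(A1)), rep(1L, NROW(A2)), rep(0L, NROW(A3)))
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    rel[neg] <- -rel[neg]
  }
  # slack (+1) for <=, surplus (-1) for >=; artificials where no unit basis
  nslack <- sum(rel != 0L)
  S <- matrix(0, m, nslack)
  basis <- integer(m)
  need_art <- logical(m)
  j <- 0L
  for (i in seq_len(m)) {
    if (rel[i] == -1L) {
      j <- j + 1L
      S[i, j] <- 1
      basis[i] <- n + j
    } else if (rel[i] == 1L) {
      j <- j + 1L
      S[i, j] <- -1
      need_art[i] <- TRUE
    } else {
      need_art[i] <- TRUE
    }
  }
  nart <- sum(need_art)
  Ar <- matrix(0, m, nart)
  k <- 0L
  for (i in which(need_art)) {
    k <- k + 1L
    Ar[i, k] <- 1
    basis[i] <- n + nslack + k
  }
  Af <- cbind(A, S, Ar)
  nreal <- n + nslack

  if (nart > 0L) {
    c1 <- c(rep(0, nreal), rep(1, nart))
    ph1 <- .simplex_core(Af, b, c1, basis, tol = tol)
    if (ph1$status != "optimal" || ph1$value > 1e-7) {
      return(list(x = rep(NA_real_, n), value = NA_real_,
                  status = "infeasible"))
    }
    Af <- ph1$A
    b <- ph1$b
    basis <- ph1$basis
    # pivot any zero-level artificial out of the basis where possible
    for (i in which(basis > nreal)) {
      cols <- which(abs(Af[i, seq_len(nreal)]) > tol)
      if (length(cols)) {
        e <- cols[1L]
        piv <- Af[i, e]
        Af[i, ] <- Af[i, ] / piv
        b[i] <- b[i] / piv
        f <- Af[, e]
        f[i] <- 0
        Af <- Af - outer(f, Af[i, ])
        b <- b - f * b[i]
        basis[i] <- e
      }
    }
  }

  cobj <- if (maximize) -obj else obj
  c2 <- c(cobj, rep(0, ncol(Af) - n))
  ph2 <- .simplex_core(Af, b, c2, basis, tol = tol, allowed = nreal)
  if (ph2$status == "unbounded") {
    return(list(x = rep(NA_real_, n), value = NA_real_, status = "unbounded"))
  }
  x <- numeric(ncol(Af))
  x[ph2$basis] <- ph2$b
  list(x = x[seq_len(n)],
       value = if (maximize) -ph2$value else ph2$value,
       status = "optimal")
}
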