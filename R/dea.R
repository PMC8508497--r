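#' Production dataset for efficiency analysis
#'
#' Bundles the input and output quantities of a set of decision-making units
#' (DMUs; e.g. hospitals) for data envelopment analysis. All quantities must
#' be strictly positive and finite: the variables in this setting are counts,
#' staffed beds, personnel and monetary expenditure, none of which can be
#' zero for an operating unit, and the efficiency program assumes a positive
#' orthant technology.
#'
#' @param inputs numeric matrix (or data frame), one row per unit, one column
#'   per input; strictly positive.
#' @param outputs numeric matrix (or data frame), one row per unit, one
#'   column per output; strictly positive.
#' @param unit_ids character vector of unique unit identifiers; defaults to
#'   row names or `unit_1 ... unit_n`.
#' @return An object of class `production_dataset` with elements `inputs`,
#'   `outputs` and `unit_ids`.
#' @examples
#' pd <- production_dataset(inputs = cbind(beds = c(1, 2, 2)),
#'                          outputs = cbind(discharges = c(1, 3, 2)),
#'                          unit_ids = c("A", "B", "C"))
#' @export
production_dataset <- function(inputs, outputs, unit_ids = NULL) {
  inputs <- as.matrix(inputs)
  outputs <- as.matrix(outputs)
  storage.mode(inputs) <- "double"
  storage.mode(outputs) <- "double"
  n <- nrow(inputs)
  if (n < 1L || ncol(inputs) < 1L || ncol(outputs) < 1L)
    stop("need at least one unit, one input and one output")
  if (nrow(outputs) != n)
    stop("inputs and outputs must have the same number of rows")
  if (!all(is.finite(inputs)) || !all(is.finite(outputs)))
    stop("all inputs and outputs must be finite")
  if (any(inputs <= 0) || any(outputs <= 0))
    stop("all inputs and outputs must be strictly positive")
  if (is.null(unit_ids)) {
    unit_ids <- rownames(inputs)
    if (is.null(unit_ids)) unit_ids <- paste0("unit_", seq_len(n))
  }
  unit_ids <- as.character(unit_ids)
  if (length(unit_ids) != n) stop("unit_ids must have one entry per unit")
  if (anyDuplicated(unit_ids)) stop("unit_ids must be unique")
  structure(list(inputs = inputs, outputs = outputs, unit_ids = unit_ids),
            class = "production_dataset")
}

#' @export
print.production_dataset <- function(x, ...) {
  cat("Production dataset:", length(x$unit_ids), "units,",
      ncol(x$inputs), "inputs,", ncol(x$outputs), "outputs\n")
  invisible(x)
}

#' Output-oriented BCC efficiency score for one unit
#'
#' Solves the output-oriented, variable-returns-to-scale (BCC) envelopment
#' program for the unit under evaluation:
#' maximize the output expansion factor phi subject to
#' sum_j lambda_j x_ij <= x_i0 for every input i,
#' sum_j lambda_j y_rj >= phi y_r0 for every output r,
#' sum_j lambda_j = 1 and lambda_j >= 0.
#' The convexity constraint sum lambda = 1 is what imposes variable returns
#' to scale. Pure technical efficiency is 1/phi; phi = 1 (PTE = 1) means the
#' unit is on the frontier, and phi - 1 is the proportional output increase
#' attainable at its current input levels.
#'
#' The unit itself (lambda_unit = 1, phi = 1) is always feasible, so
#' phi >= 1 at the optimum; phi is clipped to max(phi, 1) before inversion to
#' absorb solver round-off, guaranteeing PTE in (0, 1].
#'
#' @param dataset a [production_dataset()].
#' @param unit integer index (1-based) or unit id of the unit to evaluate.
#' @param frontier_tol units with `pte >= 1 - frontier_tol` are flagged as on
#'   the frontier; default `1e-6`.
#' @param tol feasibility tolerance passed to the LP solver; default `1e-8`.
#' @return A list of class `dea_score` with `unit_id`, `phi`, `pte`,
#'   `lambdas` (intensity weights over all units, summing to 1) and
#'   `on_frontier`.
#' @examples
#' pd <- production_dataset(cbind(c(1, 2, 2)), cbind(c(1, 3, 2)),
#'                          unit_ids = c("A", "B", "C"))
#' solve_bcc_output(pd, "C")  # phi = 1.5, pte = 2/3, peer is B
#' @export
solve_bcc_output <- function(dataset, unit, frontier_tol = 1e-6, tol = 1e-8) {
  stopifnot(inherits(dataset, "production_dataset"))
  X <- dataset$inputs
  Y <- dataset$outputs
  n <- nrow(X)
  if (is.character(unit)) unit <- match(unit, dataset$unit_ids)
  if (is.na(unit) || unit < 1L || unit > n) stop("invalid unit index")
  s <- ncol(Y)
  obj <- c(1, rep(0, n))
  A1 <- cbind(0, t(X))                      # input constraints
  b1 <- X[unit, ]
  A2 <- cbind(-Y[unit, ], t(Y))             # output expansion constraints
  b2 <- rep(0, s)
  A3 <- matrix(c(0, rep(1, n)), nrow = 1)   # convexity (VRS)
  sol <- .lp_solve(obj, A1, b1, A2, b2, A3, 1, maximize = TRUE, tol = tol)
  if (sol$status != "optimal")
    stop("BCC program did not solve (", sol$status,
         "); this cannot occur for a valid production dataset")
  phi <- max(sol$x[1], 1)
  if (phi < 1 - 1e-9) stop("internal error: phi < 1")
  lam <- pmax(sol$x[-1], 0)
  lam <- lam / sum(lam)
  pte <- 1 / phi
  structure(list(unit_id = dataset$unit_ids[unit],
                 phi = phi, pte = pte, lambdas = lam,
                 on_frontier = pte >= 1 - frontier_tol),
            class = "dea_score")
}

#' @export
print.dea_score <- function(x, ...) {
  cat(sprintf("BCC output-oriented score for %s: phi = %.4f, PTE = %.4f%s\n",
              x$unit_id, x$phi, x$pte,
              if (x$on_frontier) " (on frontier)" else ""))
  invisible(x)
}

#' Run the BCC efficiency analysis over all units
#'
#' Solves the output-oriented BCC program for every unit in the dataset and
#' summarizes the resulting pure-technical-efficiency (PTE) distribution.
#'
#' @inheritParams solve_bcc_output
#' @return An object of class `dea_result`: a list with
#'   \describe{
#'     \item{scores}{data frame `unit_id, phi, pte, on_frontier`.}
#'     \item{lambdas}{n x n matrix of intensity weights (rows = evaluated
#'       unit).}
#'     \item{summary}{list with `mean_pte`, `n_frontier` and `pct_frontier`
#'       (percentage of units on the frontier).}
#'   }
#' @examples
#' pd <- production_dataset(cbind(c(1, 2, 2)), cbind(c(1, 3, 2)),
#'                          unit_ids = c("A", "B", "C"))
#' run_dea(pd)$summary
#' @export
run_dea <- function(dataset, frontier_tol = 1e-6, tol = 1e-8) {
  stopifnot(inherits(dataset, "production_dataset"))
  n <- nrow(dataset$inputs)
  scores <- vector("list", n)
  lambdas <- matrix(0, n, n, dimnames = list(dataset$unit_ids,
                                             dataset$unit_ids))
  for (j in seq_len(n)) {
    sc <- solve_bcc_output(dataset, j, frontier_tol = frontier_tol, tol = tol)
    scores[[j]] <- sc
    lambdas[j, ] <- sc$lambdas
  }
  df <- data.frame(unit_id = vapply(scores, `[[`, "", "unit_id"),
                   phi = vapply(scores, `[[`, 0, "phi"),
                   pte = vapply(scores, `[[`, 0, "pte"),
                   on_frontier = vapply(scores, `[[`, TRUE, "on_frontier"),
                   stringsAsFactors = FALSE)
  structure(list(scores = df, lambdas = lambdas,
                 summary = list(mean_pte = mean(df$pte),
                                n_frontier = sum(df$on_frontier),
                                pct_frontier = 100 * mean(df$on_frontier))),
            class = "dea_result")
}

#' @export
print.dea_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("BCC output-oriented DEA: %d units, mean PTE %.4f, ",
                     "%d on frontier (%.1f%%)\n"),
              nrow(x$scores), s$mean_pte, s$n_frontier, s$pct_frontier))
  invisible(x)
}

#' @export
summary.dea_result <- function(object, ...) object$summary
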