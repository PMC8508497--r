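# Two-stage orchestration: DEA scores -> covariate preparation ->
# posterior sampling -> Table-style report.

#' Standardize a covariate to mean zero, standard deviation one
#'
#' (x - mean(x)) / sd(x) with the sample standard deviation (denominator
#' n - 1), the convention used to make regression covariates dimensionless
#' so that coefficients read as the effect of a one-standard-deviation
#' increase.
#'
#' @param x numeric vector with at least two distinct values.
#' @param name column name used in the error message for constant input.
#' @return Standardized vector, mean 0 and sd 1 to machine precision.
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  if (length(unique(x)) < 2)
    stop("cannot standardize constant column: ", name)
  (x - mean(x)) / stats::sd(x)
}

#' Configuration for a two-stage efficiency study
#'
#' Collects every declarative choice of a run: which columns are DEA inputs
#' and outputs (or which precomputed column holds PTE), the grouping column,
#' the level-1 and level-2 regression covariates, factor columns with their
#' reference levels, prior and MCMC settings, the seed and output paths.
#'
#' @param dea_inputs,dea_outputs character vectors of column names for the
#'   DEA stage; leave `dea_inputs` empty and set `pte_column` to skip DEA
#'   and use a precomputed efficiency column instead.
#' @param pte_column optional name of a precomputed PTE column.
#' @param unit_column column holding unique unit identifiers.
#' @param group_column column mapping each unit to its group.
#' @param level1_columns,level2_columns quantitative covariate columns at
#'   each level; level-2 columns must be constant within group and are
#'   standardized across the J group values, not the n rows.
#' @param factor_columns named character vector: names are factor columns
#'   (level 1), values their reference category.
#' @param prior a [zoib_priors()] configuration or its name.
#' @param chains,warmup,iter MCMC settings (defaults 4, 1000, 5000).
#' @param seed master seed.
#' @param frontier_tol DEA frontier tolerance.
#' @param out_dir optional directory; when set, [fit_two_stage()] writes
#'   `dea_scores.csv`, `posterior_summary.csv`, `posterior_summary.json`
#'   and `run_log.txt` there.
#' @return A `study_config` list.
#' @export
study_config <- function(dea_inputs = character(), dea_outputs = character(),
                         pte_column = NULL, unit_column = NULL,
                         group_column, level1_columns = character(),
                         level2_columns = character(),
                         factor_columns = character(),
                         prior = "default", chains = 4, warmup = 1000,
                         iter = 5000, seed = 1, frontier_tol = 1e-6,
                         out_dir = NULL) {
  if (length(intersect(dea_inputs, dea_outputs)))
    stop("a column cannot be both a DEA input and a DEA output")
  if (!length(dea_inputs) && is.null(pte_column))
    stop("either DEA input/output columns or a precomputed pte_column ",
         "must be given")
  structure(list(dea_inputs = dea_inputs, dea_outputs = dea_outputs,
                 pte_column = pte_column, unit_column = unit_column,
                 group_column = group_column,
                 level1_columns = level1_columns,
                 level2_columns = level2_columns,
                 factor_columns = factor_columns, prior = prior,
                 chains = chains, warmup = warmup, iter = iter, seed = seed,
                 frontier_tol = frontier_tol, out_dir = out_dir),
            class = "study_config")
}

.check_columns <- function(data, config) {
  need <- c(config$dea_inputs, config$dea_outputs, config$pte_column,
            config$unit_column, config$group_column,
            config$level1_columns, config$level2_columns,
            names(config$factor_columns))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("columns not found in data: ",
                         paste(miss, collapse = ", "))
}

# build the hierarchical design from a data frame per the study config;
# level-2 covariates are standardized over the J group values
.build_design <- function(data, config) {
  group <- as.factor(data[[config$group_column]])
  J <- nlevels(group)
  X1 <- NULL
  for (fc in names(config$factor_columns)) {
    f <- as.factor(data[[fc]])
    ref <- config$factor_columns[[fc]]
    if (!ref %in% levels(f))
      stop("reference level ", ref, " not present in column ", fc)
    f <- stats::relevel(f, ref = ref)
    for (lev in levels(f)[-1]) {
      col <- matrix(as.numeric(f == lev), ncol = 1,
                    dimnames = list(NULL, paste0(fc, "_", lev)))
      X1 <- cbind(X1, col)
    }
  }
  for (cc in config$level1_columns) {
    col <- matrix(standardize(data[[cc]], cc), ncol = 1,
                  dimnames = list(NULL, cc))
    X1 <- cbind(X1, col)
  }
  X2 <- NULL
  for (cc in config$level2_columns) {
    v <- tapply(data[[cc]], group, function(z) {
      if (length(unique(z)) > 1)
        stop("level-2 column ", cc, " varies within group")
      z[1]
    })
    col <- matrix(standardize(as.vector(v), cc), ncol = 1,
                  dimnames = list(levels(group), cc))
    X2 <- cbind(X2, col)
  }
  hierarchical_design(group, X1, X2)
}

#' Fit the full two-stage efficiency model
#'
#' Stage one scores every unit with the output-oriented BCC program (or
#' accepts a precomputed PTE column, so the regression stage can be
#' validated independently); stage two classifies endpoint scores,
#' standardizes the declared quantitative covariates (level-2 covariates
#' across the J groups), dummy-codes factors against their reference
#' levels, samples the multilevel zero-one inflated beta posterior and
#' summarizes it with convergence diagnostics and ratio-scale effect
#' measures.
#'
#' If `config$out_dir` is set, the DEA scores, the posterior summary (CSV,
#' 2-decimal human-readable report plus full-precision JSON sidecar) and a
#' run log (seed, MCMC settings, convergence verdicts) are written there.
#'
#' @param data data frame, one row per unit.
#' @param config a [study_config()].
#' @return Object of class `two_stage_fit`: list with `dea` (the
#'   [run_dea()] result or `NULL`), `pte`, `design`, `chains`, `summary`
#'   ([summarize_posterior()] table), `convergence`
#'   ([convergence_check()] table), `converged` (logical) and `report`
#'   ([report_table()]).
#' @export
fit_two_stage <- function(data, config) {
  stopifnot(inherits(config, "study_config"))
  .check_columns(data, config)
  dea <- NULL
  if (length(config$dea_inputs)) {
    pd <- production_dataset(
      as.matrix(data[config$dea_inputs]),
      as.matrix(data[config$dea_outputs]),
      unit_ids = if (!is.null(config$unit_column))
        as.character(data[[config$unit_column]]) else NULL)
    dea <- run_dea(pd, frontier_tol = config$frontier_tol)
    pte <- dea$scores$pte
  } else {
    pte <- data[[config$pte_column]]
  }
  design <- .build_design(data, config)
  chains <- sample_zoib(design, pte, prior = config$prior,
                        chains = config$chains, warmup = config$warmup,
                        iter = config$iter, seed = config$seed)
  summ <- summarize_posterior(chains)
  monitored <- !grepl("^u\\[", summ$parameter)
  conv <- convergence_check(summ[monitored, ])
  rep_tab <- report_table(summ, factor_columns = config$factor_columns)
  fit <- structure(list(dea = dea, pte = pte, design = design,
                        chains = chains, summary = summ,
                        convergence = conv,
                        converged = all(conv$converged),
                        report = rep_tab, config = config),
                   class = "two_stage_fit")
  if (!is.null(config$out_dir)) .write_fit_outputs(fit, config)
  fit
}

#' @export
print.two_stage_fit <- function(x, ...) {
  if (!is.null(x$dea)) print(x$dea)
  cat(sprintf("ZOIB second stage: %d monitored parameters, convergence %s\n",
              nrow(x$convergence),
              if (x$converged) "passed" else "FAILED"))
  if (!x$converged)
    cat("  unconverged:",
        paste(x$convergence$parameter[!x$convergence$converged],
              collapse = ", "), "\n")
  invisible(x)
}

.write_fit_outputs <- function(fit, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(fit$dea))
    utils::write.csv(fit$dea$scores,
                     file.path(config$out_dir, "dea_scores.csv"),
                     row.names = FALSE)
  rep_round <- fit$report
  num <- vapply(rep_round, is.numeric, TRUE)
  rep_round[num] <- lapply(rep_round[num], round, 2)
  utils::write.csv(rep_round,
                   file.path(config$out_dir, "posterior_summary.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(fit$summary,
                       file.path(config$out_dir, "posterior_summary.json"),
                       dataframe = "rows", digits = NA, na = "null")
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("mcmc: %d chains, %d warmup, %d retained iterations",
            config$chains, config$warmup, config$iter),
    sprintf("prior config: %s",
            if (is.character(config$prior)) config$prior
            else config$prior$config),
    sprintf("convergence: %s",
            if (fit$converged) "all monitored parameters passed"
            else paste("FAILED for",
                       paste(fit$convergence$parameter[
                         !fit$convergence$converged], collapse = ", "))))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(fit)
}

#' Report table in the conventional second-stage layout
#'
#' Arranges the posterior summary into three sections — the average
#' efficiency index (mu-submodel) coefficients, the frontier-membership
#' (omega-submodel) coefficients, and the precision / one-inflation /
#' random-effect block — and appends `Reference` rows for the reference
#' levels of dummy-coded factors. The ratio column holds the RMEI for
#' mu-submodel coefficients and the OR for omega-submodel coefficients.
#'
#' @param summary a [summarize_posterior()] table.
#' @param factor_columns named character vector as in [study_config()]
#'   (names = factor columns, values = reference levels), used to render
#'   the reference rows.
#' @return Data frame with columns `section, parameter, coefficient,
#'   standard_error, ci_2.5, ci_97.5, PCP, NCP, Rhat, bulk_ESS, tail_ESS,
#'   RMEI_or_OR`; reference rows carry `NA` in numeric cells.
#' @export
report_table <- function(summary, factor_columns = character()) {
  row_of <- function(p, section) {
    s <- summary[summary$parameter == p, ]
    data.frame(section = section, parameter = p,
               coefficient = s$mean, standard_error = s$sd,
               ci_2.5 = s$p2_5, ci_97.5 = s$p97_5,
               PCP = s$pcp, NCP = s$ncp, Rhat = s$rhat,
               bulk_ESS = s$bulk_ess, tail_ESS = s$tail_ess,
               RMEI_or_OR = s$ratio, stringsAsFactors = FALSE)
  }
  ref_row <- function(fc, ref, section) {
    data.frame(section = section,
               parameter = paste0(fc, "_", ref, " (Reference)"),
               coefficient = NA_real_, standard_error = NA_real_,
               ci_2.5 = NA_real_, ci_97.5 = NA_real_, PCP = NA_real_,
               NCP = NA_real_, Rhat = NA_real_, bulk_ESS = NA_real_,
               tail_ESS = NA_real_, RMEI_or_OR = NA_real_,
               stringsAsFactors = FALSE)
  }
  pn <- summary$parameter
  mu_sec <- "Average Efficiency Index Model"
  om_sec <- "Probability of Being Situated on the Efficiency Frontier Model"
  ex_sec <- paste("Accuracy, Conditional Probability of Inflation one",
                  "and Random Effect")
  out <- list()
  for (p in grep("^beta", pn, value = TRUE)) out[[length(out) + 1]] <-
    row_of(p, mu_sec)
  for (fc in names(factor_columns)) out[[length(out) + 1]] <-
    ref_row(fc, factor_columns[[fc]], mu_sec)
  for (p in grep("^gamma", pn, value = TRUE)) out[[length(out) + 1]] <-
    row_of(p, om_sec)
  for (fc in names(factor_columns)) out[[length(out) + 1]] <-
    ref_row(fc, factor_columns[[fc]], om_sec)
  for (p in intersect(c("precision", "theta", "sigma_u0"), pn))
    out[[length(out) + 1]] <- row_of(p, ex_sec)
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(section = character(), parameter = character(),
               coefficient = numeric(), standard_error = numeric(),
               ci_2.5 = numeric(), ci_97.5 = numeric(), PCP = numeric(),
               NCP = numeric(), Rhat = numeric(), bulk_ESS = numeric(),
               tail_ESS = numeric(), RMEI_or_OR = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
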