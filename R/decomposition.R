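# Wagstaff decomposition of the concentration index.
#
# With a linear outcome model y = alpha + sum_k beta_k x_k + e, the index
# decomposes exactly as
#     C = sum_k (beta_k * xbar_k / mu) * C_k + 2*cov(e_hat, r)/mu
# where C_k is the covariate's own concentration index against the common
# wealth rank and the last term is the generalized concentration index of
# the OLS residual divided by mu. The identity is exact by bilinearity of
# covariance as long as every term uses the same ranks and the same
# (population) covariance.

#' Expand raw household columns into the standard covariate set
#'
#' Reference-codes the categorical covariates the way the reference
#' analysis tabulates them: male head, literate head, household size below
#' 4, poorest wealth quintile, urban residence and low-HDI province are the
#' reference levels. Head age enters linearly (per year) and the proportion
#' of male members as a 0-100 share.
#'
#' @param table Household `data.frame` carrying `head_age`, `head_female`,
#'   `head_illiterate`, `hh_size`, `prop_male`, `urban`, `hdi_category`,
#'   `wealth_quintile`.
#' @return List with `table` (dummies appended) and `spec`, a `data.frame`
#'   of `variable`, `group` (demographic / socioeconomic / ecological) and
#'   a human-readable `label` per covariate, in display order.
#' @export
expand_covariates <- function(table) {
  needed <- c("head_age", "head_female", "head_illiterate", "hh_size",
              "prop_male", "urban", "hdi_category", "wealth_quintile")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("missing column(s) for covariate expansion: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  table$hh_size_ge4 <- as.integer(table$hh_size >= 4)
  for (q in 2:5) {
    table[[paste0("quintile_", q)]] <- as.integer(table$wealth_quintile == q)
  }
  table$rural <- as.integer(table$urban == 0)
  table$hdi_middle <- as.integer(table$hdi_category == "middle")
  table$hdi_high <- as.integer(table$hdi_category == "high")
  spec <- data.frame(
    variable = c("head_age", "head_female", "prop_male",
                 "hh_size_ge4", "head_illiterate",
                 "quintile_2", "quintile_3", "quintile_4", "quintile_5",
                 "rural", "hdi_middle", "hdi_high"),
    group = c(rep("demographic", 3), rep("socioeconomic", 6),
              rep("ecological", 3)),
    label = c("Age of household head", "Female head", "Proportion of males (%)",
              "Household size 4+", "Illiterate head",
              "Poor (Q2)", "Middle (Q3)", "Rich (Q4)", "Richest (Q5)",
              "Rural", "Middle HDI", "High HDI"),
    stringsAsFactors = FALSE
  )
  list(table = table, spec = spec)
}

#' Fit the linear outcome model behind the decomposition
#'
#' Ordinary least squares of the outcome on a set of numeric covariates
#' (categoricals must already be reference-coded to 0/1 indicators, e.g.
#' via [expand_covariates()]). Coefficient p-values use
#' heteroskedasticity-robust (HC1) standard errors with a normal reference
#' distribution.
#'
#' @param table Household `data.frame`.
#' @param covariates Character vector of numeric covariate columns.
#' @param outcome Outcome column name (default `"tehb"`).
#' @return An `outcome_model`: list with `alpha`, `beta` (named),
#'   `residuals`, `fitted`, `se`, `p_value`, `n`, `outcome`, `covariates`.
#' @export
fit_outcome_model <- function(table, covariates, outcome = "tehb") {
  stopifnot(is.data.frame(table), length(covariates) >= 1)
  missing_cols <- setdiff(c(outcome, covariates), names(table))
  if (length(missing_cols)) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[covariates])
  if (!is.numeric(x) || anyNA(x)) {
    stop("covariates must be numeric with no missing values", call. = FALSE)
  }
  y <- table[[outcome]]
  design <- cbind(`(Intercept)` = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = y, x, check.names = FALSE)
  fit <- stats::lm(
    stats::as.formula(paste0(".y ~ `", paste(covariates, collapse = "` + `"), "`")),
    data = dat)
  vc <- quiet_perfect_fit(sandwich::vcovHC(fit, type = "HC1"))
  se <- sqrt(diag(vc))
  coefs <- stats::coef(fit)
  pz <- 2 * stats::pnorm(-abs(coefs / se))
  names(coefs) <- names(se) <- names(pz) <- gsub("`", "", names(coefs))
  structure(list(
    alpha = unname(coefs["(Intercept)"]),
    beta = coefs[covariates],
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    se = se[covariates],
    p_value = pz[covariates],
    n = length(y),
    outcome = outcome,
    covariates = covariates
  ), class = "outcome_model")
}

#' Concentration index of each covariate against a common rank
#'
#' Applies the covariance-form index `2*cov(x_k, r)/mean(x_k)` to each
#' covariate (0/1 indicators included) using the shared wealth rank. A
#' negative covariate index means that covariate is concentrated among the
#' poor. Covariates with zero mean have an undefined index and come back as
#' `NA` with a warning.
#'
#' @param table Household `data.frame`.
#' @param covariates Character vector of numeric covariate columns.
#' @param rank Fractional ranks aligned with `table` rows.
#' @return Named numeric vector of covariate concentration indices.
#' @export
covariate_concentration_indices <- function(table, covariates, rank) {
  stopifnot(nrow(table) == length(rank))
  vapply(covariates, function(v) {
    x <- table[[v]]
    if (is.null(x)) stop("column not found: ", v, call. = FALSE)
    xbar <- mean(x)
    if (abs(xbar) <= 1e-10 * max(abs(x), 1)) {
      warning("covariate ", v, " has zero mean; its concentration index is undefined",
              call. = FALSE)
      return(NA_real_)
    }
    2 * pop_cov(x, rank) / xbar
  }, numeric(1))
}

#' Wagstaff decomposition of the concentration index
#'
#' Fits the linear outcome model, computes each covariate's elasticity
#' `beta_k * xbar_k / mu` and concentration index `C_k`, and assembles the
#' decomposition table: absolute contribution `elasticity * C_k`, relative
#' contribution `100 * abs / C`, and the residual term
#' `2*cov(e_hat, r)/mu` (the generalized concentration index of the OLS
#' residual over the mean). The adding-up identity
#' `sum(contributions) + residual = C` holds to floating point; it is
#' verified, not imposed.
#'
#' Covariates with zero mean are dropped from the table with a warning and
#' their `beta_k * 2*cov(x_k, r) / mu` term folded into the residual so the
#' identity stays exact.
#'
#' @param table Household `data.frame`.
#' @param covariates Character vector of numeric covariate columns, or a
#'   `data.frame` with columns `variable` and `group` (and optionally
#'   `label`) as produced by [expand_covariates()].
#' @param rank Fractional ranks aligned with `table` rows (the wealth-score
#'   ranks in the reference analysis).
#' @param outcome Outcome column name (default `"tehb"`).
#' @return A `decomposition_table`: list with `rows` (one `data.frame` row
#'   per covariate: `variable`, `group`, `beta`, `p_value`, `xbar`,
#'   `elasticity`, `c_k`, `abs_contribution`, `rel_contribution_pct`),
#'   `residual`, `total_c`, `sum_contributions`, `sum_rel_pct`,
#'   `residual_rel_pct`, `n`, `model`.
#' @export
decompose_cindex <- function(table, covariates, rank, outcome = "tehb") {
  if (is.data.frame(covariates)) {
    spec <- covariates
    stopifnot(all(c("variable", "group") %in% names(spec)))
  } else {
    spec <- data.frame(variable = covariates, group = "covariate",
                       stringsAsFactors = FALSE)
  }
  if (!"label" %in% names(spec)) spec$label <- spec$variable
  vars <- spec$variable
  stopifnot(nrow(table) == length(rank))

  model <- fit_outcome_model(table, vars, outcome = outcome)
  y <- table[[outcome]]
  mu <- mean(y)
  if (mu == 0) stop("outcome mean is zero; decomposition undefined", call. = FALSE)
  total_c <- 2 * pop_cov(y, rank) / mu

  xbar <- vapply(vars, function(v) mean(table[[v]]), numeric(1))
  c_k <- suppressWarnings(covariate_concentration_indices(table, vars, rank))
  elasticity <- unname(model$beta) * xbar / mu
  abs_contribution <- elasticity * c_k

  residual <- 2 * pop_cov(model$residuals, rank) / mu
  degenerate <- is.na(c_k)
  if (any(degenerate)) {
    warning("dropping zero-mean covariate(s) from the decomposition table: ",
            paste(vars[degenerate], collapse = ", "), call. = FALSE)
    # fold their (well-defined) generalized contribution into the residual
    for (v in vars[degenerate]) {
      residual <- residual +
        2 * unname(model$beta[v]) * pop_cov(table[[v]], rank) / mu
    }
  }

  keep <- !degenerate
  rows <- data.frame(
    variable = spec$label[keep],
    group = spec$group[keep],
    beta = unname(model$beta)[keep],
    p_value = unname(model$p_value)[keep],
    xbar = unname(xbar)[keep],
    elasticity = unname(elasticity)[keep],
    c_k = unname(c_k)[keep],
    abs_contribution = unname(abs_contribution)[keep],
    stringsAsFactors = FALSE
  )
  if (total_c != 0) {
    rows$rel_contribution_pct <- 100 * rows$abs_contribution / total_c
    residual_rel_pct <- 100 * residual / total_c
  } else {
    rows$rel_contribution_pct <- NA_real_
    residual_rel_pct <- NA_real_
  }
  structure(list(
    rows = rows,
    residual = residual,
    total_c = total_c,
    sum_contributions = sum(rows$abs_contribution),
    sum_rel_pct = if (total_c != 0) 100 * sum(rows$abs_contribution) / total_c else NA_real_,
    residual_rel_pct = residual_rel_pct,
    n = model$n,
    model = model
  ), class = "decomposition_table")
}

#' @export
print.decomposition_table <- function(x, ...) {
  cat(sprintf("Wagstaff decomposition (n = %d): C = %.4f\n", x$n, x$total_c))
  out <- x$rows
  out$stars <- significance_stars(out$p_value)
  num <- c("beta", "xbar", "elasticity", "c_k", "abs_contribution",
           "rel_contribution_pct")
  out[num] <- lapply(out[num], function(v) round(v, 4))
  print(out[c("variable", "group", "beta", "stars", "elasticity", "c_k",
              "abs_contribution", "rel_contribution_pct")], row.names = FALSE)
  cat(sprintf("Sum      %.4f  (%.1f%%)\n", x$sum_contributions, x$sum_rel_pct))
  cat(sprintf("Residual %.4f  (%.1f%%)\n", x$residual, x$residual_rel_pct))
  cat(sprintf("Total    %.4f  (100%%)\n", x$total_c))
  invisible(x)
}

# Three-level star convention: 1% / 5% / 10%.
significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}

#' Audit a decomposition cell from printed inputs
#'
#' Pure arithmetic helper: from a printed elasticity, covariate
#' concentration index and total index, recompute the absolute contribution
#' `elasticity * c_k` and the relative contribution
#' `100 * elasticity * c_k / total_c`. Used to check published
#' decomposition tables cell by cell.
#'
#' @param elasticity Printed elasticity `beta_k * xbar_k / mu`.
#' @param c_k Printed covariate concentration index.
#' @param total_c Printed total concentration index (nonzero).
#' @return Named numeric vector `c(abs_contribution, rel_pct)`.
#' @export
#' @examples
#' contribution_audit(0.117, 0.055, -0.142)  # rural-type cell
contribution_audit <- function(elasticity, c_k, total_c) {
  if (total_c == 0) stop("total_c must be nonzero", call. = FALSE)
  abs_contribution <- elasticity * c_k
  c(abs_contribution = abs_contribution,
    rel_pct = 100 * abs_contribution / total_c)
}
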