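# Concentration curves and the convenient-regression concentration index.
#
# The index C is twice the covariance between an outcome and the
# household's fractional socioeconomic rank, divided by the outcome mean.
# It is estimated here by the convenient regression
#     2 * sigma_r^2 * (y_i / mu) = alpha + phi * r_i + e_i
# whose OLS slope phi-hat is algebraically identical to 2*cov(y, r)/mu when
# sigma_r^2 is the population (divide-by-n) variance of the realized ranks;
# the regression form additionally yields a standard error.

#' Concentration index by convenient regression
#'
#' Regresses `2 * sigma_r^2 * (y / mu)` on the fractional rank `r` by OLS
#' and returns the slope as the concentration index, with a
#' heteroskedasticity-robust (HC1) standard error and normal-approximation
#' 95% confidence interval by default. The covariance-form value
#' `2 * cov(y, r) / mu` is recorded alongside; the two agree to floating
#' point on every input.
#'
#' Negative values mean the outcome is concentrated among poorer
#' households (pro-poor); positive among richer. For a non-negative outcome
#' the index lies in [-1, 1]. The index is invariant to scaling of `y` but
#' not to adding a constant.
#'
#' @param y Numeric outcome vector (the tobacco budget share, in percent,
#'   in the reference analysis).
#' @param rank Fractional socioeconomic ranks aligned with `y`, e.g. from
#'   [fractional_rank()].
#' @param se_type `"HC1"` (default), `"HAC"` (serial-correlation robust,
#'   for ordered/clustered draws) or `"classical"`.
#' @param conf_level Confidence level for the normal CI.
#' @param subgroup_label Label carried into printed/tabulated output.
#' @return A `concentration_result`: list with `c_hat`, `intercept`, `mu`,
#'   `sigma2_r`, `se`, `ci_low`, `ci_high`, `n`, `cov_form`,
#'   `subgroup_label`.
#' @export
#' @examples
#' y <- c(1, 2, 3, 4)
#' r <- c(0.25, 0.5, 0.75, 1)
#' concentration_index(y, r)$c_hat  # 0.25
concentration_index <- function(y, rank, se_type = c("HC1", "HAC", "classical"),
                                conf_level = 0.95, subgroup_label = "all") {
  se_type <- match.arg(se_type)
  stopifnot(length(y) == length(rank))
  if (anyNA(y) || anyNA(rank)) stop("missing values in y or rank", call. = FALSE)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  mu <- mean(y)
  if (mu == 0) stop("outcome mean is zero; index undefined", call. = FALSE)
  sigma2_r <- pop_var(rank)
  if (sigma2_r == 0) stop("degenerate ranks: zero variance", call. = FALSE)

  z <- 2 * sigma2_r * (y / mu)
  fit <- stats::lm(z ~ rank)
  vc <- quiet_perfect_fit(switch(se_type,
               HC1 = sandwich::vcovHC(fit, type = "HC1"),
               HAC = sandwich::vcovHAC(fit),
               classical = stats::vcov(fit)))
  se <- sqrt(vc["rank", "rank"])
  c_hat <- unname(stats::coef(fit)["rank"])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    c_hat = c_hat,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    mu = mu,
    sigma2_r = sigma2_r,
    se = se,
    ci_low = c_hat - zq * se,
    ci_high = c_hat + zq * se,
    n = n,
    cov_form = 2 * pop_cov(y, rank) / mu,
    subgroup_label = subgroup_label
  ), class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("Concentration index [%s]: C = %.4f (SE %.4f, 95%% CI %.4f to %.4f), n = %d\n",
              x$subgroup_label, x$c_hat, x$se, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Concentration curve
#'
#' Orders households from poorest to richest by fractional rank and
#' accumulates outcome shares: the curve plots the cumulative population
#' proportion `p` against the cumulative outcome share `L(p)`, from (0, 0)
#' to (1, 1). Tied ranks are pooled into a single step. The curve lies
#' above the 45-degree line of equality when the outcome is concentrated
#' among the poor.
#'
#' @param y Non-negative outcome vector with `sum(y) > 0`.
#' @param rank Fractional ranks aligned with `y`.
#' @return A `concentration_curve`: data.frame with columns `p` and `L`.
#' @export
concentration_curve <- function(y, rank) {
  stopifnot(length(y) == length(rank))
  if (any(y < 0)) stop("outcome must be non-negative for a concentration curve",
                       call. = FALSE)
  if (sum(y) == 0) stop("sum(y) is zero; curve undefined", call. = FALSE)
  agg_y <- tapply(y, rank, sum)
  agg_n <- tapply(rep(1L, length(y)), rank, sum)
  o <- order(as.numeric(names(agg_y)))
  curve <- data.frame(
    p = c(0, cumsum(as.numeric(agg_n[o])) / length(y)),
    L = c(0, cumsum(as.numeric(agg_y[o])) / sum(y))
  )
  class(curve) <- c("concentration_curve", "data.frame")
  curve
}

#' Twice the signed area between the diagonal and a concentration curve
#'
#' Trapezoid-rule evaluation of `2 * integral(p - L(p)) dp`; converges to
#' the concentration index as the sample grows (discretization error is
#' O(1/n)). Used as an internal cross-check of the regression estimator.
#'
#' @param curve A [concentration_curve()] result.
#' @return A single number.
#' @export
curve_area_index <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  p <- curve$p
  d <- p - curve$L
  2 * sum(diff(p) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Concentration indices by subgroup
#'
#' Computes the pooled (national) concentration index and one index per
#' level of a grouping column. Each subgroup is treated as a self-contained
#' sample: fractional ranks are recomputed within the subgroup from the
#' wealth score before the index is estimated. Levels with fewer than 3
#' households are skipped with a warning.
#'
#' @param table Household `data.frame` with the outcome and score columns.
#' @param group_col Name of the grouping column (e.g. `"urban"` or
#'   `"hdi_category"`); use `NULL` for the pooled result only.
#' @param outcome Outcome column name (default `"tehb"`).
#' @param score_col Wealth-score column used for ranking.
#' @param ... Passed to [concentration_index()].
#' @return A list of `concentration_result` objects, first element the
#'   pooled sample (label `"all"`), then one per subgroup level.
#' @export
subgroup_concentration <- function(table, group_col = NULL, outcome = "tehb",
                                   score_col = "wealth_score", ...) {
  stopifnot(is.data.frame(table))
  for (col in c(outcome, score_col, group_col)) {
    if (!col %in% names(table)) {
      stop("column not found: ", col, call. = FALSE)
    }
  }
  one <- function(sub, label) {
    concentration_index(sub[[outcome]], fractional_rank(sub[[score_col]]),
                        subgroup_label = label, ...)
  }
  results <- list(all = one(table, "all"))
  if (!is.null(group_col)) {
    for (lev in sort(unique(table[[group_col]]))) {
      sub <- table[table[[group_col]] == lev, ]
      label <- paste0(group_col, "=", lev)
      if (nrow(sub) < 3) {
        warning("subgroup ", label, " has fewer than 3 households; skipped",
                call. = FALSE)
        next
      }
      results[[label]] <- one(sub, label)
    }
  }
  results
}

#' Tabulate a list of concentration results
#'
#' @param results List of `concentration_result` objects, e.g. from
#'   [subgroup_concentration()].
#' @return A `data.frame` with columns `subgroup`, `n`, `c_hat`, `se`,
#'   `ci_low`, `ci_high`, `mu`.
#' @export
cindex_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(subgroup = r$subgroup_label, n = r$n, c_hat = r$c_hat,
               se = r$se, ci_low = r$ci_low, ci_high = r$ci_high, mu = r$mu,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
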