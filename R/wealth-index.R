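# Asset-based wealth index: first principal component of standardized
# asset/housing indicators, oriented so higher = richer, plus quintile
# classes and the fractional socioeconomic rank used by the concentration
# index.

#' Fit a PCA wealth index from asset indicators
#'
#' Standardizes each indicator to zero mean and unit variance (PCA on the
#' correlation structure, since asset batteries mix binaries, counts and
#' areas), extracts the first principal component, and orients its sign so
#' the score correlates positively with the plain sum of the indicators
#' (higher score = richer). Quintile cut points of the training-score
#' distribution are recorded so new households can be classified.
#'
#' @param table Household `data.frame`.
#' @param indicators Character vector (>= 2) of numeric indicator columns.
#' @return An object of class `wealth_model` with elements
#'   `indicator_names`, `indicator_means`, `indicator_scales`, `loadings`
#'   (unit norm, orientation already applied), `orientation` (+1/-1),
#'   `variance_explained`, and `quintile_cuts` (4 ascending thresholds).
#' @export
#' @examples
#' cfg <- synthetic_config(n_households = 400, seed = 7)
#' hh <- generate_households(cfg)
#' wm <- fit_wealth_index(hh, grep("^asset_", names(hh), value = TRUE))
#' wm$variance_explained
fit_wealth_index <- function(table, indicators) {
  stopifnot(is.data.frame(table))
  if (length(indicators) < 2) {
    stop("need at least 2 indicators to fit a wealth index", call. = FALSE)
  }
  missing_cols <- setdiff(indicators, names(table))
  if (length(missing_cols)) {
    stop("indicator column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[indicators])
  if (!is.numeric(x) || anyNA(x)) {
    stop("indicators must be numeric with no missing values", call. = FALSE)
  }
  if (nrow(x) <= length(indicators)) {
    stop("need more households than indicators (n = ", nrow(x),
         ", indicators = ", length(indicators), ")", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance indicator(s): ",
         paste(indicators[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, 1]
  score <- pc$x[, 1]
  orientation <- sign(stats::cov(score, rowSums(x)))
  if (orientation == 0) orientation <- 1
  loadings <- orientation * loadings
  score <- orientation * score
  model <- structure(list(
    indicator_names = indicators,
    indicator_means = stats::setNames(pc$center, indicators),
    indicator_scales = stats::setNames(pc$scale, indicators),
    loadings = stats::setNames(loadings, indicators),
    orientation = orientation,
    variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    quintile_cuts = unname(stats::quantile(score, c(0.2, 0.4, 0.6, 0.8)))
  ), class = "wealth_model")
  model
}

#' @export
print.wealth_model <- function(x, ...) {
  cat("PCA wealth index:", length(x$indicator_names), "indicators,",
      sprintf("%.1f%% variance explained\n", 100 * x$variance_explained))
  cat("loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

# Score households under a fitted model.
predict_wealth_score <- function(model, table) {
  missing_cols <- setdiff(model$indicator_names, names(table))
  if (length(missing_cols)) {
    stop("missing indicator column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[model$indicator_names])
  z <- sweep(sweep(x, 2, model$indicator_means), 2, model$indicator_scales, "/")
  drop(z %*% model$loadings)
}

#' Append wealth score and SES quintile to a household table
#'
#' Scores every household under `model` and assigns population-share
#' quintiles of the score within `table` (about n/5 households per class,
#' poorest = 1 to richest = 5). Cut points are the 20/40/60/80% quantiles of
#' the scores being classified; households with exactly tied scores always
#' share a quintile, so class sizes depart from n/5 by at most the number
#' of boundary ties (all-identical scores collapse into a single class).
#'
#' @param table Household `data.frame` containing all model indicators.
#' @param model A [fit_wealth_index()] result.
#' @return `table` with `wealth_score` and `wealth_quintile` appended.
#' @export
score_and_classify <- function(table, model) {
  stopifnot(inherits(model, "wealth_model"))
  score <- predict_wealth_score(model, table)
  cuts <- stats::quantile(score, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  table$wealth_score <- score
  table$wealth_quintile <- 1L + as.integer(rowSums(outer(score, cuts, ">")))
  table
}

#' Fractional socioeconomic rank
#'
#' Households sorted ascending by score receive rank i/n; tied scores
#' receive the mean of their positions divided by n. Ranks are returned in
#' the original input order and lie in (0, 1]. Any strictly monotone
#' transform of the scores yields identical ranks.
#'
#' @param scores Numeric vector of wealth scores (no missing values).
#' @return Numeric vector of fractional ranks aligned with `scores`.
#' @export
#' @examples
#' fractional_rank(c(10, 20, 30, 40))  # 0.25 0.50 0.75 1.00
#' fractional_rank(c(5, 5, 7))         # 0.50 0.50 1.00
fractional_rank <- function(scores) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  rank(scores, ties.method = "average") / length(scores)
}

#' Midpoint fractional rank
#'
#' The common alternative convention (2i - 1) / (2n): a constant shift of
#' the plain i/n rank by 1/(2n), so both conventions give the identical
#' concentration index (the index depends on ranks only through a
#' covariance).
#'
#' @inheritParams fractional_rank
#' @return Numeric vector of midpoint ranks in (0, 1).
#' @export
fractional_rank_midpoint <- function(scores) {
  fractional_rank(scores) - 1 / (2 * length(scores))
}

#' Serialize / restore a wealth model as flat text
#'
#' @param model A `wealth_model`.
#' @param path Output path (CSV key-value file).
#' @return `path` invisibly; `read_wealth_model()` returns the model.
#' @export
write_wealth_model <- function(model, path) {
  stopifnot(inherits(model, "wealth_model"))
  rows <- data.frame(
    field = c(rep("indicator", length(model$indicator_names)),
              "orientation", "variance_explained",
              rep("quintile_cut", 4L)),
    name = c(model$indicator_names, "", "", paste0("q", 1:4)),
    mean = c(unname(model$indicator_means), NA, NA, rep(NA, 4L)),
    scale = c(unname(model$indicator_scales), NA, NA, rep(NA, 4L)),
    loading = c(unname(model$loadings), NA, NA, rep(NA, 4L)),
    value = c(rep(NA, length(model$indicator_names)),
              model$orientation, model$variance_explained,
              model$quintile_cuts)
  )
  utils::write.csv(format(rows, digits = 17), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wealth_model
#' @export
read_wealth_model <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  ind <- rows[rows$field == "indicator", ]
  structure(list(
    indicator_names = trimws(ind$name),
    indicator_means = stats::setNames(as.numeric(ind$mean), trimws(ind$name)),
    indicator_scales = stats::setNames(as.numeric(ind$scale), trimws(ind$name)),
    loadings = stats::setNames(as.numeric(ind$loading), trimws(ind$name)),
    orientation = as.numeric(rows$value[rows$field == "orientation"]),
    variance_explained = as.numeric(rows$value[rows$field == "variance_explained"]),
    quintile_cuts = as.numeric(rows$value[rows$field == "quintile_cut"])
  ), class = "wealth_model")
}
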