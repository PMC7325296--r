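# Data ingestion, sample preparation, descriptive tables and pipeline
# orchestration.

required_household_cols <- function() {
  c("household_id", "head_age", "head_female", "head_illiterate", "hh_size",
    "prop_male", "urban", "province_id", "total_expenditure",
    "tobacco_expenditure")
}

#' Load and validate a household microdata file
#'
#' Reads a comma-separated household table, checks the schema (required
#' columns present, numeric where expected, expenditures coherent) and
#' joins the province-to-HDI-category lookup. Violations are reported with
#' the offending row numbers.
#'
#' @param path CSV of household records (header row; one row per
#'   household).
#' @param hdi_lookup_path CSV mapping `province_id` to `hdi_category`
#'   (`low`/`middle`/`high`). Defaults to the 31-province lookup shipped
#'   with the package. Ignored if the table already has an `hdi_category`
#'   column.
#' @return Validated household `data.frame` with `hdi_category` attached.
#' @export
load_households <- function(path, hdi_lookup_path = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_household_cols(), names(tab))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- setdiff(required_household_cols(), "household_id")
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing `%s` in row(s): %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    }
    tab[[col]] <- v
  }
  bad <- which(tab$total_expenditure <= 0)
  if (length(bad)) {
    stop("total_expenditure must be > 0; violated in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(tab$tobacco_expenditure < 0 |
                 tab$tobacco_expenditure > tab$total_expenditure)
  if (length(bad)) {
    stop("tobacco_expenditure must lie in [0, total_expenditure]; violated in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (!"hdi_category" %in% names(tab)) {
    if (is.null(hdi_lookup_path)) {
      hdi_lookup_path <- system.file("extdata", "province_hdi.csv",
                                     package = "concindex")
    }
    lookup <- utils::read.csv(hdi_lookup_path, stringsAsFactors = FALSE)
    stopifnot(all(c("province_id", "hdi_category") %in% names(lookup)))
    idx <- match(tab$province_id, lookup$province_id)
    if (anyNA(idx)) {
      stop("province_id values absent from the HDI lookup: ",
           paste(unique(tab$province_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    tab$hdi_category <- lookup$hdi_category[idx]
  }
  bad_hdi <- setdiff(unique(tab$hdi_category), c("low", "middle", "high"))
  if (length(bad_hdi)) {
    stop("unknown hdi_category value(s): ", paste(bad_hdi, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Restrict to tobacco-spending households and derive the budget share
#'
#' Derives `tehb = 100 * tobacco_expenditure / total_expenditure` (percent
#' of the monthly budget) and keeps only households with positive tobacco
#' expenditure, mirroring the reference analysis's inclusion rule. The
#' number of dropped households is attached as attribute `n_dropped` and
#' reported via `message()`.
#'
#' @param table Validated household `data.frame`.
#' @return The analysis subsample with `tehb` appended.
#' @export
prepare_analysis_sample <- function(table) {
  stopifnot(all(c("tobacco_expenditure", "total_expenditure") %in% names(table)))
  keep <- table$tobacco_expenditure > 0
  if (!any(keep)) stop("no households with positive tobacco expenditure",
                       call. = FALSE)
  out <- table[keep, , drop = FALSE]
  out$tehb <- 100 * out$tobacco_expenditure / out$total_expenditure
  n_dropped <- sum(!keep)
  stopifnot(nrow(out) + n_dropped == nrow(table))  # row-count conservation
  attr(out, "n_dropped") <- n_dropped
  message(sprintf("retained %d spender household(s); dropped %d with zero tobacco expenditure",
                  nrow(out), n_dropped))
  out
}

# Stratum definitions used by descriptive_table(): each maps the raw
# column onto display levels.
stratum_levels <- function(table, stratum) {
  switch(stratum,
    head_female = factor(ifelse(table$head_female == 1, "Female", "Male"),
                         levels = c("Male", "Female")),
    head_illiterate = factor(ifelse(table$head_illiterate == 1, "Illiterate",
                                    "Literate"),
                             levels = c("Illiterate", "Literate")),
    hh_size = factor(ifelse(table$hh_size >= 4, "4 and above", "Less than 4"),
                     levels = c("Less than 4", "4 and above")),
    wealth_quintile = factor(c("Poorest", "Poor", "Middle", "Rich",
                               "Richest")[table$wealth_quintile],
                             levels = c("Poorest", "Poor", "Middle", "Rich",
                                        "Richest")),
    urban = factor(ifelse(table$urban == 1, "Urban", "Rural"),
                   levels = c("Urban", "Rural")),
    hdi_category = factor(table$hdi_category,
                          levels = c("low", "middle", "high"),
                          labels = c("Low", "Middle", "High")),
    stop("unknown stratum column: ", stratum, call. = FALSE)
  )
}

#' Descriptive table of the analysis sample
#'
#' For each stratification variable, reports per level the household count,
#' its percentage of the sample, and the mean and SD of the outcome, plus
#' an overall row. Between-group significance tests are deliberately not
#' computed; the `p_value` column is emitted empty for layout
#' compatibility. Singleton strata get SD 0 by convention and a flag.
#'
#' @param table Analysis sample (after [prepare_analysis_sample()] and
#'   [score_and_classify()] if quintiles are stratified on).
#' @param strata Character vector of stratification columns; any of
#'   `head_female`, `head_illiterate`, `hh_size`, `wealth_quintile`,
#'   `urban`, `hdi_category`.
#' @param outcome Outcome column (default `"tehb"`).
#' @return `data.frame` with columns `stratum`, `level`, `n`, `pct`,
#'   `mean`, `sd`, `p_value`, `flag`.
#' @export
descriptive_table <- function(table,
                              strata = c("head_female", "head_illiterate",
                                         "hh_size", "wealth_quintile",
                                         "urban", "hdi_category"),
                              outcome = "tehb") {
  stopifnot(outcome %in% names(table))
  y <- table[[outcome]]
  one_level <- function(stratum, level, idx) {
    n <- sum(idx)
    sd_y <- if (n > 1) stats::sd(y[idx]) else 0
    data.frame(stratum = stratum, level = level, n = n,
               pct = 100 * n / nrow(table),
               mean = mean(y[idx]), sd = sd_y, p_value = "",
               flag = if (n == 1) "single household" else "",
               stringsAsFactors = FALSE)
  }
  rows <- list(data.frame(stratum = "overall", level = "All", n = nrow(table),
                          pct = 100, mean = mean(y),
                          sd = if (nrow(table) > 1) stats::sd(y) else 0,
                          p_value = "", flag = "", stringsAsFactors = FALSE))
  for (stratum in strata) {
    if (!stratum %in% names(table)) {
      stop("unknown stratum column: ", stratum, call. = FALSE)
    }
    f <- stratum_levels(table, stratum)
    for (lev in levels(f)) {
      idx <- !is.na(f) & f == lev
      if (!any(idx)) next
      rows[[length(rows) + 1L]] <- one_level(stratum, lev, idx)
    }
  }
  do.call(rbind, rows)
}

#' Run the full inequality pipeline and write its artifacts
#'
#' Orchestrates: load -> spender filter -> wealth-index PCA -> quintiles and
#' fractional ranks -> descriptive table -> national and subgroup
#' concentration indices -> concentration curves -> Wagstaff decomposition.
#' All outputs are comma-separated text; a run log records the row counts at
#' each stage, the seed and a hash of the resolved configuration.
#'
#' @param households Path to a household CSV, or an in-memory household
#'   `data.frame`.
#' @param out_dir Output directory (created if needed).
#' @param hdi_lookup_path Optional lookup CSV; see [load_households()].
#' @param indicators Asset indicator columns for the wealth index; default
#'   all `asset_*` columns.
#' @param subgroups Grouping columns for subgroup indices (default urban
#'   and HDI tier).
#' @param outcome Outcome column derived by the pipeline (`"tehb"`).
#' @param seed Seed recorded in the log (the pipeline itself is
#'   deterministic given its input).
#' @return Invisibly, a list with the scored analysis table, the wealth
#'   model, the descriptive table, the list of concentration results, the
#'   decomposition and the vector of file paths written.
#' @export
run_pipeline <- function(households, out_dir, hdi_lookup_path = NULL,
                         indicators = NULL,
                         subgroups = c("urban", "hdi_category"),
                         outcome = "tehb", seed = NA_integer_) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[pipeline] ", line)
  }

  if (is.character(households)) {
    tab <- load_households(households, hdi_lookup_path)
    note("loaded %d households from %s", nrow(tab), households)
    cfg_hash <- unname(tools::md5sum(households))
  } else {
    tab <- households
    note("received %d households in memory", nrow(tab))
    tmp <- tempfile()
    utils::write.csv(tab, tmp, row.names = FALSE)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }

  sample <- withCallingHandlers(
    prepare_analysis_sample(tab),
    message = function(m) invokeRestart("muffleMessage"))
  note("spender filter: %d in = %d retained + %d dropped",
       nrow(tab), nrow(sample), attr(sample, "n_dropped"))

  if (is.null(indicators)) {
    indicators <- grep("^asset_", names(sample), value = TRUE)
  }
  if (length(indicators) < 2) {
    stop("pipeline stage wealth_index: fewer than 2 asset indicators found",
         call. = FALSE)
  }
  model <- fit_wealth_index(sample, indicators)
  note("wealth index: %d indicators, %.1f%% variance explained",
       length(indicators), 100 * model$variance_explained)
  sample <- score_and_classify(sample, model)
  sample$frac_rank <- fractional_rank(sample$wealth_score)

  desc <- descriptive_table(sample, outcome = outcome)
  results <- list(all = concentration_index(
    sample[[outcome]], sample$frac_rank, subgroup_label = "all"))
  for (g in subgroups) {
    res_g <- suppressWarnings(
      subgroup_concentration(sample, g, outcome = outcome))
    results <- c(results, res_g[setdiff(names(res_g), "all")])
  }
  note("concentration indices: national C = %.4f (n = %d)",
       results$all$c_hat, results$all$n)

  curves <- list(all = concentration_curve(sample[[outcome]], sample$frac_rank))
  for (g in subgroups) {
    for (lev in sort(unique(sample[[g]]))) {
      sub <- sample[sample[[g]] == lev, ]
      if (nrow(sub) < 3) next
      curves[[paste0(g, "=", lev)]] <-
        concentration_curve(sub[[outcome]], fractional_rank(sub$wealth_score))
    }
  }

  expanded <- expand_covariates(sample)
  decomp <- decompose_cindex(expanded$table, expanded$spec,
                             expanded$table$frac_rank, outcome = outcome)
  gap <- abs(decomp$sum_contributions + decomp$residual - decomp$total_c)
  note("decomposition: sum + residual - total = %.3e", gap)
  stopifnot(gap < 1e-10)

  paths <- c(
    scored = file.path(out_dir, "households_scored.csv"),
    model = file.path(out_dir, "wealth_model.csv"),
    descriptives = file.path(out_dir, "descriptives.csv"),
    cindex = file.path(out_dir, "concentration_indices.csv"),
    curves = file.path(out_dir, "concentration_curves.csv"),
    decomposition = file.path(out_dir, "decomposition.csv"),
    log = file.path(out_dir, "run_log.txt")
  )
  utils::write.csv(sample, paths["scored"], row.names = FALSE)
  write_wealth_model(model, paths["model"])
  utils::write.csv(desc, paths["descriptives"], row.names = FALSE)
  utils::write.csv(cindex_table(results), paths["cindex"], row.names = FALSE)
  curve_df <- do.call(rbind, lapply(names(curves), function(nm) {
    data.frame(subgroup = nm, p = curves[[nm]]$p, L = curves[[nm]]$L,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(curve_df, paths["curves"], row.names = FALSE)

  dd <- decomp$rows
  dd$stars <- significance_stars(dd$p_value)
  footer <- data.frame(
    variable = c("Sum", "Residual", "Total"), group = "", beta = NA,
    p_value = NA, xbar = NA, elasticity = NA, c_k = NA,
    abs_contribution = c(decomp$sum_contributions, decomp$residual,
                         decomp$total_c),
    rel_contribution_pct = c(decomp$sum_rel_pct, decomp$residual_rel_pct, 100),
    stars = "", stringsAsFactors = FALSE)
  utils::write.csv(rbind(dd, footer), paths["decomposition"], row.names = FALSE)

  writeLines(c(
    sprintf("seed: %s", seed),
    sprintf("input_md5: %s", cfg_hash),
    sprintf("started: %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    log_lines
  ), paths["log"])

  invisible(list(sample = sample, model = model, descriptives = desc,
                 cindex = results, curves = curves, decomposition = decomp,
                 paths = paths))
}
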