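# Synthetic household income-expenditure survey generator.
#
# The generator emulates the structure of a national household
# income-expenditure survey: household-head demographics, urban/rural and
# province strata (provinces grouped into low/middle/high human-development
# tiers), monthly total and tobacco expenditure, and a battery of binary
# asset/housing indicators driven by a single latent wealth factor. Roughly
# one household in five records positive tobacco spending, and the tobacco
# budget share among spenders carries a configurable (by default pro-poor)
# wealth gradient, so the ground-truth concentration index implied by a
# configuration is known and recoverable.

default_asset_loadings <- function() {
  c(car = 0.90, color_tv = 0.85, internet = 0.80, computer = 0.75,
    cellphone = 0.70, freezer = 0.65, dishwasher = 0.60, microwave = 0.55,
    vacuum_cleaner = 0.50, washing_machine = 0.45, motorcycle = 0.45,
    bicycle = 0.40)
}

default_asset_base_rates <- function() {
  c(car = 0.50, color_tv = 0.85, internet = 0.40, computer = 0.30,
    cellphone = 0.90, freezer = 0.60, dishwasher = 0.15, microwave = 0.30,
    vacuum_cleaner = 0.55, washing_machine = 0.65, motorcycle = 0.20,
    bicycle = 0.25)
}

#' Configuration for the synthetic household survey generator
#'
#' Bundles every generator knob into a validated `synthetic_config` object.
#' The defaults define the reference study conditions: about 20% of
#' households with positive tobacco expenditure, a mean tobacco budget share
#' (TEHB) of about 5% among spenders, a pro-poor TEHB gradient calibrated so
#' the implied population concentration index is about -0.14, urban/rural
#' and 31-province (three HDI tiers) strata, and twelve binary asset
#' indicators loading on one latent wealth factor.
#'
#' @param n_households Number of households to simulate.
#' @param urban_share Marginal probability that a household is urban.
#' @param hdi_probs Length-3 probabilities (low, middle, high) that a
#'   household's province belongs to each human-development tier; must sum
#'   to 1.
#' @param n_provinces Number of provinces, partitioned across the three HDI
#'   tiers in proportion to `hdi_probs`.
#' @param asset_loadings Named vector in (0, 1], one per asset indicator;
#'   scales how strongly each indicator loads on latent wealth (the
#'   log-odds slope per SD of wealth is `3 * loading`, strong enough that
#'   the full battery carries a wealth signal comparable to real
#'   multi-indicator asset indices).
#' @param asset_base_rates Marginal ownership probability of each asset;
#'   recycled/validated against `asset_loadings`.
#' @param smoking_base_rate Marginal probability of positive tobacco
#'   expenditure (the spender rate).
#' @param smoking_wealth_slope Log-odds change in spender probability per SD
#'   of latent wealth (negative: the poor are more likely to spend).
#' @param tehb_intercept Linear-model mean TEHB (%) among spenders at
#'   average wealth, before floor truncation (the floor makes the realized
#'   mean slightly higher; the defaults yield a realized spender mean of
#'   about 5%).
#' @param tehb_wealth_slope Change in expected TEHB (%) per SD of latent
#'   wealth among spenders; negative values produce pro-poor concentration.
#' @param tehb_wealth_slope_urban Optional override of `tehb_wealth_slope`
#'   for urban households (`NULL`: same slope everywhere).
#' @param tehb_rural_effect Rural-minus-urban difference in expected TEHB
#'   (%), applied centred so the overall mean stays at `tehb_intercept`.
#' @param tehb_noise_sd SD (%) of household-level TEHB noise among spenders.
#' @param tehb_floor Lower truncation point (%) for TEHB among spenders.
#' @param head_age_mean,head_age_sd Household-head age distribution (years);
#'   draws are clamped to 18--95.
#' @param head_female_share Probability the household head is a woman.
#' @param head_illiterate_rate Marginal probability the head is illiterate.
#' @param illiterate_wealth_slope Log-odds change in illiteracy per SD of
#'   latent wealth.
#' @param hh_size_lambda Household size is `1 + Poisson(hh_size_lambda)`.
#' @param prop_male_mean,prop_male_sd Mean and SD (percentage points) of the
#'   proportion of male household members.
#' @param urban_wealth_slope Log-odds change in urban residence per SD of
#'   latent wealth (urban households are somewhat richer).
#' @param hdi_wealth_tilt Strength of the association between latent wealth
#'   and the province HDI tier (multinomial-logit tilt per SD of wealth).
#' @param log_expenditure_mean,log_expenditure_sd Location and scale of log
#'   total monthly expenditure (arbitrary currency units).
#' @param expenditure_wealth_slope Change in log total expenditure per SD of
#'   latent wealth.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   table.
#'
#' @return An object of class `synthetic_config` (a validated named list).
#' @seealso [generate_households()], [true_concentration_index()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_households = 500, seed = 42)
#' hh <- generate_households(cfg)
#' mean(hh$tobacco_expenditure > 0)
synthetic_config <- function(n_households = 10000L,
                             urban_share = 0.47,
                             hdi_probs = c(low = 0.35, middle = 0.33, high = 0.32),
                             n_provinces = 31L,
                             asset_loadings = default_asset_loadings(),
                             asset_base_rates = default_asset_base_rates(),
                             smoking_base_rate = 0.20,
                             smoking_wealth_slope = -0.35,
                             tehb_intercept = 4.4,
                             tehb_wealth_slope = -1.40,
                             tehb_wealth_slope_urban = NULL,
                             tehb_rural_effect = 1.2,
                             tehb_noise_sd = 4.0,
                             tehb_floor = 0.1,
                             head_age_mean = 49.9,
                             head_age_sd = 13.6,
                             head_female_share = 0.052,
                             head_illiterate_rate = 0.207,
                             illiterate_wealth_slope = -0.9,
                             hh_size_lambda = 2.8,
                             prop_male_mean = 55.2,
                             prop_male_sd = 15,
                             urban_wealth_slope = 0.3,
                             hdi_wealth_tilt = 0.35,
                             log_expenditure_mean = log(3e7),
                             log_expenditure_sd = 0.6,
                             expenditure_wealth_slope = 0.5,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) {
    stop("expected a `synthetic_config` object; see ?synthetic_config",
         call. = FALSE)
  }
  chk_num <- function(field, lo = -Inf, hi = Inf, len = 1L) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != len || anyNA(v)) {
      fail_field(field, sprintf("must be numeric of length %d", len))
    }
    if (any(v < lo) || any(v > hi)) {
      fail_field(field, sprintf("must lie in [%s, %s]", lo, hi))
    }
    invisible(v)
  }
  chk_num("n_households", lo = 1)
  if (cfg$n_households != as.integer(cfg$n_households)) {
    fail_field("n_households", "must be a whole number")
  }
  chk_num("urban_share", 0, 1)
  chk_num("hdi_probs", 0, 1, len = 3L)
  if (abs(sum(cfg$hdi_probs) - 1) > 1e-9) {
    fail_field("hdi_probs", "must sum to 1")
  }
  chk_num("n_provinces", lo = 3)
  k <- length(cfg$asset_loadings)
  if (k < 2 || !is.numeric(cfg$asset_loadings) ||
      any(cfg$asset_loadings <= 0) || any(cfg$asset_loadings > 1)) {
    fail_field("asset_loadings", "must be >= 2 values in (0, 1]")
  }
  chk_num("asset_base_rates", 0, 1, len = k)
  chk_num("smoking_base_rate", 0, 1)
  chk_num("smoking_wealth_slope")
  chk_num("tehb_intercept", lo = 0, hi = 100)
  chk_num("tehb_wealth_slope")
  if (!is.null(cfg$tehb_wealth_slope_urban)) chk_num("tehb_wealth_slope_urban")
  chk_num("tehb_rural_effect")
  if (cfg$tehb_noise_sd <= 0) fail_field("tehb_noise_sd", "must be > 0")
  chk_num("tehb_floor", lo = 0, hi = 100)
  chk_num("head_age_mean", 18, 95)
  if (cfg$head_age_sd <= 0) fail_field("head_age_sd", "must be > 0")
  chk_num("head_female_share", 0, 1)
  chk_num("head_illiterate_rate", 0, 1)
  chk_num("illiterate_wealth_slope")
  if (cfg$hh_size_lambda < 0) fail_field("hh_size_lambda", "must be >= 0")
  chk_num("prop_male_mean", 0, 100)
  if (cfg$prop_male_sd <= 0) fail_field("prop_male_sd", "must be > 0")
  chk_num("urban_wealth_slope")
  chk_num("hdi_wealth_tilt")
  chk_num("log_expenditure_mean")
  if (cfg$log_expenditure_sd <= 0) fail_field("log_expenditure_sd", "must be > 0")
  chk_num("expenditure_wealth_slope")
  chk_num("seed")
  invisible(cfg)
}

# Partition n_provinces across the three HDI tiers, proportional to
# hdi_probs, every tier getting at least one province.
province_partition <- function(n_provinces, hdi_probs) {
  sizes <- pmax(1L, round(n_provinces * hdi_probs))
  while (sum(sizes) > n_provinces) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n_provinces) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(hdi_category = c("low", "middle", "high"),
             first = starts, last = ends, stringsAsFactors = FALSE)
}

#' Generate a synthetic household survey table
#'
#' Simulates `cfg$n_households` households. Latent wealth is standard
#' normal; assets, spender status, literacy, urban residence and province
#' tier are drawn from logistic models in latent wealth; TEHB among spenders
#' is linear in wealth with Gaussian noise, truncated below at
#' `cfg$tehb_floor` and above at 100%. Tobacco expenditure is TEHB times
#' total expenditure for spenders and zero otherwise, so
#' `tobacco_expenditure <= total_expenditure` holds by construction.
#'
#' @param cfg A [synthetic_config()] object.
#' @return A `data.frame` with one row per household: `household_id`,
#'   head demographics, `hh_size`, `prop_male` (%), `urban`, `province_id`,
#'   `hdi_category`, `total_expenditure`, `tobacco_expenditure`, one
#'   `asset_*` 0/1 column per indicator, and the hidden ground-truth
#'   `latent_wealth` (synthetic data only; never available in real surveys).
#' @export
generate_households <- function(cfg) {
  validate_synthetic_config(cfg)
  n <- as.integer(cfg$n_households)
  with_seed(cfg$seed, {
    w <- stats::rnorm(n)

    # urban residence, tilted so urban households are somewhat richer
    a_urb <- calibrate_logit_intercept(cfg$urban_share, cfg$urban_wealth_slope)
    urban <- stats::rbinom(n, 1L, stats::plogis(a_urb + cfg$urban_wealth_slope * w))

    # province HDI tier: multinomial logit tilt in wealth keeps the latent
    # factor marginally standard normal while making high-HDI provinces richer
    tilt <- cfg$hdi_wealth_tilt * c(low = -1, middle = 0, high = 1)
    eta <- outer(w, tilt) + matrix(log(cfg$hdi_probs), n, 3, byrow = TRUE)
    pr <- exp(eta) / rowSums(exp(eta))
    u <- stats::runif(n)
    tier <- 1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
    hdi_category <- c("low", "middle", "high")[tier]
    part <- province_partition(cfg$n_provinces, cfg$hdi_probs)
    lo <- part$first[tier]
    hi <- part$last[tier]
    province_id <- lo + floor(stats::runif(n) * (hi - lo + 1L))

    head_age <- pmin(95, pmax(18, round(stats::rnorm(n, cfg$head_age_mean,
                                                     cfg$head_age_sd))))
    head_female <- stats::rbinom(n, 1L, cfg$head_female_share)
    a_ill <- calibrate_logit_intercept(cfg$head_illiterate_rate,
                                       cfg$illiterate_wealth_slope)
    head_illiterate <- stats::rbinom(
      n, 1L, stats::plogis(a_ill + cfg$illiterate_wealth_slope * w))
    hh_size <- 1L + stats::rpois(n, cfg$hh_size_lambda)

    m <- cfg$prop_male_mean / 100
    v <- min((cfg$prop_male_sd / 100)^2, m * (1 - m) * 0.95)
    phi <- m * (1 - m) / v - 1
    prop_male <- 100 * stats::rbeta(n, m * phi, (1 - m) * phi)

    total_expenditure <- exp(cfg$log_expenditure_mean +
                               cfg$expenditure_wealth_slope * w +
                               stats::rnorm(n, 0, cfg$log_expenditure_sd))

    a_smk <- calibrate_logit_intercept(cfg$smoking_base_rate,
                                       cfg$smoking_wealth_slope)
    spender <- stats::rbinom(
      n, 1L, stats::plogis(a_smk + cfg$smoking_wealth_slope * w)) == 1L

    slope <- rep(cfg$tehb_wealth_slope, n)
    if (!is.null(cfg$tehb_wealth_slope_urban)) {
      slope[urban == 1L] <- cfg$tehb_wealth_slope_urban
    }
    rural_centered <- (1 - urban) - (1 - cfg$urban_share)
    tehb_raw <- cfg$tehb_intercept + slope * w +
      cfg$tehb_rural_effect * rural_centered +
      stats::rnorm(n, 0, cfg$tehb_noise_sd)
    tehb <- pmin(100, pmax(cfg$tehb_floor, tehb_raw))

    assets <- matrix(0L, n, length(cfg$asset_loadings))
    for (k in seq_along(cfg$asset_loadings)) {
      a_k <- calibrate_logit_intercept(cfg$asset_base_rates[k],
                                       3 * cfg$asset_loadings[k])
      assets[, k] <- stats::rbinom(
        n, 1L, stats::plogis(a_k + 3 * cfg$asset_loadings[k] * w))
    }
    nm <- names(cfg$asset_loadings)
    if (is.null(nm)) nm <- sprintf("a%02d", seq_along(cfg$asset_loadings))
    colnames(assets) <- paste0("asset_", nm)

    out <- data.frame(
      household_id = seq_len(n),
      head_age = head_age,
      head_female = head_female,
      head_illiterate = head_illiterate,
      hh_size = hh_size,
      prop_male = prop_male,
      urban = urban,
      province_id = province_id,
      hdi_category = hdi_category,
      total_expenditure = total_expenditure,
      tobacco_expenditure = ifelse(spender, tehb / 100 * total_expenditure, 0),
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(assets))
    out$latent_wealth <- w
    out
  })
}

#' Ground-truth concentration index implied by a generator configuration
#'
#' Monte-Carlo oracle: simulates `n_oracle` households from `cfg`, keeps the
#' positive-tobacco subsample, ranks it by the *latent* wealth factor (not
#' by any fitted score), and returns `2 cov(TEHB, rank) / mean(TEHB)`. This
#' is the recovery target the full pipeline (assets -> PCA -> ranks ->
#' index) is validated against.
#'
#' @param cfg A [synthetic_config()] object.
#' @param n_oracle Simulation size; at least 1e5 recommended so Monte-Carlo
#'   error is well below the recovery tolerance.
#' @return A single number, the oracle concentration index.
#' @export
true_concentration_index <- function(cfg, n_oracle = 1e5) {
  validate_synthetic_config(cfg)
  stopifnot(n_oracle >= 1)
  big <- cfg
  big$n_households <- as.integer(n_oracle)
  tab <- generate_households(big)
  sub <- tab[tab$tobacco_expenditure > 0, ]
  tehb <- 100 * sub$tobacco_expenditure / sub$total_expenditure
  r <- fractional_rank(sub$latent_wealth)
  2 * pop_cov(tehb, r) / mean(tehb)
}

#' Write a household table and its resolved configuration to CSV
#'
#' @param table A household `data.frame`.
#' @param path Output CSV path.
#' @param cfg Optional [synthetic_config()]; when supplied, a flat
#'   `key,value` sidecar (`<path>.config.csv`) echoing the resolved
#'   configuration is written next to the table.
#' @return `path`, invisibly.
#' @export
write_households <- function(table, path, cfg = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(cfg)) {
    flat <- vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ";"),
                   character(1))
    utils::write.csv(data.frame(key = names(flat), value = unname(flat)),
                     paste0(path, ".config.csv"), row.names = FALSE)
  }
  invisible(path)
}
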