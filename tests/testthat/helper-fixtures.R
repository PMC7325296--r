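# Shared fixture builders: everything is generated in code at test time.

# Minimal valid household table (no asset columns unless asked).
make_household_fixture <- function(n = 5, n_assets = 0, seed = 123) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    tab <- data.frame(
      household_id = seq_len(n),
      head_age = sample(25:80, n, replace = TRUE),
      head_female = rbinom(n, 1, 0.1),
      head_illiterate = rbinom(n, 1, 0.2),
      hh_size = sample(1:7, n, replace = TRUE),
      prop_male = runif(n, 20, 80),
      urban = rbinom(n, 1, 0.5),
      province_id = sample(1:31, n, replace = TRUE),
      total_expenditure = exp(rnorm(n, log(3e7), 0.5)),
      tobacco_expenditure = 0
    )
    spend <- rbinom(n, 1, 0.6) == 1
    tab$tobacco_expenditure[spend] <-
      runif(sum(spend), 0.01, 0.1) * tab$total_expenditure[spend]
    if (n_assets > 0) {
      for (k in seq_len(n_assets)) {
        tab[[paste0("asset_a", k)]] <- rbinom(n, 1, 0.5)
      }
    }
    tab
  })
}

write_fixture_csv <- function(tab, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "households.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  path
}

# Small config for fast generator tests.
small_config <- function(seed = 99L, ...) {
  synthetic_config(n_households = 1000L, seed = seed, ...)
}

# Quiet wrapper around prepare_analysis_sample().
prepare_quiet <- function(tab) {
  suppressMessages(prepare_analysis_sample(tab))
}
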