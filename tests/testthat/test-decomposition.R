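test_that("adding-up identity is exact on arbitrary data", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(20:300, 1)
    tab <- data.frame(
      tehb = rexp(n, 1 / 5),
      x1 = rnorm(n),
      x2 = rbinom(n, 1, 0.4),
      x3 = runif(n, 0, 10)
    )
    r <- fractional_rank(rnorm(n))
    d <- decompose_cindex(tab, c("x1", "x2", "x3"), r)
    expect_lt(abs(d$sum_contributions + d$residual - d$total_c), 1e-10)
    expect_equal(d$sum_rel_pct + d$residual_rel_pct, 100, tolerance = 1e-6)
    expect_equal(d$rows$abs_contribution, d$rows$elasticity * d$rows$c_k,
                 tolerance = 1e-12)
  }
})

test_that("a noise-free linear outcome decomposes with zero residual", {
  set.seed(10)
  n <- 200
  tab <- data.frame(x1 = rnorm(n, 2), x2 = rbinom(n, 1, 0.5))
  tab$tehb <- 3 + 2 * tab$x1 - 1.5 * tab$x2
  r <- fractional_rank(tab$x1 + rnorm(n, sd = 0.3))
  d <- decompose_cindex(tab, c("x1", "x2"), r)
  expect_lt(abs(d$residual), 1e-10)
  expect_equal(unname(d$model$beta), c(2, -1.5), tolerance = 1e-10)
  expect_lt(max(abs(d$model$residuals)), 1e-10)
})

test_that("an outcome regressed on itself is self-decomposing", {
  set.seed(11)
  n <- 100
  tab <- data.frame(tehb = rexp(n, 1 / 5))
  tab$self <- tab$tehb
  r <- fractional_rank(rnorm(n))
  d <- decompose_cindex(tab, "self", r)
  expect_equal(unname(d$model$beta), 1, tolerance = 1e-10)
  expect_equal(d$rows$elasticity, 1, tolerance = 1e-10)
  expect_equal(d$rows$abs_contribution, d$total_c, tolerance = 1e-10)
  expect_lt(abs(d$residual), 1e-10)
})

test_that("covariate concentration indices match closed-form cases", {
  n <- 10000
  r <- (1:n) / n
  tab <- data.frame(top_half = as.integer(r > 0.5), own_rank = r)
  c_k <- covariate_concentration_indices(tab, c("top_half", "own_rank"), r)
  # indicator held by the top-ranked half: C -> 0.5
  expect_equal(unname(c_k["top_half"]), 0.5, tolerance = 1e-3)
  # a covariate equal to the rank itself: C -> 1/3
  expect_equal(unname(c_k["own_rank"]), 1 / 3, tolerance = 1e-3)
  # independence from rank: C ~ 0
  set.seed(12)
  tab$noise <- rexp(n)
  c_noise <- covariate_concentration_indices(tab, "noise", r)
  expect_lt(abs(unname(c_noise)), 0.02)
})

test_that("zero-mean covariates are flagged and folded into the residual", {
  set.seed(13)
  n <- 80
  tab <- data.frame(tehb = rexp(n, 1 / 5), x1 = rnorm(n))
  tab$centered <- tab$x1 - mean(tab$x1)
  r <- fractional_rank(rnorm(n))
  expect_warning(cc <- covariate_concentration_indices(tab, "centered", r),
                 "zero mean")
  expect_true(is.na(cc))
})

test_that("identity survives a zero-mean covariate via the residual fold", {
  set.seed(14)
  n <- 90
  tab <- data.frame(tehb = rexp(n, 1 / 5), x1 = rnorm(n), x2 = runif(n))
  tab$zm <- scale(rnorm(n), center = TRUE, scale = FALSE)[, 1]
  r <- fractional_rank(rnorm(n))
  expect_warning(d <- decompose_cindex(tab, c("x1", "x2", "zm"), r), "zero-mean")
  expect_false("zm" %in% d$rows$variable)
  expect_lt(abs(d$sum_contributions + d$residual - d$total_c), 1e-10)
})

test_that("the relative-contribution audit is pure arithmetic", {
  out <- contribution_audit(0.117, 0.055, -0.142)
  expect_equal(unname(out["abs_contribution"]), 0.117 * 0.055, tolerance = 1e-12)
  expect_equal(unname(out["rel_pct"]), 100 * 0.117 * 0.055 / -0.142,
               tolerance = 1e-12)
  expect_equal(unname(contribution_audit(0, 0.4, -0.1)), c(0, 0))
  expect_equal(unname(contribution_audit(0.5, 0, -0.1)), c(0, 0))
  expect_error(contribution_audit(0.1, 0.1, 0), "nonzero")
})

test_that("switching the reference category moves rows, not the total", {
  tab <- prepare_quiet(generate_households(small_config()))
  ind <- grep("^asset_", names(tab), value = TRUE)
  tab <- score_and_classify(tab, fit_wealth_index(tab, ind))
  r <- fractional_rank(tab$wealth_score)
  ex <- expand_covariates(tab)
  d_ref1 <- decompose_cindex(ex$table, ex$spec, r)
  # re-code with the richest quintile as reference instead of the poorest
  alt <- ex$table
  for (q in 1:4) alt[[paste0("quintile_", q)]] <- as.integer(alt$wealth_quintile == q)
  alt_vars <- sub("quintile_5", "quintile_1", ex$spec$variable)
  d_ref5 <- decompose_cindex(alt, alt_vars, r)
  expect_equal(d_ref5$total_c, d_ref1$total_c, tolerance = 1e-12)
  expect_equal(d_ref5$residual, d_ref1$residual, tolerance = 1e-10)
})

test_that("estimated elasticities recover the generating truth at scale", {
  set.seed(15)
  n <- 50000
  x1 <- rnorm(n, mean = 3)
  x2 <- rbinom(n, 1, 0.4)
  y <- 6 + 1.2 * x1 - 2 * x2 + rnorm(n, sd = 2)
  tab <- data.frame(tehb = y, x1 = x1, x2 = x2)
  r <- fractional_rank(x1 + rnorm(n))
  d <- decompose_cindex(tab, c("x1", "x2"), r)
  truth <- c(1.2 * 3 / mean(y), -2 * 0.4 / mean(y))
  expect_equal(d$rows$elasticity, truth, tolerance = 0.05)
})

test_that("recovered coefficient signs match the generator on a default run", {
  tab <- prepare_quiet(generate_households(synthetic_config(seed = 81L)))
  ind <- grep("^asset_", names(tab), value = TRUE)
  tab <- score_and_classify(tab, fit_wealth_index(tab, ind))
  ex <- expand_covariates(tab)
  d <- decompose_cindex(ex$table, ex$spec, fractional_rank(tab$wealth_score))
  q <- d$rows[grepl("^(Poor \\(|Middle \\(|Rich|Richest)", d$rows$variable), ]
  expect_true(all(q$beta < 0))        # richer quintiles spend a smaller share
  expect_true(all(diff(q$beta) < 0))  # monotone in the quintile
  expect_gt(d$rows$beta[d$rows$variable == "Rural"], 0)
  expect_lt(d$total_c, 0)
})

test_that("rank-deficient designs fail loudly with the collinear columns", {
  set.seed(16)
  tab <- data.frame(tehb = rexp(30), x1 = rnorm(30))
  tab$x2 <- 2 * tab$x1
  expect_error(fit_outcome_model(tab, c("x1", "x2")), "collinear.*x2")
  expect_error(fit_outcome_model(tab, c("x1", "ghost")), "ghost")
})
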