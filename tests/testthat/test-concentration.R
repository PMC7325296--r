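test_that("the hand-computable index is recovered exactly", {
  y <- c(1, 2, 3, 4)
  r <- c(0.25, 0.5, 0.75, 1)
  res <- concentration_index(y, r)
  # 2 * cov_pop(y, r) / mean(y) = 2 * 0.3125 / 2.5 = 0.25
  expect_equal(res$c_hat, 0.25, tolerance = 1e-12)
  expect_equal(res$mu, 2.5)
  expect_equal(res$sigma2_r, mean((r - mean(r))^2))
  # antisymmetry under rank reversal
  expect_equal(concentration_index(y, rev(r))$c_hat, -0.25, tolerance = 1e-12)
})

test_that("a constant outcome shows no inequality", {
  r <- fractional_rank(rnorm(50))
  res <- concentration_index(rep(3.2, 50), r)
  expect_equal(res$c_hat, 0, tolerance = 1e-12)
  expect_lte(res$ci_low, 1e-12)
  expect_gte(res$ci_high, -1e-12)
})

test_that("regression and covariance forms of the estimator agree", {
  set.seed(4)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    y <- rexp(n) * sample(c(1, 100), 1)
    scores <- sample(1:max(2, n %/% 3), n, replace = TRUE)  # heavy ties
    r <- fractional_rank(scores)
    if (length(unique(r)) < 2) next
    res <- suppressWarnings(concentration_index(y, r))  # small-n HC1 notes
    expect_lt(abs(res$c_hat - res$cov_form), 1e-10)
    expect_true(res$ci_low <= res$c_hat && res$c_hat <= res$ci_high)
    expect_lte(abs(res$c_hat), 1 + 1e-12)  # non-negative outcome bound
  }
})

test_that("the index is scale invariant but not translation invariant", {
  set.seed(5)
  y <- rexp(300, 1 / 5)
  r <- fractional_rank(rnorm(300))
  base <- concentration_index(y, r)$c_hat
  expect_equal(concentration_index(7.3 * y, r)$c_hat, base, tolerance = 1e-12)
  shifted <- concentration_index(y + 50, r)$c_hat
  expect_lt(abs(shifted), abs(base))
})

test_that("estimator inputs are guarded", {
  expect_error(concentration_index(c(0, 0, 0), c(0.25, 0.5, 1)), "mean is zero")
  expect_error(concentration_index(c(1, 2, 3), rep(0.5, 3)), "degenerate")
  expect_error(concentration_index(c(1, 2), c(0.5, 1)), "at least 3")
})

test_that("concentration curves have the documented geometry", {
  # constant outcome: the line of equality
  r <- fractional_rank(1:8)
  cc <- concentration_curve(rep(2, 8), r)
  expect_equal(cc$L, cc$p, tolerance = 1e-12)
  # the poorest household holding everything: extreme pro-poor step
  cc2 <- concentration_curve(c(1, 0, 0, 0), fractional_rank(c(1, 2, 3, 4)))
  expect_equal(cc2$p, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cc2$L, c(0, 1, 1, 1, 1))
  # invariants: monotone coordinates, exact endpoints
  set.seed(6)
  cc3 <- concentration_curve(rexp(100), fractional_rank(sample(1:20, 100, TRUE)))
  expect_true(all(diff(cc3$p) >= 0) && all(diff(cc3$L) >= 0))
  expect_equal(cc3$p[1], 0)
  expect_equal(utils::tail(cc3$L, 1), 1, tolerance = 1e-12)
  expect_error(concentration_curve(c(0, 0), c(0.5, 1)), "undefined")
  expect_error(concentration_curve(c(-1, 2), c(0.5, 1)), "non-negative")
})

test_that("a pro-poor synthetic run puts the curve on or above the diagonal", {
  tab <- prepare_quiet(generate_households(synthetic_config(seed = 61L)))
  ind <- grep("^asset_", names(tab), value = TRUE)
  tab <- score_and_classify(tab, fit_wealth_index(tab, ind))
  r <- fractional_rank(tab$wealth_score)
  cc <- concentration_curve(tab$tehb, r)
  expect_true(all(cc$L >= cc$p - 1e-9))
  expect_lt(concentration_index(tab$tehb, r)$c_hat, 0)
})

test_that("subgroup analysis re-ranks within each self-contained subsample", {
  set.seed(7)
  base <- data.frame(tehb = rexp(120, 1 / 5), wealth_score = rnorm(120))
  # two identical copies: each subgroup index equals the pooled index
  doubled <- rbind(cbind(base, g = "a"), cbind(base, g = "b"))
  res <- subgroup_concentration(doubled, "g")
  expect_equal(res[["g=a"]]$c_hat, res$all$c_hat, tolerance = 1e-10)
  expect_equal(res[["g=b"]]$c_hat, res$all$c_hat, tolerance = 1e-10)
  # constant outcome in one subgroup
  mixed <- base
  mixed$g <- rep(c("flat", "vary"), each = 60)
  mixed$tehb[mixed$g == "flat"] <- 4
  res2 <- subgroup_concentration(mixed, "g")
  expect_equal(res2[["g=flat"]]$c_hat, 0, tolerance = 1e-12)
  # undersized subgroups are skipped with a warning
  tiny <- base
  tiny$g <- c("solo", rep("rest", 119))
  expect_warning(res3 <- subgroup_concentration(tiny, "g"), "fewer than 3")
  expect_false("g=solo" %in% names(res3))
  expect_error(subgroup_concentration(base, "nope"), "nope")
})

test_that("a steeper urban gradient yields stronger urban inequality", {
  cfg <- synthetic_config(n_households = 20000L, tehb_wealth_slope = -1.0,
                          tehb_wealth_slope_urban = -2.4, seed = 71L)
  tab <- prepare_quiet(generate_households(cfg))
  ind <- grep("^asset_", names(tab), value = TRUE)
  tab <- score_and_classify(tab, fit_wealth_index(tab, ind))
  res <- subgroup_concentration(tab, "urban")
  expect_lt(res[["urban=1"]]$c_hat, res[["urban=0"]]$c_hat)
  expect_gt(abs(res[["urban=1"]]$c_hat), abs(res[["urban=0"]]$c_hat))
})

test_that("result tabulation mirrors the underlying objects", {
  set.seed(8)
  tab <- data.frame(tehb = rexp(60, 1 / 5), wealth_score = rnorm(60),
                    urban = rep(0:1, 30))
  res <- subgroup_concentration(tab, "urban")
  tbl <- cindex_table(res)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$c_hat[tbl$subgroup == "all"], res$all$c_hat)
  expect_true(all(tbl$ci_low <= tbl$c_hat & tbl$c_hat <= tbl$ci_high))
})
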