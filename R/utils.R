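# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Population (divide-by-n) covariance. The concentration index and the
# decomposition identity are exact only when every covariance uses the same
# divisor, so all index arithmetic goes through this helper.
pop_cov <- function(x, y) {
  mean(x * y) - mean(x) * mean(y)
}

# Population variance.
pop_var <- function(x) pop_cov(x, x)

# Solve for the logistic intercept a such that E[plogis(a + b*W)] = rate
# with W ~ N(0, 1). Keeps a configured marginal rate honest when the
# linear predictor also carries a wealth slope.
calibrate_logit_intercept <- function(rate, slope) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(-Inf)
  if (rate == 1) return(Inf)
  if (slope == 0) return(stats::qlogis(rate))
  marginal <- function(a) {
    stats::integrate(function(w) stats::plogis(a + slope * w) * stats::dnorm(w),
                     -Inf, Inf, rel.tol = 1e-10)$value - rate
  }
  half_width <- abs(slope) * 6 + 10
  stats::uniroot(marginal,
                 lower = stats::qlogis(rate) - half_width,
                 upper = stats::qlogis(rate) + half_width,
                 tol = 1e-10)$root
}

# Run an expression under a fixed seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Robust covariance helpers warn "essentially perfect fit" via summary.lm
# when the regression is exact (legitimate here: a noise-free outcome has a
# zero standard error). Muffle only that warning.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Stop with a message naming the offending field -- used by validators so
# errors are actionable from config files and the CLI alike.
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
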