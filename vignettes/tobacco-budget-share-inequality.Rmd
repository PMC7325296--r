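---
title: "Measuring and decomposing socioeconomic inequality in household tobacco budget shares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing socioeconomic inequality in household tobacco budget shares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concindex)
```

## The problem

Households that buy tobacco divert part of a limited monthly budget away
from food, education and healthcare, and this burden is not spread evenly
across the socioeconomic distribution: in most settings the tobacco budget
share is larger among poorer households. `concindex` implements the
standard health-economics toolkit for quantifying that pattern from
household income–expenditure survey microdata: an asset-based wealth index,
concentration curves, the concentration index estimated by convenient
regression, subgroup indices, and the Wagstaff decomposition of the index
into covariate contributions.

The outcome throughout is the *tobacco expenditure household budget share*
(TEHB): tobacco spending as a percentage of total monthly expenditure,
defined for households with positive tobacco expenditure. The analysis
sample is therefore the spender subsample, and the first pipeline stage is
that filter.

## Socioeconomic ranking

Surveys of this kind rarely carry a trustworthy income measure, so
socioeconomic status is proxied by a wealth index: the first principal
component of the household's asset and housing indicators.
`fit_wealth_index()` standardizes each indicator (PCA on the correlation
structure — asset batteries mix binaries, counts and areas, so raw
covariances would let high-variance indicators dominate) and orients the
component so that it correlates positively with the plain asset count;
PCA's sign is otherwise arbitrary and "higher = richer" is the convention
everything downstream assumes.

Households are then classified into population-share quintiles and given a
fractional rank $r_i = i/n$ (ties receive the mean of their positions).
Two numerical choices matter here:

* **Quintile ties.** Class boundaries are the 20/40/60/80% quantiles of
  the score, and exactly tied scores always share a class. With distinct
  scores this yields exact $n/5$ classes; with heavy ties class sizes can
  deviate by the number of tied boundary scores, and a fully degenerate
  score vector collapses into a single class. This mirrors common
  statistical practice for quantile classification.
* **Rank convention.** The plain $i/n$ rank is the default;
  `fractional_rank_midpoint()` offers the $(2i-1)/(2n)$ convention. The
  two differ by the constant $1/(2n)$, and because the concentration index
  depends on ranks only through a covariance they give identical index
  values — a property the test suite asserts rather than assumes.

## The concentration index

For outcome $y$ with mean $\mu$ and fractional rank $r$ with population
variance $\sigma_r^2$, the concentration index is
$C = 2\,\mathrm{cov}(y, r)/\mu$. It is estimated by the *convenient
regression*

$$ 2\sigma_r^2 \frac{y_i}{\mu} = \alpha + \varphi\, r_i + \varepsilon_i $$

whose OLS slope $\hat\varphi$ is algebraically identical to the covariance
form when $\sigma_r^2$ is computed as the divide-by-$n$ variance of the
realized ranks — `concindex` treats $\sigma_r^2$ as a known scaling
constant precisely so this identity is exact, and verifies it to $10^{-10}$
on every call path in the tests. The regression form exists because it
yields a standard error: the package defaults to heteroskedasticity-robust
(HC1) standard errors with normal confidence intervals, the standard
choice for this estimator, and exposes a serial-correlation-robust (HAC)
option for ordered or clustered draws; households in a cross-sectional
survey are exchangeable, so it is off by default.

$C$ is negative when the outcome is concentrated among the poor
("pro-poor" in the measurement sense), positive when among the rich, and
zero under equality. It equals twice the signed area between the
concentration curve and the diagonal; `curve_area_index()` evaluates that
area by the trapezoid rule and agrees with the regression estimate up to
$O(1/n)$ discretization error.

No small-sample $1 - 1/n$ bound correction and no Erreygers/Wagstaff
normalization for bounded outcomes is applied: the plain index is the
analysis-defining quantity here, and TEHB sits far from its upper bound of
100% in practice, where the normalizations matter most.

Subgroup analyses (urban/rural, province development tier) re-rank
households *within* each subgroup before computing the index, so each
subgroup is a self-contained sample rather than a slice of the national
ranking.

## The Wagstaff decomposition

Given a linear model $y = \alpha + \sum_k \beta_k x_k + \varepsilon$, the
index decomposes as

$$ C = \sum_k \underbrace{\frac{\beta_k \bar x_k}{\mu}}_{\text{elasticity}} C_k
   + \frac{GC_\varepsilon}{\mu}, $$

where $C_k$ is covariate $k$'s own concentration index against the same
wealth rank and $GC_\varepsilon = 2\,\mathrm{cov}(\hat\varepsilon, r)$ is
the generalized concentration index of the residual. `decompose_cindex()`
computes the residual term from the OLS residuals — never by subtraction —
so the adding-up identity holds by bilinearity of covariance and is
asserted at $10^{-10}$ on every run; subtraction is used only as a
cross-check. Relative contributions are $100 \times$ absolute contribution
$/\,C$.

Design points worth knowing:

* Wealth-quintile indicators enter the outcome model even though the rank
  derives from the same score. This is deliberate, mirrors standard
  applied practice for this decomposition, and mechanically makes wealth
  the dominant contributor; that dominance is documented behaviour, not a
  bug.
* Categorical covariates are reference-coded (male head, literate head,
  household size < 4, poorest quintile, urban, low-HDI tier). Switching a
  reference level moves contribution between the block's rows and the
  intercept but leaves the total and the residual unchanged — asserted in
  the tests.
* Coefficient stars use HC1 robust p-values at the 1%/5%/10% levels.
* A covariate with (numerically) zero mean has an undefined $C_k$; its row
  is dropped with a warning and its $\beta_k \cdot 2\mathrm{cov}(x_k,r)/\mu$
  term folded into the residual so the identity survives.

`contribution_audit()` is a pure-arithmetic helper that recomputes a
decomposition cell (absolute and relative contribution) from printed
elasticity, covariate index and total index — useful for auditing published
decomposition tables cell by cell.

## The synthetic survey generator

Restricted-access microdata cannot ship with a package, so
`generate_households()` simulates a survey with the structure the analysis
assumes, and with a *known* ground-truth inequality level. A single latent
wealth factor $W \sim N(0,1)$ drives everything:

* **Assets.** Each of twelve binary indicators is Bernoulli with
  $\mathrm{logit}\,P(\text{own}) = a_k + 3\lambda_k W$, loadings
  $\lambda_k \in (0,1]$. The factor 3 makes the battery carry the wealth
  signal typical of real multi-indicator asset indices (PCA score vs.
  latent wealth Spearman correlation ≈ 0.9); a weaker battery would
  attenuate every downstream index estimate through rank measurement
  error.
* **Spending participation vs. intensity.** The probability of positive
  tobacco expenditure follows a logistic model in $W$ (default marginal
  rate 20%, mild pro-poor slope), while TEHB among spenders is linear in
  $W$ with Gaussian noise, floored at 0.1% and capped at 100%. Prevalence
  and intensity get separate slopes because they are distinct phenomena
  with distinct published magnitudes. The intensity model is linear
  because the decomposition itself is linear — linear truth makes
  parameter-recovery tests sharp, at the cost of realism in the far tails.
* **Calibrated intercepts.** Every logistic intercept (spending, urban
  residence, illiteracy, assets) is solved numerically so the *marginal*
  rate equals the configured rate even under a nonzero wealth slope;
  otherwise the logistic curvature would silently shift a configured 20%
  spender rate.
* **Strata.** Urban residence tilts mildly toward wealth; provinces are
  grouped into low/middle/high development tiers with a multinomial-logit
  tilt that leaves $W$ marginally standard normal. Rural households get a
  centred positive TEHB shift (default +1.2 points rural minus urban),
  reproducing the familiar rural excess without moving the overall mean.
* **Defaults as study conditions.** The default configuration
  (`synthetic_config()`) was calibrated once, against the latent-rank
  Monte-Carlo oracle `true_concentration_index()` at $n = 10^6$, to a
  ground-truth index of about −0.14 with a realized spender mean TEHB of
  about 5.1% — magnitudes typical of national tobacco budget-share
  studies — and frozen. All cross-correlations between covariates beyond
  the latent factor are generator choices: the generator is a testbed, not
  an estimate of any country's joint distribution.

The oracle ranks by *latent* wealth, the pipeline by the *fitted PCA
score*; the gap between the two is exactly the measurement-error
attenuation a real analysis suffers, which is why the recovery check
(pipeline within ±0.02 mean absolute error of the oracle across 20
replicate surveys of 10,000 households) is the package's most informative
end-to-end test.

## What passing tests do and do not show

The generator is deliberately simple: one latent factor, conditionally
independent indicators, linear intensity. Passing tests therefore show
that the estimators are implemented correctly and recover known truth
under the model's own assumptions. They do not show robustness to
multi-factor wealth structure, informative survey design (the generator
ignores cluster sampling and weights — the reference analysis is
unweighted), measurement error in expenditures, or non-linear wealth–TEHB
relationships. The printed-table audits check published arithmetic, not
the package against restricted microdata, which is not reproducible at
desk scale.

## Problem sizes and tolerances

Default test and validation sizes, chosen to keep the full suite
fast while leaving Monte-Carlo error well inside each tolerance: generator
unit tests at $n = 1{,}000$–$50{,}000$; oracle at $10^5$–$10^6$; recovery
at 20 replicates of $n = 10{,}000$; estimator-equivalence property at
1,000 random datasets of $n = 5$–500 with heavy rank ties. Exact algebraic
identities (regression ≡ covariance form; decomposition adding-up) are
asserted at $10^{-10}$; Monte-Carlo checks at tolerances derived from
binomial or simulation error (e.g. spender rate ±0.01 at $n = 50{,}000$).

## Known limitations

* Binary indicators only in the default battery; polychoric PCA and
  multiple-correspondence alternatives are out of scope.
* No dominance testing between concentration curves and no standard
  errors for decomposition contributions.
* The two-part structure (participation + intensity) is simulated but not
  modelled: the decomposition is the standard single-equation linear one,
  applied to the spender subsample, as in the reference analysis.
* Survey weights are not supported anywhere; all quantities are
  unweighted household statistics.
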