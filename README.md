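# concindex

Socioeconomic inequality in household budget-share outcomes — concentration
curves, the convenient-regression concentration index, and the Wagstaff
decomposition — with an asset-PCA wealth index and a synthetic household
income–expenditure survey generator for validation.

The motivating application is the tobacco budget share: the percentage of
a household's monthly expenditure spent on tobacco (TEHB), analysed on the
subsample of households with positive tobacco spending. Tobacco spending is
typically concentrated among poorer households, and quantifying *how*
concentrated, and *why*, is the job of this toolkit. It is aimed at health
economists and epidemiologists working with income–expenditure survey
microdata.

## The method

Households are ranked by an asset-based wealth index (first principal
component of standardized asset indicators, oriented so higher = richer)
and given fractional ranks $r_i = i/n$. For outcome $y$ with mean $\mu$,
the concentration index is

$$ C = \frac{2\,\mathrm{cov}(y, r)}{\mu}, $$

estimated by OLS on the convenient regression
$2\sigma_r^2 (y_i/\mu) = \alpha + \varphi r_i + \varepsilon_i$, whose slope
$\hat\varphi$ equals the covariance form exactly and comes with an HC1
robust standard error. $C < 0$ means the outcome is concentrated among the
poor. Given a linear model $y = \alpha + \sum_k \beta_k x_k + \varepsilon$,
the index decomposes exactly into covariate contributions,

$$ C = \sum_k \frac{\beta_k \bar x_k}{\mu} C_k + \frac{GC_\varepsilon}{\mu}, $$

elasticity times the covariate's own concentration index, plus the
generalized concentration index of the residual. See the vignette
(`vignettes/tobacco-budget-share-inequality.Rmd`) for assumptions,
numerical choices and the generator's design.

## Worked example

```r
library(concindex)

cfg    <- synthetic_config(seed = 2024L)          # 10,000 households
hh     <- generate_households(cfg)
sample <- prepare_analysis_sample(hh)             # spender subsample + tehb
wm     <- fit_wealth_index(sample, grep("^asset_", names(sample), value = TRUE))
sample <- score_and_classify(sample, wm)
r      <- fractional_rank(sample$wealth_score)

concentration_index(sample$tehb, r)
#> Concentration index [all]: C = -0.1264 (SE 0.0091, 95% CI -0.1443 to -0.1085), n = 2002

ex <- expand_covariates(sample)
decompose_cindex(ex$table, ex$spec, r)
#> Wagstaff decomposition (n = 2002): C = -0.1264
#>  ... per-covariate rows (beta, elasticity, c_k, contribution) ...
#> Sum      -0.1197  (94.7%)
#> Residual -0.0067  (5.3%)
#> Total    -0.1264  (100%)
```

Of the 10,000 simulated households, 2,002 report positive tobacco spending
(the configured rate is 20%); their mean budget share is about 5.3%. The
national index of −0.126 (CI excluding zero) says tobacco budget shares
are concentrated among the poorer households; the generator's ground-truth
index, computable exactly because the data are synthetic, is
`true_concentration_index(cfg)` ≈ −0.141, and the gap is the attenuation
from ranking by a fitted asset index instead of true wealth. In the
decomposition, the wealth-quintile block dominates the explained part
(richer households spend a smaller share), with the residual under 6% of
the total.

`run_pipeline("households.csv", "out/")` runs the whole chain (load →
filter → wealth index → ranks → descriptives → national and subgroup
indices → curves → decomposition) and writes every table as CSV plus a run
log. A thin CLI over the same functions is in `inst/cli/tehb.R`
(subcommands `simulate`, `wealth-index`, `cindex`, `decompose`, `run`).

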