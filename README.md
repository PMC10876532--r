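# pmsource

Long-term fine particulate matter (PM2.5) is a complex mixture of
chemical constituents (sulfate, nitrate, ammonium, carbon fractions and
trace metals) emitted by distinct sources — coal burning, traffic,
residual-oil combustion, crustal dust, biomass burning. `pmsource` is an
R package for epidemiologists studying how that mixture relates to
aggregated health-outcome counts (here, hospital admissions for
non-respiratory infections among older adults) in ZIP-code-year panels.
It implements the full analytic chain:

* **Rate models.** Quasi-Poisson regression of admission counts with a
  log person-time offset,

  `log E(count_ij) = b0 + b1 * PM2.5_ij + b'Z_ij + log(beneficiaries_ij)`,

  with Pearson-based dispersion, cluster-robust variance over ZIP codes
  (bias-reduced CR2 by default; CR1/CR0 optional), rate ratios per
  exposure increment (e.g. per SD = 3.7 µg/m³), and a low-exposure
  restriction (`pm25 <= 9`).
* **Weighted quantile sum (WQS) mixture regression.** Decile-scored
  constituents, positivity-constrained weights on the simplex
  (softmax-parameterized, Fisher-scoring optimizer), 100 bootstrap
  samples aggregated by signal-weighted means, quasi-Poisson link, and
  influential-constituent flags (weight > 1/15).
* **Source apportionment.** Three time periods × three Ward clusters of
  ZIP-level constituent profiles; within each stratum a non-negative
  matrix factorization (rank 4–5, multiplicative updates, seeded
  restarts) on SD-standardized concentrations; tracer-rule labeling
  (Ni/V → oil combustion, SO4/NH4 → coal, Cu/Fe/Zn/EC → traffic, Si/Ca
  → soil, K/OC → biomass, NO3/NH4 → nitrate); factor scores converted
  to µg/m³ and rescaled to unit SD.
* **Random-effects pooling.** Mutually adjusted per-stratum source
  effects combined across strata by DerSimonian–Laird meta-analysis.
* **Synthetic panels with known truth.** Because the Medicare admission
  data such analyses use are restricted-access, the package includes a
  generator (latent non-negative source factors, correlated covariates
  with a planted confounder, gamma-Poisson overdispersed counts,
  calibrated to the published PM2.5 and ZIP-size distributions) so every
  stage can be validated by parameter recovery.

## Worked example

```r
library(pmsource)

cfg <- synthetic_config(n_zips = 300, seed = 42)   # true RR/SD = 1.108
gp  <- generate_panel(cfg)

fit <- fit_quasipoisson(gp$panel, "non_respiratory")
fit
#> Quasi-Poisson rate model, outcome 'non_respiratory' (5100 obs, 300 clusters)
#>   pm25: 0.02806 (robust SE 0.00117), dispersion 1.60

rr_per_delta(fit, 3.7)
#> RR per 3.7 units (non_respiratory): 1.109 (95% CI 1.100-1.119), +10.9%
```

The fitted slope (0.02806 per µg/m³) converts to a rate ratio of 1.109
per 3.7 µg/m³ of PM2.5 — a 10.9% increase in the admission rate per SD,
recovering the generator's true value of 1.108 well within the robust
interval. The same panel restricted to low exposure:

```r
low <- restrict_panel(gp$panel, pm25 <= 9)
#> restrict_panel: kept 2157 of 5100 rows (2943 dropped)
rr_per_delta(fit_quasipoisson(low, "non_respiratory"), 3.7)
#> RR per 3.7 units (non_respiratory): 1.140 (95% CI 1.100-1.183), +14.0%
```

Pooling stratum-specific source effects:

```r
eff <- data.frame(source = "oil combustion", outcome = "non_respiratory",
                  log_rr = c(0.12, 0.16, 0.10), se = c(0.04, 0.05, 0.03))
pool_random_effects(eff)[, c("source", "rr", "ci_low", "ci_high", "tau2", "k_strata")]
#>           source       rr  ci_low  ci_high tau2 k_strata
#> 1 oil combustion 1.124217 1.07754 1.172917    0        3
```

The heavier stages follow the same pattern: `fit_wqs_bootstrap(panel,
"non_respiratory", B = 100, seed = 1)` returns aggregated constituent
weights and the rate ratio per decile of the mixture index;
`apportion(panel, seed = 1)` runs the stratified NMF and returns labeled,
SD-scaled source exposures that `fit_stratum_models()` and
`pool_random_effects()` consume. `run_all()` chains everything and
writes CSV report tables; a command-line front end with the same
subcommands lives in `inst/scripts/pm_pipeline.R`. The methods vignette
(`vignettes/pmsource-methods.Rmd`) documents the models, defaults and
design choices.

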