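test_that("DL pooling matches the hand-evaluated two-study example", {
  eff <- data.frame(source = "oil combustion", outcome = "non_respiratory",
                    log_rr = c(0.1, 0.3), se = c(0.05, 0.10))
  pooled <- pool_random_effects(eff)
  # frozen values from the direct formula transcription
  expect_equal(pooled$q_stat, 3.2, tolerance = 1e-12)
  expect_equal(pooled$tau2, 0.01375, tolerance = 1e-12)
  expect_equal(pooled$log_rr, 0.18125, tolerance = 1e-12)
  expect_equal(pooled$se, 0.0982264602843857, tolerance = 1e-12)
  # and against the independent oracle function
  o <- dl_oracle(eff$log_rr, eff$se)
  expect_equal(pooled$log_rr, o$mu, tolerance = 1e-14)
  expect_equal(pooled$tau2, o$tau2, tolerance = 1e-14)
})

test_that("DL pooling agrees with metafor on a larger example", {
  skip_if_not_installed("metafor")
  set.seed(9)
  y <- rnorm(9, 0.12, 0.08)
  se <- runif(9, 0.03, 0.12)
  eff <- data.frame(source = "coal burning", outcome = "non_respiratory",
                    log_rr = y, se = se)
  pooled <- pool_random_effects(eff)
  r <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(pooled$log_rr, as.numeric(r$beta), tolerance = 1e-10)
  expect_equal(pooled$tau2, r$tau2, tolerance = 1e-10)
})

test_that("homogeneous strata pool to themselves with zero heterogeneity", {
  eff <- data.frame(source = "traffic", outcome = "non_respiratory",
                    log_rr = rep(0.2, 5), se = rep(0.04, 5))
  pooled <- pool_random_effects(eff)
  expect_equal(pooled$log_rr, 0.2, tolerance = 1e-12)
  expect_equal(pooled$tau2, 0)
  # tau2 = 0 reduces to the fixed-effect inverse-variance average
  set.seed(4)
  y <- c(0.1, 0.105, 0.095)
  se <- c(0.2, 0.25, 0.22)   # Q < k-1 here, so tau2 truncates to 0
  eff2 <- data.frame(source = "soil", outcome = "o", log_rr = y, se = se)
  p2 <- pool_random_effects(eff2)
  expect_equal(p2$tau2, 0)
  expect_equal(p2$log_rr, sum(y / se^2) / sum(1 / se^2), tolerance = 1e-12)
})

test_that("heterogeneity widens the pooled interval", {
  y <- c(-0.1, 0.1, 0.3, 0.5)
  se <- rep(0.05, 4)
  eff <- data.frame(source = "s", outcome = "o", log_rr = y, se = se)
  pooled <- pool_random_effects(eff)
  expect_gt(pooled$tau2, 0)
  fe_se <- sqrt(1 / sum(1 / se^2))
  expect_gt(pooled$se, fe_se)
  expect_true(pooled$ci_low < pooled$rr && pooled$rr < pooled$ci_high)
})

test_that("DL recovers simulated between-stratum heterogeneity", {
  tau2_true <- 0.01
  est <- run_seeded(12, vapply(1:200, function(i) {
    se <- runif(9, 0.02, 0.05)
    y <- rnorm(9, 0.1, sqrt(tau2_true)) + rnorm(9, 0, se)
    eff <- data.frame(source = "s", outcome = "o", log_rr = y, se = se)
    pool_random_effects(eff)$tau2
  }, numeric(1)))
  expect_gte(median(est), 0.004)
  expect_lte(median(est), 0.02)
})

test_that("degenerate pooling inputs are handled explicitly", {
  eff <- data.frame(source = "s", outcome = "o", log_rr = 0.1, se = 0.05)
  expect_warning(p <- pool_random_effects(eff), "single stratum")
  expect_equal(p$log_rr, 0.1)
  expect_equal(p$k_strata, 1)
  bad <- data.frame(source = "s", outcome = "o", log_rr = c(0.1, 0.2),
                    se = c(0.05, 0))
  expect_error(pool_random_effects(bad), "positive")
})

test_that("stratum models mutually adjust and flag collinear factors", {
  gp <- small_panel(n_zips = 120, n_years = 4, seed = 55)
  panel <- gp$panel
  n <- nrow(panel)
  set.seed(3)
  e1 <- panel$pm25 / sd(panel$pm25)
  e2 <- rnorm(n)
  fake_sm <- structure(list(strata = list(list(
    stratum = "all", period = "all", cluster = 1, rows = seq_len(n),
    k = 2, W = NULL, labels = c("oil combustion", "soil"),
    scaled = cbind(e1, e2) ))), class = "pm_source_model")
  eff <- fit_stratum_models(panel, fake_sm, "non_respiratory")
  expect_equal(nrow(eff), 2)
  # the pm25-based factor's coefficient equals a direct panel-model fit
  # with the same design (mutual adjustment included)
  panel$src1 <- e1; panel$src2 <- e2
  direct <- fit_quasipoisson(panel, "non_respiratory", exposure = "src1",
                             covariates = c("src2", attr(panel, "covariates"),
                                            "factor(year)"))
  expect_equal(eff$log_rr[eff$source == "oil combustion"],
               unname(direct$coefficients["src1"]), tolerance = 1e-10)
  # an (almost) duplicated factor triggers the collinearity guard
  fake_dup <- fake_sm
  fake_dup$strata[[1]]$scaled <- cbind(e1, e1 + 1e-9 * rnorm(n))
  expect_error(fit_stratum_models(panel, fake_dup, "non_respiratory"),
               "collinear")
})

test_that("a non-causal orthogonal source reads as null", {
  hits <- 0L
  reps <- 25
  for (r in seq_len(reps)) {
    gp <- small_panel(n_zips = 90, n_years = 3, seed = 700 + r)
    panel <- gp$panel
    e1 <- panel$pm25 / sd(panel$pm25)
    e2 <- run_seeded(800 + r, rnorm(nrow(panel)))
    sm <- structure(list(strata = list(list(
      stratum = "all", rows = seq_len(nrow(panel)), k = 2, W = NULL,
      labels = c("causal", "null"), scaled = cbind(e1, e2)))),
      class = "pm_source_model")
    eff <- fit_stratum_models(panel, sm, "non_respiratory")
    nul <- eff[eff$source == "null", ]
    hits <- hits + (abs(nul$log_rr) < 3 * nul$se)
  }
  expect_gte(hits / reps, 0.9)
})
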