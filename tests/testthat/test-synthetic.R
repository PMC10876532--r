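test_that("config validation rejects impossible study settings", {
  expect_error(synthetic_config(dispersion = 0.5), "dispersion")
  expect_error(synthetic_config(beneficiary_range = c(50, 1000)),
               "more than 100")
  expect_error(synthetic_config(true_wqs_weights = rep(0.1, 15)), "sum to 1")
  expect_error(synthetic_config(noise_cv = -0.1), "noise_cv")
  L <- default_loading_matrix(5); L[1, 1] <- -1
  expect_error(synthetic_config(loading_matrix = L), ">= 0")
})

test_that("panel generation is deterministic and respects the grid", {
  cfg <- synthetic_config(n_zips = 50, years = 2001:2003, seed = 7)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_equal(nrow(a$panel), 150)
  expect_false(anyDuplicated(a$panel[, c("zip", "year")]) > 0)
  expect_true(all(a$panel[, pm_constituents()] >= 0))
  expect_true(all(a$panel$beneficiaries > 100))
  expect_true(all(vapply(pm_outcomes(), function(o)
    all(a$panel[[paste0("count_", o)]] <= a$panel$beneficiaries),
    logical(1))))
  # CSV round-trip is byte-identical under the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_panel(a$panel, f1)
  write_panel(generate_panel(cfg)$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("source scores are non-negative and independent across sources", {
  cfg <- synthetic_config(n_zips = 625, years = 2001:2016, seed = 3,
                          trend_rates = rep(0, 5),
                          cluster_multipliers = matrix(1, 3, 5))
  s <- run_seeded(11, generate_source_scores(cfg))
  expect_true(all(s >= 0))
  expect_gte(nrow(s), 10000)
  cors <- cor(s)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  # determinism under a fixed seed
  s2 <- run_seeded(11, generate_source_scores(cfg))
  expect_identical(s, s2)
})

test_that("degenerate one-source scores have the configured mean", {
  cfg <- synthetic_config(n_zips = 500, years = 2001:2010, n_sources = 1,
                          seed = 5, trend_rates = 0, zip_effect_sd = 0,
                          cluster_multipliers = matrix(1, 3, 1))
  s <- run_seeded(2, generate_source_scores(cfg))
  expect_equal(ncol(s), 1)
  mc_se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1), 3 * mc_se)
})

test_that("constituents are the exact mixture when noiseless", {
  cfg <- synthetic_config(n_zips = 20, years = 2001:2002, seed = 9)
  s <- run_seeded(4, generate_source_scores(cfg))
  X <- generate_constituents(s, cfg$loading_matrix, noise_cv = 0)
  expect_equal(X, s %*% t(cfg$loading_matrix), ignore_attr = TRUE)
  expect_error(generate_constituents(s, cfg$loading_matrix, noise_cv = -1),
               "noise_cv")
})

test_that("rank-1 loadings give perfectly correlated constituent columns", {
  L1 <- default_loading_matrix(1)
  s <- matrix(rgamma(200, 2, 2), ncol = 1)
  X <- generate_constituents(s, L1, noise_cv = 0)
  nz <- which(L1[, 1] > 0)
  cors <- cor(X[, nz])
  expect_equal(max(abs(cors - 1)), 0, tolerance = 1e-12)
})

test_that("multiplicative noise has the configured coefficient of variation", {
  s <- matrix(rgamma(20000 * 3, 5, 5), ncol = 3)
  L <- default_loading_matrix(3)
  X <- run_seeded(8, generate_constituents(s, L, noise_cv = 0.2))
  base <- s %*% t(L)
  nz <- which(colSums(t(L)) > 0)  # constituents actually produced
  cvs <- vapply(nz, function(j) {
    r <- X[, j] / base[, j]
    sd(r) / mean(r)
  }, numeric(1))
  expect_true(all(abs(cvs - 0.2) < 0.02))
})

test_that("counts match the gamma-Poisson moment structure", {
  # Poisson limit: variance/mean near 1
  y1 <- run_seeded(1, generate_counts(rep(10, 50000), dispersion = 1))
  expect_lt(abs(var(y1) / mean(y1) - 1), 0.05)
  # phi = 3 at fixed mu = 10: variance/mean in [2.6, 3.4]
  y3 <- run_seeded(2, generate_counts(rep(10, 50000), dispersion = 3))
  vm <- var(y3) / mean(y3)
  expect_gte(vm, 2.6)
  expect_lte(vm, 3.4)
  expect_error(generate_counts(c(5, Inf)), "row 2")
})

test_that("null effect yields the baseline rate", {
  cfg <- synthetic_config(n_zips = 400, years = 2001:2005, seed = 21,
                          true_rr_per_sd = setNames(rep(1, 5), pm_outcomes()),
                          covariate_effects = rep(0, 5),
                          year_rate_trend = 0, zip_re_sd = 0,
                          dispersion = 1)
  p <- generate_panel(cfg)$panel
  rate <- sum(p$count_non_respiratory) / sum(p$beneficiaries)
  se <- sqrt(sum(p$count_non_respiratory)) / sum(p$beneficiaries)
  expect_lt(abs(rate - 0.0251), 3 * se)
})

test_that("omitting the confounder biases the exposure estimate, adjusting removes it", {
  truth <- log(1.108) / 3.7
  reps <- 40
  naive <- adj <- numeric(reps)
  for (r in seq_len(reps)) {
    p <- small_panel(n_zips = 80, n_years = 4, seed = 100 + r,
                     confounding = 0.4,
                     covariate_effects = c(z1 = 0.15, z2 = 0, z3 = 0,
                                           z4 = 0, z5 = 0))$panel
    fn <- fit_quasipoisson(p, "non_respiratory",
                           covariates = c("z2", "factor(year)"))
    fa <- fit_quasipoisson(p, "non_respiratory",
                           covariates = c("z1", "z2", "factor(year)"))
    naive[r] <- fn$coefficients["pm25"]
    adj[r] <- fa$coefficients["pm25"]
  }
  mc_se <- sd(adj) / sqrt(reps)
  expect_lt(abs(mean(adj) - truth), 2 * mc_se)
  # the naive estimate is biased upward by the positive confounder
  expect_gt(mean(naive) - truth, 3 * sd(naive) / sqrt(reps))
})
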