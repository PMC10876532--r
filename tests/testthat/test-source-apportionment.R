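test_that("mean profiles average within period and ignore row order", {
  panel <- data.frame(zip = c("A", "A", "B"), year = c(2001, 2002, 2001))
  for (cn in pm_constituents()) panel[[cn]] <- c(2, 4, 10)
  prof <- mean_profiles(panel, 2001:2002)
  expect_equal(unname(prof["A", "so4"]), 3)
  expect_equal(unname(prof["B", "ec"]), 10)
  # single-year period reproduces that year's values
  prof1 <- mean_profiles(panel, 2001)
  expect_equal(unname(prof1["A", "oc"]), 2)
  # permuting input rows leaves the (ordered) output unchanged
  prof_p <- mean_profiles(panel[c(3, 1, 2), ], 2001:2002)
  expect_identical(prof, prof_p)
  # a ZIP absent from the period is excluded with a message
  expect_message(mean_profiles(panel, 2002), "absent")
})

test_that("Ward clustering separates well-separated 1-D profiles", {
  prof <- matrix(c(0, 1, 10, 11), ncol = 1,
                 dimnames = list(c("z1", "z2", "z3", "z4"), "so4"))
  cl <- ward_cluster(prof, k = 2)
  expect_equal(cl[["z1"]], cl[["z2"]])
  expect_equal(cl[["z3"]], cl[["z4"]])
  expect_false(cl[["z1"]] == cl[["z3"]])
  # k = n gives singletons; duplicates co-cluster
  expect_equal(sort(unname(ward_cluster(prof, k = 4))), 1:4)
  prof2 <- prof[c(1, 1, 3, 3), , drop = FALSE]
  rownames(prof2) <- paste0("d", 1:4)
  cl2 <- ward_cluster(prof2, k = 2)
  expect_equal(cl2[["d1"]], cl2[["d2"]])
  expect_equal(cl2[["d3"]], cl2[["d4"]])
  expect_error(ward_cluster(prof, k = 9), "exceeds")
  # row order does not change labels
  expect_identical(ward_cluster(prof[c(3, 1, 4, 2), , drop = FALSE], k = 2),
                   cl)
})

test_that("NMF recovers an exact low-rank factorization", {
  set.seed(1)
  W0 <- cbind(c(rep(1, 8), rep(0, 7)), c(rep(0, 7), rep(1, 8)))
  H0 <- matrix(rgamma(200, 2, 1), ncol = 2)
  X <- H0 %*% t(W0)
  rownames(W0) <- colnames(X) <- pm_constituents()
  f <- suppressWarnings(
    fit_nmf(X, 2, seed = 3, n_init = 5, max_iter = 6000, tol = 1e-9))
  expect_lt(f$error, 1e-6)
  expect_true(all(f$W >= 0) && all(f$H >= 0))
  expect_equal(colSums(f$W), c(factor1 = 1, factor2 = 1), tolerance = 1e-8)
  # k = 1 on rank-1 data recovers the generating direction
  X1 <- H0[, 1, drop = FALSE] %*% t(W0[, 1, drop = FALSE])
  colnames(X1) <- pm_constituents()
  f1 <- fit_nmf(X1, 1, seed = 3, n_init = 3)
  expect_gt(pmsource:::cosine_cols(f1$W[, 1], W0[, 1]), 0.9999)
  expect_error(fit_nmf(-X, 2), "non-negative")
  expect_error(fit_nmf(X, 20), "smaller")
})

test_that("tracer labeling follows the greedy rule table", {
  cons <- pm_constituents()
  mk <- function(...) {
    v <- setNames(rep(1e-6, 15), cons)
    args <- list(...)
    v[names(args)] <- unlist(args)
    v / sum(v)
  }
  # Ni/V-dominated factor is residual-oil combustion
  W <- cbind(oilish = mk(ni = 5, v = 5), coalish = mk(so4 = 8, nh4 = 2))
  rownames(W) <- cons
  expect_equal(label_sources(W),
               c("oil combustion", "coal burning"))
  # uniform loadings cannot earn a label
  Wu <- matrix(1 / 15, 15, 3, dimnames = list(cons, NULL))
  expect_equal(label_sources(Wu), rep("unassigned", 3))
  # two SO4-dominant factors: higher tracer score takes coal burning,
  # the other falls to its next-best rule (nitrate here)
  W2 <- cbind(a = mk(so4 = 3, nh4 = 1), b = mk(so4 = 2, no3 = 2, nh4 = 1))
  rownames(W2) <- cons
  expect_equal(label_sources(W2),
               c("coal burning", "regionally transported nitrate"))
})

test_that("mass conversion closes the mass balance and scales to unit SD", {
  set.seed(7)
  W0 <- cbind(c(rep(0.2, 5), rep(0, 10)), c(rep(0, 10), rep(0.2, 5)))
  rownames(W0) <- pm_constituents()
  H0 <- matrix(rgamma(300, 3, 1), ncol = 2)
  X <- H0 %*% t(W0)
  colnames(X) <- pm_constituents()
  f <- suppressWarnings(
    fit_nmf(X, 2, seed = 5, n_init = 5, max_iter = 6000, tol = 1e-9))
  ms <- massify_and_scale(f$W, f$H)
  expect_equal(rowSums(ms$mass), rowSums(X), tolerance = 1e-5)
  expect_equal(unname(apply(ms$scaled, 2, sd)), c(1, 1), tolerance = 1e-8)
  # doubling a factor's scores doubles mass, leaves the scaled series fixed
  H2 <- f$H; H2[, 1] <- 2 * H2[, 1]
  ms2 <- massify_and_scale(f$W, H2)
  expect_equal(ms2$mass[, 1], 2 * ms$mass[, 1])
  expect_equal(ms2$scaled[, 1], ms$scaled[, 1], tolerance = 1e-12)
  # constant factor scores have zero variance and are dropped
  H3 <- f$H; H3[, 2] <- 1
  expect_warning(ms3 <- massify_and_scale(f$W, H3), "zero-variance")
  expect_equal(ncol(ms3$scaled), 1)
})

test_that("factor matching finds the planted permutation", {
  set.seed(2)
  W <- matrix(rgamma(15 * 3, 2), 15, 3,
              dimnames = list(pm_constituents(), NULL))
  perm <- c(3, 1, 2)
  mc <- match_factors(W[, perm], W)
  expect_equal(unname(mc), rep(1, 3), tolerance = 1e-12)
})

test_that("stratified apportionment recovers planted clusters and labels", {
  cfg <- synthetic_config(n_zips = 180, years = 2000:2016,
                          effect_mode = "sources", seed = 41)
  gp <- generate_panel(cfg)
  sm <- suppressWarnings(apportion(gp$panel, seed = 77, n_init = 4))
  expect_equal(length(sm$strata), 9)
  # Ward clusters align with the generator's latent regions
  cl <- sm$zip_clusters[["2006-2010"]]
  tc <- gp$truth$zip_cluster[names(cl)]
  agree <- max(apply(table(cl, tc), 1, max) / table(cl))
  expect_gt(mean(agree), 0.8)
  # the dominant fossil/traffic labels are found in nearly every stratum
  for (lab in c("coal burning", "traffic")) {
    hits <- sum(vapply(sm$strata, function(s) lab %in% s$labels, logical(1)))
    expect_gte(hits, 8)
  }
  # every stratum's scaled exposures have unit SD
  for (s in sm$strata)
    expect_equal(unname(apply(s$scaled, 2, sd)),
                 rep(1, ncol(s$scaled)), tolerance = 1e-8)
})
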