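#' Default non-negative constituent loading matrix
#'
#' Loadings (micrograms per cubic metre of each constituent per unit of
#' source activity) for up to six latent sources: coal burning (secondary
#' sulfate/ammonium), traffic (organic and elemental carbon, Cu/Fe/Zn),
#' residual-oil combustion (Ni/V plus some sulfate), crustal soil (Si/Ca),
#' biomass burning (K/OC) and regionally transported nitrate (NO3/NH4).
#' Magnitudes are calibrated so that the default five-source panel has a
#' total PM2.5 distribution comparable to the contiguous-US ZIP-code-year
#' distribution (median near 9.7, SD near 3.7 micrograms per cubic metre).
#'
#' @param n_sources Number of leading sources to keep (4 to 6).
#' @param scale Overall mass scale multiplier.
#' @return 15 x n_sources non-negative matrix with constituent rownames
#'   and source-label colnames.
#' @export
default_loading_matrix <- function(n_sources = 5, scale = 1.47) {
  cons <- pm_constituents()
  src <- c("coal burning", "traffic", "oil combustion", "soil",
           "biomass burning", "regionally transported nitrate")
  L <- matrix(0, nrow = 15, ncol = 6, dimnames = list(cons, src))
  L[c("so4", "nh4", "oc", "ec", "fe", "pb", "br", "v"), 1] <-
    c(2.20, 0.55, 0.15, 0.03, 0.005, 0.002, 0.001, 0.001)
  L[c("oc", "ec", "fe", "no3", "ca", "zn", "cu", "pb"), 2] <-
    c(0.70, 0.35, 0.06, 0.05, 0.01, 0.008, 0.005, 0.003)
  L[c("so4", "oc", "ec", "v", "ni", "fe", "zn"), 3] <-
    c(0.28, 0.08, 0.05, 0.005, 0.003, 0.005, 0.001)
  L[c("si", "ca", "fe", "k", "oc", "ec"), 4] <-
    c(0.12, 0.05, 0.03, 0.01, 0.05, 0.002)
  L[c("oc", "k", "ec", "no3", "br"), 5] <-
    c(0.90, 0.06, 0.10, 0.02, 0.002)
  L[c("no3", "nh4", "so4"), 6] <- c(1.10, 0.35, 0.05)
  if (n_sources < 1 || n_sources > 6)
    stopf("n_sources must be between 1 and 6, got %d", n_sources)
  L[, seq_len(n_sources), drop = FALSE] * scale
}

#' Configuration for the synthetic ZIP-code-year panel generator
#'
#' Defines the data-generating process used for validation and
#' parameter-recovery studies: latent non-negative source factors with
#' per-ZIP and per-year multiplicative structure, constituent
#' concentrations as noisy non-negative mixtures of those factors,
#' correlated ZIP-level covariates, and overdispersed admission counts
#' from a log-linear rate model with a log-beneficiary offset.
#'
#' True exposure effects are expressed as rate ratios per `sd_ref`
#' micrograms per cubic metre of PM2.5 (default 3.7, a typical SD of
#' long-term ZIP-level PM2.5), so recovery studies can convert fitted
#' slopes with a known increment. Four effect modes are supported:
#' `"pm25"` (log rate linear in total PM2.5), `"piecewise"` (two-segment
#' log-linear response with a breakpoint), `"wqs"` (log rate linear in a
#' weighted decile index of the constituents, which are then drawn as
#' independent lognormals so mixture weights are identifiable), and
#' `"sources"` (log rate linear in SD-scaled latent source mass
#' contributions).
#'
#' @param n_zips Number of ZIP codes (> 1).
#' @param years Integer vector of calendar years (default 2000:2016).
#' @param n_sources Number of latent sources, 4 to 6 (default 5).
#' @param loading_matrix 15 x n_sources non-negative matrix (micrograms
#'   per cubic metre per unit score); default [default_loading_matrix()].
#' @param effect_mode One of "pm25", "piecewise", "wqs", "sources".
#' @param true_rr_per_sd Named vector of true rate ratios per `sd_ref`
#'   of PM2.5, one per outcome category ("pm25" mode).
#' @param rr_low,rr_high,breakpoint Piecewise mode: rate ratios per
#'   `sd_ref` below and above the breakpoint (micrograms per cubic metre).
#' @param true_wqs_weights Length-15 non-negative simplex vector of true
#'   mixture weights ("wqs" mode).
#' @param true_rr_per_decile True rate ratio per one-decile increase in
#'   the weighted mixture index ("wqs" mode).
#' @param true_source_rr Vector (length `n_sources`) of true rate ratios
#'   per within-stratum SD of each source's mass contribution
#'   ("sources" mode).
#' @param sd_ref Reference PM2.5 increment (micrograms per cubic metre)
#'   defining "per SD" effects; default 3.7.
#' @param dispersion Overdispersion factor phi >= 1 (variance = phi * mean).
#' @param baseline_rates Named per-person-year admission rates at average
#'   exposure/covariates, one per outcome.
#' @param covariate_effects Log-rate effects of the 5 standard-normal
#'   covariates z1..z5.
#' @param confounding Correlation between covariate z1 and PM2.5.
#' @param year_rate_trend Log-rate trend per calendar year (secular trend
#'   absorbed by year indicators in analysis).
#' @param zip_re_sd SD of the ZIP-level log-rate random effect creating
#'   within-ZIP correlation across years.
#' @param gamma_shape Shape of the gamma source-score distribution
#'   (mean 1, variance 1/shape).
#' @param zip_effect_sd SD (log scale) of per-ZIP source multipliers.
#' @param cluster_multipliers 3 x n_sources matrix of per-ZIP-cluster
#'   source multipliers (three latent regions with distinct profiles).
#' @param trend_rates Per-source exponential time-trend rates per year
#'   (relative to 2008).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise on constituents.
#' @param remainder_fraction Fraction of total PM2.5 mass not covered by
#'   the 15 constituents (PM2.5 = constituent sum / (1 - fraction)).
#' @param beneficiary_range Integer bounds for beneficiaries per
#'   ZIP-code-year; minimum must exceed 100.
#' @param seed RNG seed for [generate_panel()].
#' @return Object of class `pm_synth_config` (validated list).
#' @export
synthetic_config <- function(n_zips = 300,
                             years = 2000:2016,
                             n_sources = 5,
                             loading_matrix = NULL,
                             effect_mode = c("pm25", "piecewise", "wqs", "sources"),
                             true_rr_per_sd = c(non_respiratory = 1.108,
                                                cns = 1.007,
                                                intestinal = 1.068,
                                                urinary = 1.120,
                                                septicemia = 1.128),
                             rr_low = 1.215, rr_high = 1.108, breakpoint = 9,
                             true_wqs_weights = rep(1 / 15, 15),
                             true_rr_per_decile = 1.103,
                             true_source_rr = NULL,
                             sd_ref = 3.7,
                             dispersion = 1.5,
                             baseline_rates = c(non_respiratory = 0.0251,
                                                cns = 0.0008,
                                                intestinal = 0.004,
                                                urinary = 0.009,
                                                septicemia = 0.010),
                             covariate_effects = c(z1 = 0.06, z2 = -0.04,
                                                   z3 = 0.04, z4 = 0.03,
                                                   z5 = -0.03),
                             confounding = 0.3,
                             year_rate_trend = 0.005,
                             zip_re_sd = 0.05,
                             gamma_shape = 5,
                             zip_effect_sd = 0.25,
                             cluster_multipliers = NULL,
                             trend_rates = NULL,
                             noise_cv = 0.15,
                             remainder_fraction = 0.15,
                             beneficiary_range = c(101L, 20000L),
                             seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  if (n_zips < 2) stopf("n_zips must be at least 2")
  if (!(n_sources %in% 1:6)) stopf("n_sources must be in 1..6")
  if (is.null(loading_matrix))
    loading_matrix <- default_loading_matrix(n_sources)
  loading_matrix <- as.matrix(loading_matrix)
  if (nrow(loading_matrix) != 15 || ncol(loading_matrix) != n_sources)
    stopf("loading_matrix must be 15 x %d, got %d x %d",
          n_sources, nrow(loading_matrix), ncol(loading_matrix))
  if (any(loading_matrix < 0)) stopf("loading_matrix entries must be >= 0")
  if (is.null(rownames(loading_matrix)))
    rownames(loading_matrix) <- pm_constituents()
  if (length(true_wqs_weights) != 15 || any(true_wqs_weights < 0))
    stopf("true_wqs_weights must be 15 non-negative values")
  if (abs(sum(true_wqs_weights) - 1) > 1e-12)
    stopf("true_wqs_weights must sum to 1 (got %.15f)", sum(true_wqs_weights))
  if (is.null(names(true_wqs_weights)))
    names(true_wqs_weights) <- pm_constituents()
  if (dispersion < 1) stopf("dispersion must be >= 1")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (remainder_fraction < 0 || remainder_fraction >= 1)
    stopf("remainder_fraction must be in [0, 1)")
  beneficiary_range <- as.integer(beneficiary_range)
  if (beneficiary_range[1] <= 100)
    stopf("beneficiary minimum must exceed 100 (panel includes only ZIPs with more than 100 beneficiaries)")
  miss <- setdiff(pm_outcomes(), names(true_rr_per_sd))
  if (length(miss)) stopf("true_rr_per_sd missing outcomes: %s",
                          paste(miss, collapse = ", "))
  if (is.null(true_source_rr)) {
    # Defaults follow the pooled source-specific estimates for total
    # non-respiratory infections (coal, traffic, oil, soil, biomass, nitrate).
    full <- c(1.182, 1.206, 1.145, 1.089, 1.089, 1.078)
    true_source_rr <- full[seq_len(n_sources)]
  }
  if (length(true_source_rr) != n_sources)
    stopf("true_source_rr must have length n_sources = %d", n_sources)
  names(true_source_rr) <- colnames(loading_matrix)
  if (is.null(cluster_multipliers)) {
    # Three regional profiles (coal-, traffic/oil- and soil/biomass-
    # dominated), normalized so every cluster has the same expected total
    # mass: region contrasts live in composition, not in total PM2.5.
    cm <- rbind(c(1.27, 0.76, 0.68, 0.51, 0.76, 1.00),
                c(0.85, 1.42, 1.70, 0.66, 0.76, 0.85),
                c(0.63, 1.01, 0.76, 2.28, 1.77, 0.70))
    cluster_multipliers <- cm[, seq_len(n_sources), drop = FALSE]
  }
  cluster_multipliers <- as.matrix(cluster_multipliers)
  if (ncol(cluster_multipliers) != n_sources || nrow(cluster_multipliers) != 3)
    stopf("cluster_multipliers must be 3 x n_sources")
  if (is.null(trend_rates)) {
    trend_rates <- c(-0.05, -0.02, -0.03, 0, 0, -0.03)[seq_len(n_sources)]
  }
  if (length(trend_rates) != n_sources)
    stopf("trend_rates must have length n_sources")
  cfg <- list(n_zips = as.integer(n_zips), years = as.integer(years),
              n_sources = as.integer(n_sources),
              loading_matrix = loading_matrix, effect_mode = effect_mode,
              true_rr_per_sd = true_rr_per_sd, rr_low = rr_low,
              rr_high = rr_high, breakpoint = breakpoint,
              true_wqs_weights = true_wqs_weights,
              true_rr_per_decile = true_rr_per_decile,
              true_source_rr = true_source_rr, sd_ref = sd_ref,
              dispersion = dispersion, baseline_rates = baseline_rates,
              covariate_effects = covariate_effects,
              confounding = confounding, year_rate_trend = year_rate_trend,
              zip_re_sd = zip_re_sd, gamma_shape = gamma_shape,
              zip_effect_sd = zip_effect_sd,
              cluster_multipliers = cluster_multipliers,
              trend_rates = trend_rates, noise_cv = noise_cv,
              remainder_fraction = remainder_fraction,
              beneficiary_range = beneficiary_range,
              seed = as.integer(seed))
  class(cfg) <- "pm_synth_config"
  cfg
}

# Internal: the zip-year grid with latent region clusters and periods.
synth_grid <- function(config) {
  zips <- sprintf("Z%04d", seq_len(config$n_zips))
  cluster <- rep_len(1:3, config$n_zips)
  grid <- expand.grid(zip = zips, year = config$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$zip, grid$year), , drop = FALSE]
  rownames(grid) <- NULL
  grid$zip_cluster <- cluster[match(grid$zip, zips)]
  grid
}

#' Draw latent source activity scores
#'
#' Generates the non-negative source-score matrix underlying a synthetic
#' panel: independent gamma draws (mean 1, variance 1/`gamma_shape`) per
#' source, multiplied by a per-ZIP lognormal random level, a per-region
#' cluster multiplier, and a deterministic exponential time trend.
#'
#' @param config A [synthetic_config()] object.
#' @return Matrix (n_zips * n_years) x n_sources with a `grid` attribute
#'   (data frame of zip, year, zip_cluster per row).
#' @export
generate_source_scores <- function(config) {
  stopifnot(inherits(config, "pm_synth_config"))
  grid <- synth_grid(config)
  n <- nrow(grid)
  k <- config$n_sources
  zips <- unique(grid$zip)
  # per-ZIP lognormal multipliers, mean 1
  zm <- matrix(exp(stats::rnorm(length(zips) * k, 0, config$zip_effect_sd) -
                     config$zip_effect_sd^2 / 2),
               nrow = length(zips), ncol = k, dimnames = list(zips, NULL))
  sh <- config$gamma_shape
  scores <- matrix(stats::rgamma(n * k, shape = sh, rate = sh),
                   nrow = n, ncol = k)
  trend <- exp(outer(grid$year - 2008, config$trend_rates))
  cm <- config$cluster_multipliers[grid$zip_cluster, , drop = FALSE]
  scores <- scores * zm[grid$zip, , drop = FALSE] * trend * cm
  colnames(scores) <- colnames(config$loading_matrix)
  attr(scores, "grid") <- grid
  scores
}

#' Generate constituent concentrations from source scores
#'
#' Computes constituent concentrations as the non-negative mixture
#' `scores %*% t(loading_matrix)` with multiplicative lognormal
#' measurement noise of a given coefficient of variation.
#'
#' @param scores Observation x source score matrix (>= 0).
#' @param loading_matrix 15 x n_sources non-negative loading matrix.
#' @param noise_cv Coefficient of variation of the lognormal noise
#'   (0 gives the exact mixture).
#' @return Observation x 15 matrix of concentrations (micrograms per
#'   cubic metre), columns named by constituent.
#' @export
generate_constituents <- function(scores, loading_matrix, noise_cv = 0.15) {
  scores <- as.matrix(scores)
  loading_matrix <- as.matrix(loading_matrix)
  if (ncol(scores) != ncol(loading_matrix))
    stopf("scores has %d sources but loading_matrix has %d columns",
          ncol(scores), ncol(loading_matrix))
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  X <- scores %*% t(loading_matrix)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(X), -sdlog^2 / 2, sdlog),
                    nrow = nrow(X))
    X <- X * noise
  }
  X[X < 0] <- 0
  colnames(X) <- rownames(loading_matrix)
  X
}

#' Total PM2.5 from constituent concentrations
#'
#' The 15 modeled constituents cover most, but not all, of total PM2.5
#' mass; total mass is the constituent row sum inflated by the unmeasured
#' remainder fraction.
#'
#' @param constituents Observation x 15 concentration matrix.
#' @param remainder_fraction Fraction of total mass not covered (default
#'   0.15).
#' @return Numeric vector of PM2.5 (micrograms per cubic metre).
#' @export
pm25_from_constituents <- function(constituents, remainder_fraction = 0.15) {
  rowSums(as.matrix(constituents)) / (1 - remainder_fraction)
}

#' Draw overdispersed counts with variance phi * mean
#'
#' Gamma-Poisson (negative binomial) mixture parameterized so that the
#' variance equals `dispersion * mu` exactly for every observation,
#' matching the quasi-Poisson variance function. `dispersion = 1` gives
#' Poisson draws.
#'
#' @param mu Vector of positive means.
#' @param dispersion Overdispersion factor phi >= 1.
#' @return Integer vector of counts.
#' @export
generate_counts <- function(mu, dispersion = 1) {
  bad <- which(!is.finite(mu) | mu < 0 | mu > 1e12)
  if (length(bad))
    stopf("non-finite or overflowing count mean at row %d (mu = %g)",
          bad[1], mu[bad[1]])
  if (dispersion < 1) stopf("dispersion must be >= 1")
  if (dispersion == 1) return(stats::rpois(length(mu), mu))
  size <- mu / (dispersion - 1)
  out <- stats::rnbinom(length(mu), size = size, mu = mu)
  out[mu == 0] <- 0L
  out
}

#' Generate a synthetic ZIP-code-year panel with known truth
#'
#' Composes [generate_source_scores()], [generate_constituents()] and
#' [generate_counts()] into a complete long-format panel: admission
#' counts per outcome category, beneficiary counts, total PM2.5 and 15
#' constituent concentrations, five standard-normal covariates (z1
#' correlated with PM2.5 to create confounding) and calendar year.
#' Returns the panel together with a `pm_truth` object recording every
#' generating parameter for recovery studies.
#'
#' @param config A [synthetic_config()] object.
#' @param seed Optional override of `config$seed`.
#' @return List with elements `panel` (data frame, one row per
#'   ZIP-code-year) and `truth` (class `pm_truth`).
#' @export
generate_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pm_synth_config"))
  if (is.null(seed)) seed <- config$seed
  run_seeded(seed, {
    grid <- synth_grid(config)
    n <- nrow(grid)
    wqs_mode <- identical(config$effect_mode, "wqs")
    scores <- NULL
    if (wqs_mode) {
      # Independent lognormal constituents at field-realistic levels so
      # that mixture weights are identifiable (no latent-factor collinearity).
      med <- c(ec = 0.5, nh4 = 1.0, no3 = 1.2, oc = 2.0, so4 = 2.5,
               br = 0.003, ca = 0.05, cu = 0.005, fe = 0.08, k = 0.07,
               ni = 0.002, pb = 0.005, si = 0.12, v = 0.003, zn = 0.012)
      X <- vapply(pm_constituents(), function(cn)
        stats::rlnorm(n, log(med[[cn]]), 0.5), numeric(n))
    } else {
      scores <- generate_source_scores(config)
      X <- generate_constituents(scores, config$loading_matrix,
                                 config$noise_cv)
    }
    pm25 <- pm25_from_constituents(X, config$remainder_fraction)

    # covariates: z1 confounded with PM2.5, z2..z5 independent
    rho <- config$confounding
    z <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("z", 1:5)))
    z[, 1] <- rho * as.numeric(scale(pm25)) + sqrt(1 - rho^2) * z[, 1]

    # beneficiaries: lognormal calibrated to the published ZIP-size
    # distribution (median 536, IQR roughly 222-1530)
    rng <- config$beneficiary_range
    ben <- round(stats::rlnorm(length(unique(grid$zip)), log(536), 1.4))
    ben <- pmin(pmax(ben, rng[1]), rng[2])
    beneficiaries <- ben[match(grid$zip, unique(grid$zip))]

    zip_re <- stats::rnorm(length(unique(grid$zip)), 0, config$zip_re_sd)
    eta_common <- drop(z %*% config$covariate_effects) -
      sum(config$covariate_effects * colMeans(z)) +
      config$year_rate_trend * (grid$year - mean(config$years)) +
      zip_re[match(grid$zip, unique(grid$zip))]

    b_ref <- log(config$true_rr_per_sd[pm_outcomes()]) / config$sd_ref
    exposure_term <- switch(config$effect_mode,
      pm25 = {
        ctr <- pm25 - mean(pm25)
        outer(ctr, b_ref)
      },
      piecewise = {
        lo <- pmin(pm25, config$breakpoint)
        hi <- pmax(pm25 - config$breakpoint, 0)
        b_lo <- log(config$rr_low) / config$sd_ref
        b_hi <- log(config$rr_high) / config$sd_ref
        term <- b_lo * lo + b_hi * hi
        matrix(term - mean(term), n, 5)
      },
      wqs = {
        q <- quantize(X, q = 10)
        idx <- drop(q$scores %*% config$true_wqs_weights)
        term <- log(config$true_rr_per_decile) * (idx - mean(idx))
        matrix(term, n, 5)
      },
      sources = {
        mass <- sweep(scores, 2, colSums(config$loading_matrix), "*")
        per <- assign_periods(grid$year)
        strat <- interaction(per, grid$zip_cluster, drop = TRUE)
        scaled <- mass
        for (s in levels(strat)) {
          r <- strat == s
          scaled[r, ] <- sweep(mass[r, , drop = FALSE], 2,
                               apply(mass[r, , drop = FALSE], 2, stats::sd), "/")
        }
        term <- drop(scaled %*% log(config$true_source_rr))
        matrix(term - mean(term), n, 5)
      })
    colnames(exposure_term) <- pm_outcomes()

    counts <- matrix(0L, n, 5, dimnames = list(NULL, pm_outcomes()))
    for (o in pm_outcomes()) {
      mu <- beneficiaries * config$baseline_rates[[o]] *
        exp(eta_common + exposure_term[, o])
      counts[, o] <- pmin(generate_counts(mu, config$dispersion),
                          beneficiaries)
    }

    panel <- data.frame(zip = grid$zip, year = grid$year,
                        stringsAsFactors = FALSE)
    for (o in pm_outcomes()) panel[[paste0("count_", o)]] <- counts[, o]
    panel$beneficiaries <- beneficiaries
    panel$pm25 <- pm25
    panel <- cbind(panel, as.data.frame(X), as.data.frame(z))
    attr(panel, "covariates") <- paste0("z", 1:5)

    truth <- list(config = config, seed = seed,
                  effect_mode = config$effect_mode,
                  beta_exposure = b_ref,
                  true_rr_per_sd = config$true_rr_per_sd,
                  true_wqs_weights = config$true_wqs_weights,
                  true_rr_per_decile = config$true_rr_per_decile,
                  true_source_rr = config$true_source_rr,
                  loading_matrix = config$loading_matrix,
                  zip_cluster = stats::setNames(
                    grid$zip_cluster[!duplicated(grid$zip)],
                    grid$zip[!duplicated(grid$zip)]),
                  scores = scores,
                  pm25_sd = stats::sd(pm25),
                  constituent_sds = apply(X, 2, stats::sd))
    class(truth) <- "pm_truth"
    list(panel = panel, truth = truth)
  })
}

#' @export
print.pm_synth_config <- function(x, ...) {
  cat("Synthetic panel configuration\n")
  cat(sprintf("  %d ZIPs x years %d-%d, %d latent sources, effect mode '%s'\n",
              x$n_zips, min(x$years), max(x$years), x$n_sources,
              x$effect_mode))
  cat(sprintf("  dispersion phi = %.2f, noise CV = %.2f, seed = %d\n",
              x$dispersion, x$noise_cv, x$seed))
  invisible(x)
}

#' @export
print.pm_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth (mode '%s'): realized PM2.5 SD %.2f\n",
              x$effect_mode, x$pm25_sd))
  invisible(x)
}
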