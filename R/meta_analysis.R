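#' Mutually adjusted stratum-specific source-effect regressions
#'
#' Within each stratum of a [apportion()] model, fits a quasi-Poisson
#' rate regression of the outcome on all identified SD-rescaled source
#' exposures simultaneously (mutually adjusted) plus covariates,
#' calendar-year indicators and the log person-time offset, with
#' cluster-robust (ZIP) standard errors. One effect record is returned
#' per (stratum, labeled source).
#'
#' @param panel Panel data frame used to build the source model.
#' @param source_model A `pm_source_model` from [apportion()].
#' @param outcome Outcome category or count column.
#' @param covariates Adjustment terms; default panel covariates plus
#'   calendar-year indicators.
#' @param offset Person-time column (default "beneficiaries").
#' @param include_unassigned Keep unlabeled factors in the model (they
#'   are always adjusted for; this controls whether their effects are
#'   also reported). Default FALSE.
#' @return Data frame of class `pm_stratum_effects`: columns `stratum`,
#'   `source`, `outcome`, `log_rr` (per SD), `se` (robust), `n_obs`.
#' @export
fit_stratum_models <- function(panel, source_model, outcome,
                               covariates = NULL,
                               offset = "beneficiaries",
                               include_unassigned = FALSE) {
  stopifnot(inherits(source_model, "pm_source_model"))
  if (is.null(covariates)) covariates <- attr(panel, "covariates")
  res <- list()
  for (s in source_model$strata) {
    E <- s$scaled
    if (ncol(E) < 2) stopf("stratum %s has fewer than 2 source factors",
                           s$stratum)
    cm <- stats::cor(E)
    diag(cm) <- 0
    if (any(abs(cm) > 0.99)) {
      ix <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      stopf("collinear source factors in stratum %s: %s and %s (|r| = %.3f)",
            s$stratum, s$labels[ix[1]], s$labels[ix[2]], max(abs(cm)))
    }
    sub <- panel[s$rows, , drop = FALSE]
    src_cols <- sprintf("src_f%d", seq_len(ncol(E)))
    for (j in seq_len(ncol(E))) sub[[src_cols[j]]] <- E[, j]
    covs <- c(src_cols[-1], covariates,
              if (length(unique(sub$year)) > 1) "factor(year)")
    fit <- fit_quasipoisson(sub, outcome, exposure = src_cols[1],
                            covariates = covs, offset = offset,
                            cluster_by = "zip")
    se_all <- sqrt(diag(fit$vcov_robust))
    for (j in seq_len(ncol(E))) {
      if (!include_unassigned && s$labels[j] == "unassigned") next
      res[[length(res) + 1]] <- data.frame(
        stratum = s$stratum, source = s$labels[j], outcome = outcome,
        log_rr = unname(fit$coefficients[src_cols[j]]),
        se = unname(se_all[src_cols[j]]),
        n_obs = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("pm_stratum_effects", class(out))
  out
}

#' DerSimonian-Laird random-effects pooling of stratum effects
#'
#' Pools per-source log rate ratios across strata with the
#' moment-based DerSimonian-Laird estimator: with fixed-effect weights
#' `w_i = 1/se_i^2`, Cochran's `Q = sum w_i (y_i - ybar)^2`, and
#' `tau2 = max(0, (Q - (k-1)) / (sum w_i - sum w_i^2 / sum w_i))`; the
#' pooled estimate uses weights `1 / (se_i^2 + tau2)` with a normal 95
#' percent interval. A single stratum passes through with a warning.
#'
#' @param effects Data frame with columns `source`, `outcome`, `log_rr`,
#'   `se` (e.g. from [fit_stratum_models()]).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame of class `pm_pooled`: one row per (source,
#'   outcome) with `log_rr`, `se`, `ci_low`, `ci_high` (rate-ratio
#'   scale), `rr`, `percent`, `tau2`, `q_stat`, `k_strata`.
#' @export
pool_random_effects <- function(effects, conf_level = 0.95) {
  if (any(effects$se <= 0)) stopf("all standard errors must be positive")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  groups <- unique(effects[, c("source", "outcome"), drop = FALSE])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- effects[effects$source == groups$source[i] &
                   effects$outcome == groups$outcome[i], , drop = FALSE]
    y <- g$log_rr
    v <- g$se^2
    k <- nrow(g)
    if (k == 1) {
      warning(sprintf("source '%s': single stratum, passing through",
                      groups$source[i]))
      tau2 <- 0; Q <- 0
      mu <- y; se <- g$se
    } else {
      w <- 1 / v
      ybar <- sum(w * y) / sum(w)
      Q <- sum(w * (y - ybar)^2)
      tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
      ws <- 1 / (v + tau2)
      mu <- sum(ws * y) / sum(ws)
      se <- sqrt(1 / sum(ws))
    }
    data.frame(source = groups$source[i], outcome = groups$outcome[i],
               log_rr = mu, se = se, rr = exp(mu),
               ci_low = exp(mu - zq * se), ci_high = exp(mu + zq * se),
               percent = 100 * (exp(mu) - 1), tau2 = tau2, q_stat = Q,
               k_strata = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pm_pooled", class(out))
  out
}
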