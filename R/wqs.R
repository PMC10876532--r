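#' Decile-score a constituent matrix
#'
#' Converts each constituent column to integer quantile scores
#' 0..(q - 1) using empirical quantile cut points computed on the data
#' supplied (by convention the full panel, so that bootstrap resamples
#' share one set of cut points). A value's score is the number of cut
#' points strictly below it; values tied with a cut point therefore fall
#' in the lower bin.
#'
#' @param x Matrix or data frame of raw concentrations.
#' @param q Number of quantile groups (default 10, deciles).
#' @return Object of class `pm_quantized`: list with the
#'   integer-valued `scores` matrix (double storage), `cutpoints` list,
#'   and `q`.
#' @export
quantize <- function(x, q = 10) {
  x <- as.matrix(x)
  if (q < 2) stopf("q must be at least 2")
  nd <- apply(x, 2, function(v) length(unique(v)))
  if (any(nd < q))
    stopf("column(s) with fewer than %d distinct values: %s", q,
          paste(colnames(x)[nd < q], collapse = ", "))
  cuts <- lapply(seq_len(ncol(x)), function(j)
    stats::quantile(x[, j], probs = seq_len(q - 1) / q, names = FALSE,
                    type = 7))
  names(cuts) <- colnames(x)
  scores <- vapply(seq_len(ncol(x)), function(j)
    findInterval(x[, j], cuts[[j]], left.open = TRUE), integer(nrow(x)))
  colnames(scores) <- colnames(x)
  storage.mode(scores) <- "double"  # avoids re-coercion in matrix products
  out <- list(scores = scores, cutpoints = cuts, q = q)
  class(out) <- "pm_quantized"
  out
}

# Softmax over logits with a fixed zero reference in the last position.
softmax_ref <- function(theta_free) {
  th <- c(theta_free, 0)
  w <- exp(th - max(th))
  w / sum(w)
}

# Negative Poisson log-likelihood (up to constants) and gradient for the
# WQS model log mu = Zl b + beta1 * (Q w) + off, w = softmax(theta).
wqs_objective <- function(Zl, Q, y, off) {
  p <- ncol(Zl)
  m <- ncol(Q)
  cache <- new.env(parent = emptyenv())
  compute <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(invisible())
    b <- par[seq_len(p)]
    beta1 <- par[p + 1]
    w <- softmax_ref(par[-seq_len(p + 1)])
    s <- drop(Q %*% w)
    eta <- drop(Zl %*% b) + beta1 * s + off
    mu <- exp(pmin(eta, 500))
    cache$par <- par; cache$w <- w; cache$s <- s
    cache$eta <- eta; cache$mu <- mu
    invisible()
  }
  fn <- function(par) {
    compute(par)
    v <- sum(cache$mu) - sum(y * cache$eta)
    if (!is.finite(v)) v <- .Machine$double.xmax / 1e6
    v
  }
  gr <- function(par) {
    compute(par)
    r <- cache$mu - y
    beta1 <- par[p + 1]
    g_b <- drop(crossprod(Zl, r))
    g_beta1 <- sum(r * cache$s)
    gw <- beta1 * drop(crossprod(Q, r))
    w <- cache$w
    g_th <- (w * (gw - sum(w * gw)))[-m]
    g <- c(g_b, g_beta1, g_th)
    g[!is.finite(g)] <- 0
    g
  }
  list(fn = fn, gr = gr)
}

# Fisher scoring (Gauss-Newton) on the joint nonlinear predictor
# eta = Zl b + beta1 * (Q softmax(theta)) + off with Poisson weights.
# Quadratic local convergence makes warm-started bootstrap fits cheap;
# step-halving guards the ascent. Returns NULL on breakdown (caller
# falls back to BFGS).
wqs_scoring <- function(Q, y, Zl, off, par0, maxit = 100, reltol = 1e-8) {
  p <- ncol(Zl)
  m <- ncol(Q)
  obj <- wqs_objective(Zl, Q, y, off)
  par <- par0
  nll <- obj$fn(par)
  if (!is.finite(nll)) return(NULL)
  for (it in seq_len(maxit)) {
    b <- par[seq_len(p)]
    beta1 <- par[p + 1]
    w <- softmax_ref(par[-seq_len(p + 1)])
    s <- drop(Q %*% w)
    eta <- drop(Zl %*% b) + beta1 * s + off
    mu <- exp(pmin(eta, 500))
    M <- diag(w) - tcrossprod(w)
    J <- cbind(Zl, s, beta1 * (Q %*% M[, -m, drop = FALSE]))
    r <- y - mu
    g <- drop(crossprod(J, r))
    A <- crossprod(J, J * mu)
    diag(A) <- diag(A) + 1e-8 * max(diag(A), 1e-8)
    step <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    # step-halving line search on the negative log-likelihood
    ok <- FALSE
    fac <- 1
    for (h in 1:12) {
      cand <- par + fac * step
      v <- obj$fn(cand)
      if (is.finite(v) && v <= nll + 1e-12) { ok <- TRUE; break }
      fac <- fac / 2
    }
    if (!ok) break
    conv <- (nll - v) < reltol * (abs(nll) + 1e-10)
    par <- cand
    nll <- v
    if (conv) return(list(par = par, value = nll, convergence = 0))
  }
  list(par = par, value = nll, convergence = 1)
}

# Quasi-Poisson fit of y ~ Zl + index with offset, index coefficient and
# model-based SE only; used for bootstrap signal weights.
fixed_index_fit <- function(Zl, index, y, off) {
  X <- cbind(Zl, wqs_index = index)
  f <- stats::glm.fit(X, y, family = stats::poisson(), offset = off)
  mu <- f$fitted.values
  phi <- sum((y - mu)^2 / mu) / (length(y) - ncol(X))
  R <- qr.R(f$qr)
  cov_u <- chol2inv(R)
  se <- sqrt(phi * diag(cov_u))
  k <- ncol(X)
  list(beta = f$coefficients[k], se = se[k], phi = phi)
}

#' Single constrained WQS fit
#'
#' Maximizes the Poisson likelihood of
#' `log mu = Zl b + beta1 * (Q w) + offset` over the regression
#' coefficients jointly with mixture weights `w` constrained to the
#' probability simplex (non-negative, summing to one) via a softmax
#' reparameterization, using BFGS with analytic gradients. Deterministic
#' multi-start (uniform weights, a start informed by univariate
#' residual associations, and a negative-direction start) mitigates
#' local optima; a supplied warm start replaces the multi-start.
#'
#' @param Q Integer quantile-score matrix (observations x constituents).
#' @param y Count outcome vector.
#' @param Zl Linear-covariate design matrix (including intercept).
#' @param off Log person-time offset vector.
#' @param start Optional warm-start parameter vector from a previous fit.
#' @param n_starts Number of deterministic starts when `start` is NULL.
#' @param maxit BFGS iteration cap.
#' @param reltol Relative convergence tolerance on the objective
#'   (default 1e-8).
#' @return List: `weights` (simplex vector), `beta_index`, `se_index`
#'   (model-based quasi-Poisson SE at the fitted weights), `coefficients`
#'   (linear part), `par`, `value`, `converged`.
#' @export
wqs_fit_single <- function(Q, y, Zl, off, start = NULL, n_starts = 3,
                           maxit = 400, reltol = 1e-8) {
  p <- ncol(Zl)
  m <- ncol(Q)
  obj <- wqs_objective(Zl, Q, y, off)
  starts <- list()
  if (!is.null(start)) {
    starts[[1]] <- start
  } else {
    base <- stats::glm.fit(Zl, y, family = stats::poisson(), offset = off)
    b0 <- base$coefficients
    r0 <- y - base$fitted.values
    u <- drop(crossprod(Q, r0))
    u <- u / max(abs(u), 1e-12)
    starts[[1]] <- c(b0, 0.01, rep(0, m - 1))
    if (n_starts >= 2) starts[[2]] <- c(b0, 0.05, (2 * u)[-m])
    if (n_starts >= 3) starts[[3]] <- c(b0, -0.01, rep(0, m - 1))
  }
  best <- NULL
  for (s in starts) {
    ans <- wqs_scoring(Q, y, Zl, off, s, maxit = maxit, reltol = reltol)
    if (is.null(ans) || ans$convergence != 0)
      ans <- tryCatch(
        stats::optim(s, obj$fn, obj$gr, method = "BFGS",
                     control = list(maxit = maxit, reltol = reltol)),
        error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$value < best$value) best <- ans
  }
  if (is.null(best)) stopf("WQS optimization failed for all starts")
  w <- softmax_ref(best$par[-seq_len(p + 1)])
  names(w) <- colnames(Q)
  idx <- drop(Q %*% w)
  fx <- fixed_index_fit(Zl, idx, y, off)
  list(weights = w, beta_index = best$par[p + 1], se_index = fx$se,
       coefficients = best$par[seq_len(p)], par = best$par,
       value = best$value, converged = best$convergence == 0)
}

#' Bootstrap weighted quantile sum regression
#'
#' Estimates the association between a quantized constituent mixture and
#' an admission count outcome with a quasi-Poisson link. Decile cut
#' points are computed once on the full panel; `B` bootstrap resamples of
#' ZIP-code-year rows are each fit with positivity-constrained weights
#' ([wqs_fit_single()], warm-started from the full-data solution); the
#' final weights are the signal-weighted average of bootstrap weight
#' vectors (weights proportional to each bootstrap's |t| statistic for
#' the index; plain averaging available). The mixture coefficient and its
#' 95 percent interval come from refitting the full panel with the index
#' fixed at the aggregated weights, with cluster-robust variance.
#'
#' @param panel Panel data frame.
#' @param outcome Outcome category or count column.
#' @param constituents Constituent column names (default the 15 modeled
#'   constituents).
#' @param covariates Adjustment terms; default panel covariates plus
#'   calendar-year indicators.
#' @param offset Person-time column (default "beneficiaries").
#' @param q Number of quantile groups (default 10).
#' @param B Number of bootstrap samples (default 100).
#' @param seed RNG seed controlling resampling.
#' @param aggregation "signal" (default) or "mean".
#' @param n_starts Multi-start count for the full-data fit.
#' @param cluster_by Cluster column for the final robust CI.
#' @return Object of class `pm_wqs_fit`: aggregated `weights`,
#'   `beta_index` (log RR per decile), `rr_per_decile` with `ci_low` /
#'   `ci_high`, `bootstrap_weights` (B x 15), `bootstrap_beta`,
#'   `n_failed`, `influence_threshold`, and the final `fit`
#'   (`pm_glm_fit`).
#' @export
fit_wqs_bootstrap <- function(panel, outcome,
                              constituents = pm_constituents(),
                              covariates = NULL, offset = "beneficiaries",
                              q = 10, B = 100, seed = 1,
                              aggregation = c("signal", "mean"),
                              n_starts = 3, cluster_by = "zip") {
  aggregation <- match.arg(aggregation)
  if (B < 2) stopf("B must be at least 2")
  ycol <- count_col(outcome)
  if (is.null(covariates))
    covariates <- c(attr(panel, "covariates"),
                    if (length(unique(panel$year)) > 1) "factor(year)")
  qz <- quantize(panel[, constituents, drop = FALSE], q = q)
  Q <- qz$scores
  y <- panel[[ycol]]
  off <- log(panel[[offset]])
  Zl <- stats::model.matrix(stats::reformulate(covariates), panel)

  full <- wqs_fit_single(Q, y, Zl, off, n_starts = n_starts)

  n <- nrow(panel)
  m <- length(constituents)
  bw <- matrix(NA_real_, B, m, dimnames = list(NULL, constituents))
  bb <- rep(NA_real_, B)
  bse <- rep(NA_real_, B)
  run_seeded(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(
        wqs_fit_single(Q[idx, , drop = FALSE], y[idx],
                       Zl[idx, , drop = FALSE], off[idx],
                       start = full$par, maxit = 200, reltol = 1e-8),
        error = function(e) NULL)
      if (is.null(fb) || !is.finite(fb$se_index) || fb$se_index <= 0) next
      bw[b, ] <- fb$weights
      bb[b] <- fb$beta_index
      bse[b] <- fb$se_index
    }
  })
  ok <- !is.na(bb)
  if (sum(ok) < B / 2)
    stopf("more than half of the bootstrap fits failed (%d of %d)",
          sum(!ok), B)
  sig <- if (aggregation == "signal") abs(bb[ok] / bse[ok]) else rep(1, sum(ok))
  w_agg <- drop(crossprod(bw[ok, , drop = FALSE], sig)) / sum(sig)
  w_agg <- w_agg / sum(w_agg)

  panel$wqs_index <- drop(Q %*% w_agg)
  final <- fit_quasipoisson(panel, outcome, exposure = "wqs_index",
                            covariates = covariates, offset = offset,
                            cluster_by = cluster_by)
  rr <- rr_per_delta(final, delta = 1)
  out <- list(weights = w_agg, beta_index = log(rr$rr),
              rr_per_decile = rr$rr, ci_low = rr$ci_low,
              ci_high = rr$ci_high, percent = rr$percent,
              bootstrap_weights = bw[ok, , drop = FALSE],
              bootstrap_beta = bb[ok], bootstrap_se = bse[ok],
              n_failed = sum(!ok), B = sum(ok),
              influence_threshold = 1 / m,
              full_data_weights = full$weights,
              outcome = outcome, fit = final, seed = seed)
  class(out) <- "pm_wqs_fit"
  out
}

#' @export
print.pm_wqs_fit <- function(x, digits = 3, ...) {
  cat(sprintf("WQS fit, outcome '%s' (%d bootstrap fits, %d failed)\n",
              x$outcome, x$B, x$n_failed))
  cat(sprintf("  RR per decile of mixture index: %.3f (95%% CI %.3f-%.3f)\n",
              x$rr_per_decile, x$ci_low, x$ci_high))
  w <- sort(x$weights, decreasing = TRUE)
  cat("  top weights:",
      paste(sprintf("%s %.1f%%", names(w)[1:3], 100 * w[1:3]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Constituents above the equal-weight influence threshold
#'
#' Flags constituents whose aggregated WQS weight exceeds 1/m (the value
#' every constituent would take if all contributed equally), the
#' customary threshold for "most influential" mixture members.
#'
#' @param fit A `pm_wqs_fit` object (or a bare named weight vector).
#' @param threshold Influence cutoff; default 1/m.
#' @return Character vector of flagged constituent names, ordered by
#'   decreasing weight.
#' @export
influential_constituents <- function(fit, threshold = NULL) {
  w <- if (inherits(fit, "pm_wqs_fit")) fit$weights else fit
  if (is.null(threshold)) threshold <- 1 / length(w)
  w <- sort(w[w > threshold], decreasing = TRUE)
  names(w)
}
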