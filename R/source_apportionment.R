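#' Assign calendar years to analysis periods
#'
#' @param year Integer vector of years.
#' @param periods Named list of year vectors; default the three periods
#'   2000-2005, 2006-2010 and 2011-2016.
#' @return Factor of period labels (NA for years outside all periods).
#' @export
assign_periods <- function(year,
                           periods = list("2000-2005" = 2000:2005,
                                          "2006-2010" = 2006:2010,
                                          "2011-2016" = 2011:2016)) {
  lab <- rep(NA_character_, length(year))
  for (p in names(periods)) lab[year %in% periods[[p]]] <- p
  factor(lab, levels = names(periods))
}

#' Per-ZIP mean constituent profiles within a period
#'
#' @param panel Panel data frame.
#' @param years Years defining the period.
#' @param constituents Constituent columns (default all 15).
#' @return Matrix (ZIPs x constituents) of arithmetic means, rows ordered
#'   by ZIP code; ZIPs absent from the period are excluded with a message.
#' @export
mean_profiles <- function(panel, years, constituents = pm_constituents()) {
  sub <- panel[panel$year %in% years, , drop = FALSE]
  if (nrow(sub) == 0) stopf("no rows in the requested period")
  zips <- sort(unique(panel$zip))
  present <- sort(unique(sub$zip))
  missing <- setdiff(zips, present)
  if (length(missing))
    message(sprintf("mean_profiles: %d ZIP(s) absent from period, excluded",
                    length(missing)))
  prof <- t(vapply(present, function(z)
    colMeans(sub[sub$zip == z, constituents, drop = FALSE]),
    numeric(length(constituents))))
  rownames(prof) <- present
  colnames(prof) <- constituents
  prof
}

#' Ward's hierarchical clustering of constituent profiles
#'
#' Agglomerative clustering with Ward's minimum-variance linkage
#' (`hclust` method "ward.D2") on Euclidean distances between
#' per-constituent standardized profiles, cut at `k` clusters. Profiles
#' are standardized by default because the high-mass species (sulfate,
#' nitrate, organic carbon) would otherwise dominate the distance.
#' Rows are ordered by name before clustering so the labels do not depend
#' on input row order.
#'
#' @param profiles ZIPs x constituents matrix (rownames = ZIP codes).
#' @param k Number of clusters (default 3).
#' @param standardize Standardize columns before computing distances.
#' @return Named integer vector of cluster labels (1..k), names = ZIPs.
#' @export
ward_cluster <- function(profiles, k = 3, standardize = TRUE) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles))
    stopf("k = %d exceeds the number of profiles (%d)", k, nrow(profiles))
  ord <- order(rownames(profiles))
  profiles <- profiles[ord, , drop = FALSE]
  Xs <- if (standardize) {
    sds <- apply(profiles, 2, stats::sd)
    sweep(sweep(profiles, 2, colMeans(profiles)), 2, pmax(sds, 1e-12), "/")
  } else profiles
  hc <- stats::hclust(stats::dist(Xs), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative data matrix `X` (observations x
#' constituents) as `X ~ H %*% t(W)` with `W` (constituents x k) and `H`
#' (observations x k) non-negative, minimizing Frobenius reconstruction
#' error with Lee-Seung multiplicative updates. The best of `n_init`
#' seeded random restarts is kept. Columns of `W` are normalized to unit
#' sum with the compensating scale absorbed into `H`, so `H[i, k]` is the
#' mass (micrograms per cubic metre) contributed by factor k to
#' observation i.
#'
#' @param X Non-negative matrix, observations in rows.
#' @param k Number of factors (k < min(dim(X))).
#' @param seed RNG seed for the restarts.
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Update iterations per restart (default 1000).
#' @param tol Relative-error improvement tolerance for early stopping.
#' @return List: `W` (15 x k, unit column sums), `H` (n x k), `error`
#'   (relative Frobenius error), `converged`, `iterations`.
#' @export
fit_nmf <- function(X, k, seed = 1, n_init = 10, max_iter = 1000,
                    tol = 1e-5) {
  X <- as.matrix(X)
  if (any(X < 0)) stopf("X must be non-negative")
  if (k >= min(dim(X))) stopf("k must be smaller than both dimensions of X")
  eps <- 1e-12
  nx <- sqrt(sum(X^2))
  best <- NULL
  run_seeded(seed, {
    for (init in seq_len(n_init)) {
      mx <- mean(X)
      H <- matrix(stats::runif(nrow(X) * k, 0, sqrt(mx)), nrow(X), k)
      Wt <- matrix(stats::runif(k * ncol(X), 0, sqrt(mx)), k, ncol(X))
      err_prev <- Inf
      converged <- FALSE
      it <- 0
      for (it in seq_len(max_iter)) {
        H <- H * (X %*% t(Wt)) / (H %*% (Wt %*% t(Wt)) + eps)
        Wt <- Wt * (t(H) %*% X) / ((t(H) %*% H) %*% Wt + eps)
        if (it %% 10 == 0 || it == max_iter) {
          err <- sqrt(sum((X - H %*% Wt)^2)) / nx
          if (is.finite(err_prev) && err_prev - err < tol * max(err, 1e-12)) {
            converged <- TRUE
            err_prev <- err
            break
          }
          err_prev <- err
        }
      }
      if (is.null(best) || err_prev < best$error)
        best <- list(H = H, Wt = Wt, error = err_prev,
                     converged = converged, iterations = it)
    }
  })
  if (!best$converged)
    warning("NMF did not reach the improvement tolerance; returning best iterate")
  W <- t(best$Wt)
  s <- colSums(W)
  s[s < eps] <- eps
  W <- sweep(W, 2, s, "/")
  H <- sweep(best$H, 2, s, "*")
  ord <- order(colSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[, ord, drop = FALSE]
  rownames(W) <- colnames(X)
  colnames(W) <- colnames(H) <- paste0("factor", seq_len(k))
  list(W = W, H = H, error = best$error, converged = best$converged,
       iterations = best$iterations)
}

#' Choose the NMF rank between candidate values
#'
#' Fits each candidate rank and selects by interpretability, the
#' receptor-modelling criterion: the rank whose factors map to the
#' largest number of distinct tracer-labeled sources wins; ties go to
#' the smaller rank (parsimony). Variance-based gains do not separate
#' the candidate ranks here because an extra factor can always absorb
#' structured multiplicative noise in the high-mass species, whereas a
#' genuine extra source earns an additional tracer label and a spurious
#' one does not.
#'
#' @param X Non-negative matrix.
#' @param ks Candidate ranks in increasing order (default 4:5).
#' @param rules Tracer rule table for the labeling step.
#' @param ... Passed to [fit_nmf()].
#' @return The selected [fit_nmf()] result with added `k`, `labels` and
#'   `explained_variance` (share of centered total variance) elements.
#' @export
choose_nmf_rank <- function(X, ks = c(4, 5), rules = pm_tracer_rules(), ...) {
  fits <- lapply(ks, function(k) fit_nmf(X, k, ...))
  labs <- lapply(fits, function(f) label_sources(f$W, rules = rules))
  n_assigned <- vapply(labs, function(l) sum(l != "unassigned"), integer(1))
  pick <- which.max(n_assigned)  # first max: ties favor the smaller rank
  out <- fits[[pick]]
  out$k <- ks[pick]
  out$labels <- labs[[pick]]
  tss <- sum(scale(X, scale = FALSE)^2)
  out$explained_variance <- 1 - out$error^2 * sum(X^2) / tss
  out
}

#' Label NMF factors with emission sources via tracer rules
#'
#' For each factor, the share of every constituent's loading explained by
#' that factor is computed (rows of `W` normalized to sum one across
#' factors); a factor's score for a candidate source is the mean share of
#' that source's tracer constituents. Factors and labels are matched
#' greedily by decreasing score, each label used at most once; factors
#' whose best remaining score falls below `min_score` are labeled
#' "unassigned" (a factor must explain at least that fraction of its
#' tracers' mass to earn a source name).
#'
#' @param W Constituents x factors loading matrix (unit column sums).
#' @param rules Tracer rule table ([pm_tracer_rules()] by default).
#' @param min_score Minimum mean tracer share (default 0.35).
#' @return Character vector of labels, one per factor.
#' @export
label_sources <- function(W, rules = pm_tracer_rules(), min_score = 0.35) {
  W <- as.matrix(W)
  k <- ncol(W)
  share <- W / pmax(rowSums(W), 1e-12)
  scores <- matrix(NA_real_, k, length(rules),
                   dimnames = list(colnames(W), names(rules)))
  for (r in names(rules)) {
    tr <- intersect(rules[[r]], rownames(W))
    if (!length(tr)) next
    scores[, r] <- colMeans(share[tr, , drop = FALSE])
  }
  labels <- rep("unassigned", k)
  used <- character(0)
  repeat {
    s <- scores
    s[labels != "unassigned", ] <- NA
    s[, used] <- NA
    if (all(is.na(s)) || max(s, na.rm = TRUE) < min_score) break
    ix <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
    labels[ix[1]] <- colnames(scores)[ix[2]]
    used <- c(used, colnames(scores)[ix[2]])
  }
  labels
}

#' Mass contributions and SD-rescaled source exposures
#'
#' Under the unit-column-sum convention of [fit_nmf()], factor k's mass
#' contribution to an observation is `H[i, k] * sum(W[, k])` micrograms
#' per cubic metre. Each factor's series is then divided by its standard
#' deviation so that effect estimates are per SD of source-specific
#' PM2.5. Zero-variance factors are dropped with a warning.
#'
#' @param W Constituents x factors loading matrix.
#' @param H Observations x factors score matrix.
#' @return List: `mass` (micrograms per cubic metre), `scaled` (SD
#'   units, per-column SD = 1), `sds` (the divisors), `kept` (column
#'   indices retained).
#' @export
massify_and_scale <- function(W, H) {
  mass <- sweep(as.matrix(H), 2, colSums(as.matrix(W)), "*")
  sds <- apply(mass, 2, stats::sd)
  kept <- which(sds > 1e-10)
  if (length(kept) < ncol(mass))
    warning(sprintf("dropping %d zero-variance factor(s)",
                    ncol(mass) - length(kept)))
  mass <- mass[, kept, drop = FALSE]
  scaled <- sweep(mass, 2, sds[kept], "/")
  list(mass = mass, scaled = scaled, sds = sds[kept], kept = kept)
}

#' Stratified NMF source apportionment of a constituent panel
#'
#' Implements the full apportionment chain: rows are assigned to time
#' periods; within each period ZIP codes are grouped into `k_clusters`
#' Ward clusters of mean constituent profiles; within each of the
#' resulting strata (period x cluster) an NMF of the zip-year constituent
#' matrix is fit at the rank chosen from `ranks`, factors are labeled by
#' tracer rules, and factor scores are converted to mass and rescaled to
#' SD units within the stratum.
#'
#' @param panel Panel data frame.
#' @param periods Named list of year vectors (default the three standard
#'   periods).
#' @param k_clusters Ward clusters per period (default 3).
#' @param ranks Candidate NMF ranks (default 4:5).
#' @param seed RNG seed (NMF restarts).
#' @param constituents Constituent columns.
#' @param n_init NMF restarts per rank.
#' @param standardize_nmf Run the factorization on per-constituent
#'   SD-standardized concentrations (default TRUE), converting factor
#'   levels back to micrograms per cubic metre afterwards. Without this,
#'   the Frobenius objective is dominated by the high-mass species and
#'   factors traced by low-mass elements (Ni, V, Cu) are not
#'   identifiable; tracer labeling is invariant to the choice.
#' @return Object of class `pm_source_model`: list of strata, each with
#'   `stratum`, `period`, `cluster`, `rows` (panel row indices), `k`,
#'   `W`, `labels`, `mass`, `scaled`, `sds`, `error`; plus
#'   `zip_clusters` (per period) and `periods`.
#' @export
apportion <- function(panel, periods = list("2000-2005" = 2000:2005,
                                            "2006-2010" = 2006:2010,
                                            "2011-2016" = 2011:2016),
                      k_clusters = 3, ranks = c(4, 5), seed = 1,
                      constituents = pm_constituents(), n_init = 10,
                      standardize_nmf = TRUE) {
  per <- assign_periods(panel$year, periods)
  if (anyNA(per))
    stopf("%d rows have years outside the given periods", sum(is.na(per)))
  strata <- list()
  zip_clusters <- list()
  for (p in names(periods)) {
    rows_p <- which(per == p)
    if (!length(rows_p)) next
    prof <- mean_profiles(panel[rows_p, , drop = FALSE], periods[[p]],
                          constituents)
    cl <- ward_cluster(prof, k = k_clusters)
    zip_clusters[[p]] <- cl
    for (cc in sort(unique(cl))) {
      rows <- rows_p[panel$zip[rows_p] %in% names(cl)[cl == cc]]
      X <- as.matrix(panel[rows, constituents, drop = FALSE])
      sdj <- pmax(apply(X, 2, stats::sd), 1e-12)
      Xin <- if (standardize_nmf) sweep(X, 2, sdj, "/") else X
      fit <- choose_nmf_rank(Xin, ks = ranks, seed = seed + cc,
                             n_init = n_init)
      labels <- fit$labels
      W <- fit$W
      H <- fit$H
      if (standardize_nmf) {
        # undo the scaling: X ~ H (W * sd)^T, then renormalize columns
        W <- sweep(W, 1, sdj, "*")
        cw <- colSums(W)
        W <- sweep(W, 2, cw, "/")
        H <- sweep(H, 2, cw, "*")
      }
      ms <- massify_and_scale(W, H)
      labels <- labels[ms$kept]
      strata[[paste(p, cc, sep = "/")]] <-
        list(stratum = paste(p, cc, sep = "/"), period = p, cluster = cc,
             rows = rows, k = fit$k, W = W, labels = labels,
             mass = ms$mass, scaled = ms$scaled, sds = ms$sds,
             error = fit$error)
    }
  }
  out <- list(strata = strata, zip_clusters = zip_clusters,
              periods = periods, constituents = constituents, seed = seed)
  class(out) <- "pm_source_model"
  out
}

#' @export
print.pm_source_model <- function(x, ...) {
  cat(sprintf("Source apportionment: %d strata\n", length(x$strata)))
  for (s in x$strata)
    cat(sprintf("  %s: k = %d, rel. error %.3f, labels: %s\n",
                s$stratum, s$k, s$error, paste(s$labels, collapse = ", ")))
  invisible(x)
}

#' Best-permutation cosine match between estimated and true loadings
#'
#' Matches estimated factor loadings to reference loadings by the
#' factor permutation maximizing total column-wise cosine similarity
#' (exhaustive over permutations; intended for small k) and returns the
#' matched cosines.
#'
#' @param W_est,W_ref Loading matrices with the same row space
#'   (constituents x factors); `W_ref` may have at least as many columns.
#' @return Numeric vector: for each estimated factor, the cosine with its
#'   matched reference column; names give the matched reference column.
#' @export
match_factors <- function(W_est, W_ref) {
  W_est <- as.matrix(W_est); W_ref <- as.matrix(W_ref)
  k <- ncol(W_est)
  if (ncol(W_ref) < k) stopf("W_ref needs at least %d columns", k)
  cs <- matrix(0, k, ncol(W_ref))
  for (i in seq_len(k)) for (j in seq_len(ncol(W_ref)))
    cs[i, j] <- cosine_cols(W_est[, i], W_ref[, j])
  perms <- permutations_of(seq_len(ncol(W_ref)), k)
  tot <- vapply(perms, function(p) sum(cs[cbind(seq_len(k), p)]),
                numeric(1))
  best <- perms[[which.max(tot)]]
  out <- cs[cbind(seq_len(k), best)]
  names(out) <- colnames(W_ref)[best]
  out
}

# All ordered selections of `k` elements from `v` (k! * choose(n,k) total).
permutations_of <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i], k - 1))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}
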