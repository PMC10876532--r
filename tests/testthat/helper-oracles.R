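# Independent oracles and small fixture builders used across tests.

# Hand-rolled iteratively reweighted least squares for a Poisson GLM with
# log link and offset; independent of stats::glm.
irls_poisson_oracle <- function(X, y, offset, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(sum(y) / sum(exp(offset)))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    z <- eta - offset + (y - mu) / mu
    fit <- lm.wfit(X, z, w = mu)
    new <- fit$coefficients
    if (max(abs(new - beta)) < tol) return(new)
    beta <- new
  }
  beta
}

# Direct transcription of the DerSimonian-Laird formulas.
dl_oracle <- function(y, se) {
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(mu = sum(ws * y) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2,
       Q = Q)
}

# A small deterministic-seed panel for GLM-level tests.
small_panel <- function(n_zips = 100, n_years = 5, seed = 42, ...) {
  cfg <- synthetic_config(n_zips = n_zips, years = 2000 + seq_len(n_years),
                          seed = seed, ...)
  generate_panel(cfg)
}

# Uniform-weight helper on the 15 constituents.
weights_with_top3 <- function(so4 = 0.308, ni = 0.225, cu = 0.153) {
  w <- setNames(rep((1 - so4 - ni - cu) / 12, 15), pm_constituents())
  w[c("so4", "ni", "cu")] <- c(so4, ni, cu)
  w
}

run_seeded <- pmsource:::run_seeded
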