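# Independent oracles used to cross-check the implementation.

# NIPALS first weight vector for a single response, iterated to
# convergence (independent of the closed-form path in the package).
nipals_first_weights <- function(X_samples_by_genes, y, tol = 1e-12,
                                 max_iter = 500L) {
  u <- y - mean(y)
  Xc <- scale(X_samples_by_genes, scale = FALSE)
  w <- rep(1 / sqrt(ncol(Xc)), ncol(Xc))
  for (i in seq_len(max_iter)) {
    w_new <- drop(crossprod(Xc, u))
    w_new <- w_new / sqrt(sum(w_new^2))
    if (sqrt(sum((w_new - w)^2)) < tol) return(w_new)
    w <- w_new
  }
  w
}

# Hand-rolled two-sample log-rank chi-square (O - E with hypergeometric
# variance summed over distinct event times).
logrank_chi2_oracle <- function(times, events, grp) {
  g1 <- grp == sort(unique(grp))[1L]
  OmE <- 0
  V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# Brute-force Benjamini-Hochberg from the step-up definition:
# adj_(i) = min over j >= i of p_(j) * n / j, clipped at 1.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(p[o][i:n] * n / (i:n)))
  }
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# Monte-Carlo standard error of sq_sum/K per gene: w_i^2/(1-u_i^2) is
# Beta(1/2, (p-2)/2) under the uniform measure on the constrained sphere.
orthosphere_moment_se <- function(u, K) {
  p <- length(u)
  a <- 0.5
  b <- (p - 2) / 2
  v <- a * b / ((a + b)^2 * (a + b + 1))
  (1 - u^2) * sqrt(v / K)
}

# Small fully specified four-group dataset for structural tests.
tiny_dataset <- function(seed = 1L) {
  generate_dataset(synthetic_config(
    n_genes = 60,
    group_sizes = c(tumorA = 6, tumorB = 6, normalA = 8, normalB = 8),
    seed = seed
  ))
}
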