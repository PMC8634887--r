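# shared fixture builders (all data generated in code, fixed seeds)

# one-factor linear panel: Y_p = loading_p * eta + N(0, err_sd_p)
make_factor_panel <- function(n_per_group = 100, loadings = c(1, 1, 1),
                              err_sd = c(0.5, 0.5, 0.5), shift = 0,
                              seed = 1, eta_r = stats::rnorm) {
  stopifnot(length(loadings) == length(err_sd))
  set.seed(seed)
  eta <- c(eta_r(n_per_group), shift + eta_r(n_per_group))
  vals <- vapply(seq_along(loadings), function(p)
    loadings[p] * eta + stats::rnorm(2 * n_per_group, sd = err_sd[p]),
    numeric(2 * n_per_group))
  indicator_panel(vals, rep(c("group1", "group2"), each = n_per_group))
}

# population moments of P standardized one-factor indicators with given
# reliabilities: Sigma[p,q] = sqrt(rel_p * rel_q), diag 1, psi = 1 - rel
factor_moments <- function(rel) {
  S <- sqrt(outer(rel, rel))
  diag(S) <- 1
  list(S = S, psi = 1 - rel)
}

# brute-force probabilistic index: literal double loop over all pairs
pi_bruteforce <- function(x, y) {
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi < yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# brute-force maximal reliability over the nonnegative weight simplex at a
# given grid resolution; returns the best achieved reliability
grid_search_reliability <- function(S, psi, step = 0.01) {
  best <- 0
  g <- seq(0, 1, by = step)
  for (a1 in g) for (a2 in seq(0, 1 - a1, by = step)) {
    a <- c(a1, a2, 1 - a1 - a2)
    tot <- drop(crossprod(a, S %*% a))
    if (tot > 0) best <- max(best, (tot - sum(a^2 * psi)) / tot)
  }
  best
}

# two-group panel whose pooled sample covariance equals S exactly
# (center, whiten by the empirical Cholesky, recolor by chol(S))
exact_cov_panel <- function(S, n_per_group, seed) {
  set.seed(seed)
  P <- ncol(S)
  Z <- matrix(stats::rnorm(2 * n_per_group * P), 2 * n_per_group, P)
  Z <- scale(Z, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z))) %*% chol(S)
  indicator_panel(Z, rep(c("a", "b"), each = n_per_group))
}

# random positive-definite one-factor instance (P = 3) on the standardized
# scale, with reliabilities drawn in [0.15, 0.95]
random_factor_instance <- function(seed) {
  set.seed(seed)
  rel <- stats::runif(3, 0.15, 0.95)
  factor_moments(rel)
}
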