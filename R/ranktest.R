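#' Probabilistic index of two samples
#'
#' Estimates `P(X < Y) + 0.5 P(X = Y)`: the probability that a randomly
#' chosen subject of the first sample scores below a randomly chosen subject
#' of the second, with tied cross-group pairs counted as one half. Computed
#' from pooled mid-ranks in `O((m+n) log(m+n))`, which is exactly the pairwise
#' count `(1/(mn)) sum_ij [I(x_i < y_j) + 0.5 I(x_i = y_j)]`.
#'
#' @param x,y numeric vectors (each nonempty).
#' @return the probabilistic index, a value in \[0, 1\].
#' @examples
#' probabilistic_index(c(1, 3, 5), c(2, 4, 6))  # 6/9
#' @export
probabilistic_index <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    lw_stop("both samples must be nonempty", "lw_empty_group")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))                       # mid-ranks handle ties
  (sum(r[(m + 1L):(m + n)]) - n * (n + 1) / 2) / (m * n)
}

#' Standardized Wilcoxon-Mann-Whitney statistic
#'
#' Returns `u = (pi_hat - 0.5) / sigma0` with the tie-free null standard
#' deviation `sigma0 = sqrt((m + n + 1) / (12 m n))`. With
#' `tie_correction = TRUE`, `sigma0` subtracts the usual tied-group term
#' `sum(t^3 - t) / (12 m n N (N - 1))`.
#'
#' @inheritParams probabilistic_index
#' @param tie_correction use the tie-corrected null variance (default keeps
#'   the tie-free formula).
#' @return list with elements `u`, `sigma0` and `pi_hat`.
#' @export
wmw_statistic <- function(x, y, tie_correction = FALSE) {
  m <- length(x); n <- length(y)
  pi_hat <- probabilistic_index(x, y)
  v <- (m + n + 1) / (12 * m * n)
  if (tie_correction) {
    N <- m + n
    t <- table(c(x, y))
    v <- v - sum(t^3 - t) / (12 * m * n * N * (N - 1))
  }
  sigma0 <- sqrt(v)
  list(u = (pi_hat - 0.5) / sigma0, sigma0 = sigma0, pi_hat = pi_hat)
}

# exact null distribution of u by full enumeration of group assignments;
# returns the vector of u values over all C(m+n, m) assignments
enumerate_wmw <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  sigma0 <- sqrt((m + n + 1) / (12 * m * n))
  combos <- utils::combn(m + n, n)
  u <- (colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2) / (m * n)
  (u - 0.5) / sigma0
}

#' p-value for the Wilcoxon-Mann-Whitney statistic
#'
#' @inheritParams wmw_statistic
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   stated in terms of the probabilistic index `P(X < Y)` against 0.5.
#' @param method `"normal"` (standard normal approximation of `u`, no
#'   continuity correction), `"exact"` (full enumeration of the
#'   `choose(m+n, m)` group assignments; tie-free samples with `m + n <= 12`),
#'   or `"permutation"` (Monte Carlo enumeration with `n_perm` seeded draws;
#'   the observed statistic is included in numerator and denominator). When
#'   `n_perm` is at least the number of distinct assignments the permutation
#'   method enumerates exhaustively and coincides with `"exact"`.
#' @param n_perm number of permutation draws.
#' @param seed integer seed for the permutation draws; the caller's RNG
#'   stream is left untouched.
#' @return the p-value.
#' @export
wmw_pvalue <- function(x, y, alternative = c("two.sided", "less", "greater"),
                       method = c("normal", "exact", "permutation"),
                       n_perm = 10000L, seed = NULL, tie_correction = FALSE) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  st <- wmw_statistic(x, y, tie_correction = tie_correction)
  m <- length(x); n <- length(y)
  tail_prob <- function(u_null, u_obs) {
    eps <- 1e-12
    switch(alternative,
           two.sided = mean(abs(u_null) >= abs(u_obs) - eps),
           greater   = mean(u_null >= u_obs - eps),
           less      = mean(u_null <= u_obs + eps))
  }
  if (method == "normal") {
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(st$u)),
                greater   = stats::pnorm(st$u, lower.tail = FALSE),
                less      = stats::pnorm(st$u))
    return(min(p, 1))
  }
  n_total <- choose(m + n, m)
  if (method == "exact") {
    if (m + n > 12L)
      lw_stop(sprintf("exact enumeration limited to m + n <= 12 (got %d); use method = 'permutation'",
                      m + n), "lw_enumeration_too_large")
    if (anyDuplicated(c(x, y)))
      lw_stop("exact method requires tie-free data", "lw_ties_present")
    return(tail_prob(enumerate_wmw(x, y), st$u))
  }
  # permutation
  if (n_perm >= n_total && m + n <= 12L)
    return(tail_prob(enumerate_wmw(x, y), st$u))
  if (n_perm < 100L)
    warning("fewer than 100 permutations gives a very coarse p-value")
  r <- rank(c(x, y))
  sigma0 <- st$sigma0
  u_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ry <- r[sample.int(m + n, n)]
      ((sum(ry) - n * (n + 1) / 2) / (m * n) - 0.5) / sigma0
    }, numeric(1))
  })
  eps <- 1e-12
  hits <- switch(alternative,
                 two.sided = sum(abs(u_perm) >= abs(st$u) - eps),
                 greater   = sum(u_perm >= st$u - eps),
                 less      = sum(u_perm <= st$u + eps))
  (1 + hits) / (1 + n_perm)
}

#' Rank test for a latent variable measured by multiple indicators
#'
#' End-to-end test of equality of the latent distribution between two groups:
#' aggregates the indicators into a composite (unweighted mean of the
#' pooled-standardized indicators, or the maximally reliable weighted
#' composite built from triad-estimated error variances) and applies the
#' Wilcoxon-Mann-Whitney test to the composite scores. Because the test uses
#' ranks only, it is valid for any strictly monotone indicator-latent
#' relationship and is robust to outliers and skewness; equality of the
#' measurement-error distribution across groups is the key assumption.
#'
#' @param panel an [indicator_panel()].
#' @param strategy `"mean"` (default) or `"max_rel"`; the latter requires at
#'   least 3 indicators for triad estimation.
#' @param alternative see [wmw_pvalue()]; refers to
#'   `P(group 1 < group 2)` vs 0.5, group 1 being the panel's first
#'   (reference) level.
#' @param method inference method; `"auto"` (default) uses the normal
#'   approximation when both groups have at least 20 subjects and a seeded
#'   permutation null (`n_perm` draws) below that.
#' @param n_perm,seed permutation settings, see [wmw_pvalue()].
#' @param tie_correction use tie-corrected null variance for the normal
#'   approximation.
#' @return object of class `latent_wmw`: probabilistic index `pi_hat`
#'   (`P(group1 < group2)` on the composite), standardized statistic `u`,
#'   `sigma0`, `p_value`, the inference `method` used, `alternative`, group
#'   sizes `m`, `n`, the `strategy`, and the fitted `composite`
#'   (a `composite_scores` object).
#' @examples
#' pan <- simulate_panel(wmw_scenario("normal", m = 60, n = 60,
#'                                    hypothesis = "alternative"), seed = 1)
#' latent_wmw_test(pan, strategy = "max_rel")
#' @export
latent_wmw_test <- function(panel,
                            strategy = c("mean", "max_rel", "single"),
                            alternative = c("two.sided", "less", "greater"),
                            method = c("auto", "normal", "exact", "permutation"),
                            n_perm = 10000L, seed = NULL,
                            tie_correction = FALSE) {
  stopifnot(inherits(panel, "indicator_panel"))
  strategy <- match.arg(strategy)
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  P <- ncol(panel$values)
  if (strategy == "single" && P != 1L)
    lw_stop("strategy 'single' requires exactly one indicator",
            "lw_unsupported_design")
  if (strategy == "max_rel" && P < 3L)
    lw_stop("strategy 'max_rel' needs >= 3 indicators for triad estimation; use strategy = 'mean'",
            "lw_unsupported_design")
  comp <- switch(strategy,
                 single = structure(list(values = drop(panel$values[, 1L]),
                                         group = panel$group,
                                         weights = new_composite_weights(1, "single")),
                                    class = "composite_scores"),
                 mean = mean_composite(panel),
                 max_rel = max_reliable_composite(panel,
                                                  estimate_error_variances(panel)))
  g <- split_by_group(panel, comp$values)
  if (method == "auto")
    method <- if (min(panel$m, panel$n) >= 20L) "normal" else "permutation"
  st <- wmw_statistic(g$x, g$y, tie_correction = tie_correction)
  p <- wmw_pvalue(g$x, g$y, alternative = alternative, method = method,
                  n_perm = n_perm, seed = seed,
                  tie_correction = tie_correction)
  structure(list(pi_hat = st$pi_hat, u_statistic = st$u, sigma0 = st$sigma0,
                 p_value = p, method = method, alternative = alternative,
                 m = panel$m, n = panel$n,
                 strategy = if (strategy == "single") "single-indicator" else strategy,
                 groups = levels(panel$group), composite = comp),
            class = "latent_wmw")
}

#' @export
print.latent_wmw <- function(x, digits = 4, ...) {
  cat("Wilcoxon-Mann-Whitney test for a latent variable\n")
  cat(sprintf("  composite: %s;  groups: %s (m = %d) vs %s (n = %d)\n",
              x$strategy, x$groups[1], x$m, x$groups[2], x$n))
  cat(sprintf("  P(%s < %s) = %.*f  (probabilistic index)\n",
              x$groups[1], x$groups[2], digits, x$pi_hat))
  cat(sprintf("  u = %.*f,  p-value = %.*g  (%s, %s)\n",
              digits, x$u_statistic, digits, x$p_value, x$method,
              x$alternative))
  invisible(x)
}
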