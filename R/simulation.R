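#' Welch two-sample t-test with optional permutation inference
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom (via [stats::t.test()]) serves as the parametric competitor of the
#' rank test. For small groups a permutation null of the statistic is
#' available: group labels are reshuffled `n_perm` times (seeded) and the
#' observed statistic is included in numerator and denominator.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation draws.
#' @return two-sided p-value.
#' @export
welch_t_test <- function(x, y, method = c("asymptotic", "permutation"),
                         n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L)
    lw_stop("Welch test needs at least two observations per group",
            "lw_bad_input")
  if (stats::var(c(x, y)) == 0)
    lw_stop("all observations identical; t statistic undefined",
            "lw_degenerate")
  if (method == "asymptotic")
    return(stats::t.test(x, y, var.equal = FALSE)$p.value)
  z <- c(x, y); z2 <- z^2
  N <- m + n
  S <- sum(z); SS <- sum(z2)
  t_from_idx <- function(idx) {
    # idx: m x B matrix of group 1 positions
    s1 <- colSums(matrix(z[idx], nrow = m))
    ss1 <- colSums(matrix(z2[idx], nrow = m))
    mu1 <- s1 / m; mu2 <- (S - s1) / n
    v1 <- (ss1 - m * mu1^2) / (m - 1)
    v2 <- (SS - ss1 - n * mu2^2) / (n - 1)
    (mu1 - mu2) / sqrt(v1 / m + v2 / n)
  }
  t_obs <- t_from_idx(matrix(seq_len(m), ncol = 1L))
  n_total <- choose(N, m)
  if (n_perm >= n_total && N <= 12L) {
    idx <- utils::combn(N, m)
    t_null <- t_from_idx(idx)
    return(mean(abs(t_null) >= abs(t_obs) - 1e-12))
  }
  idx <- with_seed(seed,
                   vapply(seq_len(n_perm), function(b) sample.int(N, m),
                          integer(m)))
  t_null <- t_from_idx(idx)
  (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
}

sim_methods <- c("wmw_max_rel", "wmw_mean", "t_max_rel", "t_mean")

# fast per-replicate analysis used inside the Monte Carlo loop: returns
# two-sided p-values for the requested methods plus a degenerate-triad flag
analyse_replicate <- function(panel, methods, t_method, n_perm, seed) {
  z <- scale(panel$values)          # pooled standardization
  g1 <- panel$group == levels(panel$group)[1]
  p_out <- stats::setNames(rep(NA_real_, length(methods)), methods)
  failed <- FALSE
  need_maxrel <- any(c("wmw_max_rel", "t_max_rel") %in% methods)
  comp <- list(mean = rowMeans(z))
  if (need_maxrel) {
    w <- tryCatch({
      S <- stats::cov(panel$values)
      ev <- pmax(triad_error_variances(S), 0)
      psi <- ev / diag(S)
      Sz <- stats::cov(z)
      L <- chol(Sz)
      M <- Sz - diag(psi, ncol(z))
      B <- backsolve(L, t(backsolve(L, t(M), transpose = TRUE)),
                     transpose = TRUE)
      a <- backsolve(L, eigen((B + t(B)) / 2, symmetric = TRUE)$vectors[, 1L])
      normalize_weights(a)
    }, error = function(e) NULL)
    if (is.null(w)) {               # degenerate triad: fall back to the mean
      failed <- TRUE
      w <- rep(1 / sqrt(ncol(z)), ncol(z))
    }
    comp$max_rel <- drop(z %*% w)
  }
  for (meth in methods) {
    v <- if (grepl("max_rel", meth)) comp$max_rel else comp$mean
    x <- v[g1]; y <- v[!g1]
    p_out[meth] <-
      if (startsWith(meth, "wmw_")) {
        u <- wmw_statistic(x, y)$u
        2 * stats::pnorm(-abs(u))
      } else {
        welch_t_test(x, y, method = t_method, n_perm = n_perm, seed = seed)
      }
  }
  list(p = p_out, failed = failed)
}

#' Monte Carlo rejection rates for one scenario
#'
#' Replicates the scenario `n_reps` times and records, for each analysis
#' method, the fraction of replicates whose two-sided p-value falls below
#' the scenario's `alpha`. The four methods are the rank test on the
#' maximally reliable composite (`wmw_max_rel`), the rank test on the
#' unweighted mean composite (`wmw_mean`), and the Welch t-test on the same
#' two composites (`t_max_rel`, `t_mean`). Rank-test inference uses the
#' normal approximation (the generated data are continuous, so ties have
#' probability zero); the t-tests use a seeded permutation null (`n_perm`
#' draws) when either group has fewer than 20 subjects and the asymptotic
#' Welch-Satterthwaite reference otherwise. Replicates whose triad
#' estimation degenerates fall back to equal weights and are counted in
#' `failures`, keeping the rejection-rate denominator at `n_reps`.
#'
#' @param scenario a [wmw_scenario()].
#' @param methods subset of `c("wmw_max_rel", "wmw_mean", "t_max_rel",
#'   "t_mean")`.
#' @param n_reps number of Monte Carlo replicates (>= 1).
#' @param seed base seed; per-replicate seeds are derived from it, so any
#'   subset of replicates is independently reproducible.
#' @param n_perm permutations for the small-sample t-test null.
#' @return object of class `scenario_result`: list with the `scenario`,
#'   per-method `rejection_rate` and binomial `mc_se`, `n_reps`, `seed` and
#'   `failures`.
#' @export
run_scenario <- function(scenario, methods = sim_methods, n_reps = 1000L,
                         seed = 1L, n_perm = 1000L) {
  stopifnot(inherits(scenario, "wmw_scenario"))
  if (n_reps < 1L) lw_stop("n_reps must be at least 1", "lw_bad_input")
  methods <- match.arg(methods, sim_methods, several.ok = TRUE)
  cal <- scenario_calibration(scenario)
  t_method <- if (min(scenario$m, scenario$n) < 20L) "permutation"
              else "asymptotic"
  rej <- matrix(0, nrow = n_reps, ncol = length(methods),
                dimnames = list(NULL, methods))
  failures <- 0L
  for (i in seq_len(n_reps)) {
    rs <- derive_seed(seed, i)
    panel <- simulate_panel(scenario, seed = rs, calibration = cal)
    res <- analyse_replicate(panel, methods, t_method, n_perm,
                             seed = derive_seed(rs, 1L))
    rej[i, ] <- res$p < scenario$alpha
    failures <- failures + res$failed
  }
  if (failures == n_reps)
    lw_stop("triad estimation degenerated in every replicate", "lw_degenerate")
  rate <- colMeans(rej)
  structure(list(scenario = scenario,
                 rejection_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / n_reps),
                 n_reps = as.integer(n_reps), seed = seed,
                 failures = failures),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  tab <- data.frame(rejection_rate = x$rejection_rate, mc_se = x$mc_se)
  print(round(tab, 4))
  cat(sprintf("  %d replicates, seed %d, %d degenerate-triad fallback(s)\n",
              x$n_reps, x$seed, x$failures))
  invisible(x)
}

#' Run a grid of scenarios
#'
#' Applies [run_scenario()] to every scenario in a list, giving each an
#' independent seed substream, and stacks the results into a long-format
#' table (one row per scenario x method).
#'
#' @param scenarios list of [wmw_scenario()] objects (e.g. from
#'   [scenario_grid()]).
#' @param methods,n_reps,n_perm see [run_scenario()].
#' @param seed base seed.
#' @param out optional path; when given the table is also written as TSV
#'   (`.tsv`) or JSON (`.json`) via [write_result()].
#' @return data.frame with the scenario descriptors, `method`,
#'   `rejection_rate`, `mc_se`, `n_reps`, `failures` and the scenario seed.
#' @export
run_grid <- function(scenarios, methods = sim_methods, n_reps = 1000L,
                     seed = 1L, n_perm = 1000L, out = NULL) {
  if (length(scenarios) == 0L)
    lw_stop("scenario list is empty", "lw_bad_input")
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    res <- run_scenario(sc, methods = methods, n_reps = n_reps,
                        seed = derive_seed(seed, 100003L * i),
                        n_perm = n_perm)
    data.frame(latent_dist = sc$latent_dist, linearity = sc$linearity,
               reliability = sc$reliability, m = sc$m, n = sc$n,
               setting = sc$setting, hypothesis = sc$hypothesis,
               delta = sc$delta, method = names(res$rejection_rate),
               rejection_rate = unname(res$rejection_rate),
               mc_se = unname(res$mc_se), n_reps = res$n_reps,
               failures = res$failures, seed = res$seed,
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) write_result(tab, out)
  tab
}
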