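#' Standardize indicators on pooled moments
#'
#' Centers and scales every indicator by its pooled (both groups combined)
#' mean and standard deviation. Both aggregation strategies operate on this
#' shared standardized scale so that a single linear combination — hence a
#' measurement-invariant composite — is applied to the two groups.
#'
#' @param panel an [indicator_panel()].
#' @return an [indicator_panel()] whose columns have pooled mean 0 and pooled
#'   variance 1.
#' @export
standardize <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  sds <- apply(panel$values, 2L, stats::sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    bad <- panel$indicator_names[sds <= 0 | !is.finite(sds)][1]
    lw_stop(sprintf("indicator '%s' is constant; cannot standardize", bad),
            "lw_constant_indicator")
  }
  out <- panel
  out$values <- scale(panel$values, center = TRUE, scale = sds)
  attr(out$values, "scaled:center") <- NULL
  attr(out$values, "scaled:scale") <- NULL
  out
}

# unit Euclidean norm, oriented so the average loading (or, if zero, the
# first nonzero loading) is positive
normalize_weights <- function(a) {
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) lw_stop("weights must not all be zero", "lw_degenerate_weights")
  a <- a / nrm
  s <- mean(a)
  if (s == 0) s <- a[which(a != 0)[1]]
  if (s < 0) a <- -a
  a
}

new_composite_weights <- function(weights, strategy, est_reliability = NA_real_) {
  structure(list(weights = normalize_weights(weights), strategy = strategy,
                 est_reliability = est_reliability,
                 normalization = "unit-norm, positive mean loading"),
            class = "composite_weights")
}

#' Unweighted-mean composite of standardized indicators
#'
#' The simplest aggregation: `Y_agg = (1/P) sum_p Z_p`, with `Z_p` the
#' pooled-standardized indicators. Treats all indicators as equally reliable.
#'
#' @param panel an [indicator_panel()].
#' @param estimates optional [estimate_error_variances()] result, used only to
#'   fill in the composite's estimated reliability.
#' @return an object of class `composite_scores`: list with per-subject
#'   `values`, the panel `group` factor, and the `composite_weights` used.
#' @export
mean_composite <- function(panel, estimates = NULL) {
  std <- standardize(panel)
  P <- ncol(std$values)
  w <- new_composite_weights(rep(1, P), "mean")
  if (!is.null(estimates))
    w$est_reliability <- composite_reliability(
      rep(1 / P, P),
      stats::cov(std$values),
      std_error_variances(estimates))
  structure(list(values = rowMeans(std$values), group = panel$group,
                 weights = w),
            class = "composite_scores")
}

# error variances re-expressed on the pooled-standardized scale
std_error_variances <- function(estimates) {
  estimates$error_variance / diag(estimates$pooled_cov)
}

#' Reliability of a weighted composite
#'
#' For weights `a`, indicator covariance `Sigma` and mutually uncorrelated
#' measurement errors with variances `psi_p`, the composite
#' `sum_p a_p Y_p` has reliability
#' `(a' Sigma a - sum_p a_p^2 psi_p) / (a' Sigma a)`, clipped to \[0, 1\].
#' Invariant to rescaling of `a`.
#'
#' @param weights numeric weight vector.
#' @param pooled_cov covariance matrix of the indicators the weights apply to.
#' @param error_variance per-indicator error variances on the same scale.
#' @return reliability in \[0, 1\].
#' @export
composite_reliability <- function(weights, pooled_cov, error_variance) {
  a <- as.numeric(weights)
  total <- drop(crossprod(a, as.matrix(pooled_cov) %*% a))
  if (!is.finite(total) || total <= 0)
    lw_stop("weights give a composite with nonpositive variance",
            "lw_degenerate_weights")
  min(max((total - sum(a^2 * error_variance)) / total, 0), 1)
}

#' Maximally reliable composite
#'
#' Chooses weights for the pooled-standardized indicators that maximize the
#' estimated composite reliability, so that less reliable indicators are
#' down-weighted. With `Sigma` the pooled covariance of the standardized
#' indicators and `Psi` the diagonal matrix of standardized error variances,
#' maximizing reliability is the generalized eigenproblem
#' `(Sigma - Psi) a = lambda Sigma a`; the leading eigenvector is the closed-
#' form optimum (solved through a Cholesky factor of `Sigma`, so the result is
#' deterministic). By construction the achieved reliability is at least the
#' best single indicator's.
#'
#' @param panel an [indicator_panel()] with at least two indicators.
#' @param estimates a `measurement_estimates` object for the same panel,
#'   typically from [estimate_error_variances()].
#' @return a `composite_scores` object (see [mean_composite()]) whose
#'   `weights` carry strategy `"max_rel"` and the achieved estimated
#'   reliability.
#' @export
max_reliable_composite <- function(panel, estimates) {
  stopifnot(inherits(panel, "indicator_panel"),
            inherits(estimates, "measurement_estimates"))
  P <- ncol(panel$values)
  if (P < 2L)
    lw_stop("a weighted composite needs at least 2 indicators",
            "lw_unsupported_design")
  std <- standardize(panel)
  Sz <- stats::cov(std$values)
  psi <- std_error_variances(estimates)
  L <- tryCatch(chol(Sz), error = function(e)
    lw_stop("pooled covariance of the standardized indicators is singular (collinear indicators)",
            "lw_collinear_indicators"))
  # whiten: B = L^-T (Sz - Psi) L^-1 is symmetric; leading eigvec maps back
  M <- Sz - diag(psi, P)
  B <- backsolve(L, t(backsolve(L, t(M), transpose = TRUE)), transpose = TRUE)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  a <- backsolve(L, eig$vectors[, 1L])
  w <- new_composite_weights(a, "max_rel")
  w$est_reliability <- composite_reliability(w$weights, Sz, psi)
  structure(list(values = drop(std$values %*% w$weights), group = panel$group,
                 weights = w),
            class = "composite_scores")
}

#' @export
print.composite_scores <- function(x, ...) {
  cat(sprintf("Composite scores (%s strategy) for %d subjects\n",
              x$weights$strategy, length(x$values)))
  cat("  weights:",
      paste(sprintf("%.4f", x$weights$weights), collapse = ", "), "\n")
  if (!is.na(x$weights$est_reliability))
    cat(sprintf("  estimated reliability: %.4f\n", x$weights$est_reliability))
  invisible(x)
}
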