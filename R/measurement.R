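#' Triad estimates of measurement-error variances
#'
#' Under a single-factor measurement model with linear loadings,
#' `Y1 = h(eta) + e1`, `Y2 = a2 + b2 h(eta) + e2`, `Y3 = a3 + b3 h(eta) + e3`
#' and mutually uncorrelated errors, the error variance of an indicator is
#' identified from the covariances of any triad containing it:
#' `var(e1) = var(Y1) - cov(Y1, Y2) cov(Y1, Y3) / cov(Y2, Y3)`.
#' This function applies the formula to every indicator, rotating the triad
#' indices; with more than three indicators the estimate for indicator `p` is
#' averaged over all triads containing `p`.
#'
#' Moments are pooled over both groups (unbiased `n - 1` denominator): the
#' composite that consumes these estimates must be a single linear combination
#' shared by the two groups, so its reliability is a property of the pooled
#' sample.
#'
#' @param panel an [indicator_panel()] with at least three indicators.
#' @param tol relative tolerance below which a pairwise covariance is treated
#'   as zero and the triad declared degenerate; the default
#'   `1e-8 * sd_p * sd_q` guards against division by a vanishing covariance.
#'
#' @return An object of class `measurement_estimates`: list with
#'   `pooled_cov` (P x P), `error_variance` (length P, clipped at 0),
#'   `reliability` (length P, clipped to \[0, 1\]), and `truncation_flags`
#'   marking indicators whose estimate was clipped.
#' @seealso [estimate_reliability()], [max_reliable_composite()]
#' @export
estimate_error_variances <- function(panel, tol = 1e-8) {
  stopifnot(inherits(panel, "indicator_panel"))
  P <- ncol(panel$values)
  if (P < 3L)
    lw_stop(paste0("triad estimation needs at least 3 indicators (got ", P,
                   "); error variances are not identifiable from fewer"),
            "lw_unsupported_design")
  S <- stats::cov(panel$values)
  ev <- triad_error_variances(S, tol = tol)
  clipped_var <- ev < 0
  ev[clipped_var] <- 0
  rel <- (diag(S) - ev) / diag(S)
  clipped_rel <- rel < 0 | rel > 1
  rel <- pmin(pmax(rel, 0), 1)
  structure(list(pooled_cov = S,
                 error_variance = stats::setNames(ev, panel$indicator_names),
                 reliability = stats::setNames(rel, panel$indicator_names),
                 truncation_flags = stats::setNames(clipped_var | clipped_rel,
                                                    panel$indicator_names)),
            class = "measurement_estimates")
}

#' Triad error-variance formula applied to a covariance matrix
#'
#' Workhorse behind [estimate_error_variances()], exposed for direct use on
#' population or sample covariance matrices. Estimates may be negative in
#' finite samples; no clipping is applied here.
#'
#' @param S symmetric covariance matrix of at least three indicators.
#' @param tol relative zero-covariance tolerance (see
#'   [estimate_error_variances()]).
#' @return numeric vector of error-variance estimates, one per indicator.
#' @export
triad_error_variances <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  P <- ncol(S)
  if (P < 3L)
    lw_stop("triad formula needs at least 3 indicators",
            "lw_unsupported_design")
  sds <- sqrt(diag(S))
  check_pair <- function(i, j) {
    if (abs(S[i, j]) <= tol * sds[i] * sds[j])
      lw_stop(sprintf(
        "covariance between indicators %d and %d is numerically zero; triad estimate undefined",
        i, j), "lw_degenerate_covariance")
  }
  ev <- numeric(P)
  for (p in seq_len(P)) {
    others <- setdiff(seq_len(P), p)
    pairs <- utils::combn(others, 2L)
    est <- apply(pairs, 2L, function(qr) {
      q <- qr[1]; r <- qr[2]
      check_pair(p, q); check_pair(p, r); check_pair(q, r)
      S[p, p] - S[p, q] * S[p, r] / S[q, r]
    })
    ev[p] <- mean(est)
  }
  ev
}

#' Reliability of an indicator
#'
#' The proportion of an indicator's variance not attributable to measurement
#' error, `(var(Y) - var(e)) / var(Y)`, clipped to \[0, 1\].
#'
#' @param var_y total variance of the indicator (> 0).
#' @param var_eps nonnegative measurement-error variance.
#' @return reliability in \[0, 1\]; attribute `"truncated"` is `TRUE` when the
#'   raw ratio fell outside the unit interval.
#' @examples
#' estimate_reliability(1.25, 0.25)  # 0.8
#' @export
estimate_reliability <- function(var_y, var_eps) {
  if (!is.finite(var_y) || var_y <= 0)
    lw_stop("indicator variance must be positive", "lw_invalid_variance")
  if (var_eps < 0)
    lw_stop("error variance must be nonnegative", "lw_invalid_variance")
  raw <- (var_y - var_eps) / var_y
  out <- min(max(raw, 0), 1)
  attr(out, "truncated") <- raw < 0 || raw > 1
  out
}

#' @export
print.measurement_estimates <- function(x, ...) {
  cat("Triad measurement estimates (pooled over groups)\n")
  print(data.frame(error_variance = x$error_variance,
                   reliability = x$reliability,
                   truncated = x$truncation_flags))
  invisible(x)
}
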