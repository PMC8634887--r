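#' Sample size for the rank test at a design probabilistic index
#'
#' Noether-type approximation for the total sample size `N = m + n` needed to
#' detect a probabilistic index `delta` with the Wilcoxon-Mann-Whitney test:
#' `N = (z_alpha + z_beta)^2 / (12 c (1 - c) (delta - 1/2)^2)`, rounded up.
#' `c = m / (m + n)` is the allocation fraction in group 1. The formula is
#' stated for a one-sided test; the two-sided variant replaces `alpha` by
#' `alpha / 2`.
#'
#' @param alpha significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param c allocation fraction `m / (m + n)` in (0, 1); 0.5 means balanced.
#' @param delta design probabilistic index in (0, 1), different from 0.5.
#' @param sidedness `"one"` (default, as the formula is usually quoted) or
#'   `"two"`.
#' @return integer total sample size `N` (ceiling), with attribute `"split"`
#'   giving `m = round(c N)` and `n = N - m`.
#' @examples
#' required_sample_size(0.05, 0.80, 0.5, 0.65)  # 92
#' @export
required_sample_size <- function(alpha = 0.05, power = 0.80, c = 0.5,
                                 delta, sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, c > 0, c < 1,
            delta > 0, delta < 1)
  if (delta == 0.5)
    lw_stop("delta = 0.5 is the null value; the required sample size is undefined",
            "lw_undefined_design")
  a <- if (sidedness == "one") alpha else alpha / 2
  z_a <- stats::qnorm(1 - a)
  z_b <- stats::qnorm(power)
  N <- ceiling((z_a + z_b)^2 / (12 * c * (1 - c) * (delta - 0.5)^2))
  m <- round(c * N)
  structure(as.integer(N), split = c(m = as.integer(m),
                                     n = as.integer(N - m)))
}

#' Expected power of the rank test at a given total sample size
#'
#' Inverts the sample-size approximation:
#' `1 - beta = Phi( sqrt(N 12 c (1 - c) (delta - 1/2)^2) - z_alpha )`.
#'
#' @param N total sample size (>= 2).
#' @param c allocation fraction in (0, 1).
#' @param delta design probabilistic index in (0, 1).
#' @param alpha significance level.
#' @param sidedness `"one"` or `"two"` (uses `alpha / 2`).
#' @return expected power in (0, 1).
#' @examples
#' expected_power(92, 0.5, 0.65, 0.05)  # about 0.801
#' @export
expected_power <- function(N, c = 0.5, delta, alpha = 0.05,
                           sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  stopifnot(N >= 2, c > 0, c < 1, delta > 0, delta < 1, alpha > 0, alpha < 1)
  a <- if (sidedness == "one") alpha else alpha / 2
  stats::pnorm(sqrt(N * 12 * c * (1 - c) * (delta - 0.5)^2) -
                 stats::qnorm(1 - a))
}

#' Convert between a standardized mean difference and the probabilistic index
#'
#' Under a normal location shift of size `d` standard deviations, the
#' probabilistic index is `pi = Phi(d / sqrt(2))`; a standardized effect of
#' 0.55 (a medium effect) corresponds to an index of about 65%. The inverse
#' is `d = sqrt(2) * qnorm(pi)`.
#'
#' @param d standardized mean difference (Cohen's d).
#' @return `pi_from_standardized_diff`: probabilistic index in (0, 1).
#' @examples
#' pi_from_standardized_diff(0.55)  # 0.6513
#' @export
pi_from_standardized_diff <- function(d) {
  stopifnot(is.finite(d))
  stats::pnorm(d / sqrt(2))
}

#' @rdname pi_from_standardized_diff
#' @param pi probabilistic index in (0, 1).
#' @return `standardized_diff_from_pi`: the standardized difference.
#' @export
standardized_diff_from_pi <- function(pi) {
  stopifnot(pi > 0, pi < 1)
  sqrt(2) * stats::qnorm(pi)
}
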