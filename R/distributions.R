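# Latent-variable distribution menu used by the simulation engine.
# All four are centered at zero and leptokurtic to skew-symmetric degrees
# that occur in questionnaire data: N(0,1); Student t with 5 df
# (variance 5/3); Laplace(0, 1.25) (variance 2 * 1.25^2 = 3.125); and the
# standard exponential shifted to mean zero (variance 1, skewness 2).

rlaplace <- function(n, location = 0, scale = 1) {
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log1p(-2 * abs(u))
}

dlaplace <- function(x, location = 0, scale = 1)
  exp(-abs(x - location) / scale) / (2 * scale)

plaplace <- function(q, location = 0, scale = 1) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

qlaplace <- function(p, location = 0, scale = 1) {
  location - scale * sign(p - 0.5) * log1p(-2 * abs(p - 0.5))
}

#' Latent distribution menu
#'
#' Returns the sampling, density and distribution functions plus the exact
#' variance and support of one of the four latent-variable laws used by the
#' simulation engine: `"normal"` (N(0,1)), `"t5"` (Student t, 5 df),
#' `"laplace"` (Laplace with scale 1.25), `"exponential"` (standard
#' exponential shifted to mean zero).
#'
#' @param name distribution name.
#' @return list with functions `r`, `d`, `p`, `q`, numeric `var`, and
#'   `support` (length-2 interval).
#' @export
latent_distribution <- function(name = c("normal", "t5", "laplace",
                                         "exponential")) {
  name <- match.arg(name)
  switch(name,
    normal = list(r = stats::rnorm, d = stats::dnorm, p = stats::pnorm,
                  q = stats::qnorm, var = 1, support = c(-Inf, Inf)),
    t5 = list(r = function(n) stats::rt(n, df = 5),
              d = function(x) stats::dt(x, df = 5),
              p = function(q) stats::pt(q, df = 5),
              q = function(p) stats::qt(p, df = 5),
              var = 5 / 3, support = c(-Inf, Inf)),
    laplace = list(r = function(n) rlaplace(n, 0, 1.25),
                   d = function(x) dlaplace(x, 0, 1.25),
                   p = function(q) plaplace(q, 0, 1.25),
                   q = function(p) qlaplace(p, 0, 1.25),
                   var = 2 * 1.25^2, support = c(-Inf, Inf)),
    exponential = list(r = function(n) stats::rexp(n) - 1,
                       d = function(x) stats::dexp(x + 1),
                       p = function(q) stats::pexp(q + 1),
                       q = function(p) stats::qexp(p) - 1,
                       var = 1, support = c(-1, Inf)))
}

#' Monotone measurement functions
#'
#' Applies the indicator-latent link `h` used by the data-generating process:
#' either the identity, or the strictly increasing sigmoid
#' `h(v) = qnorm(pt(v, df))` (probit of a t CDF, df 1 or 3), which bends a
#' linear relation into the curvilinear, floor/ceiling-like trends seen in
#' questionnaire scores.
#'
#' @param values numeric vector.
#' @param spec a list `list(type = "identity")` or
#'   `list(type = "t_cdf_probit", df = 1)` (df 1 or 3).
#' @return transformed values, same length.
#' @export
transform_h <- function(values, spec = list(type = "identity")) {
  type <- spec$type %||% "identity"
  switch(type,
         identity = values,
         t_cdf_probit = {
           df <- spec$df
           if (!df %in% c(1, 3))
             lw_stop("t_cdf_probit supports df = 1 or 3", "lw_bad_input")
           stats::qnorm(stats::pt(values, df = df))
         },
         lw_stop(sprintf("unknown transform '%s'", type), "lw_bad_input"))
}
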