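# Deterministic calibrations for the simulation engine: the latent group
# shift implied by a target probabilistic index, and the measurement-error
# standard deviation implied by a target reliability.

# memo cache for quadrature/root-finding results (seed-free, so safe)
.calib_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  val <- force(expr)
  assign(key, val, envir = .calib_cache)
  val
}

#' Latent shift matching a target probabilistic index
#'
#' Solves `P(zeta < beta + zeta*) = delta` for the location shift `beta`,
#' where `zeta` and `zeta*` are i.i.d. from the chosen latent distribution.
#' The left side is the convolution integral
#' `integral F(beta + z) f(z) dz`, evaluated by adaptive quadrature and
#' inverted by deterministic root bracketing (tolerance 1e-6 on the index).
#' For the normal the closed form is `beta = sqrt(2) qnorm(delta)`.
#'
#' @param dist latent distribution name, see [latent_distribution()].
#' @param delta target probabilistic index in (0, 1).
#' @return the shift `beta` (0 when `delta = 0.5`).
#' @examples
#' calibrate_shift("normal", 0.65)       # sqrt(2) * qnorm(0.65)
#' calibrate_shift("exponential", 0.65)  # -log(0.7): Exp differences are Laplace
#' @export
calibrate_shift <- function(dist, delta) {
  stopifnot(delta > 0, delta < 1)
  if (delta == 0.5) return(0)
  if (dist == "normal") return(sqrt(2) * stats::qnorm(delta))
  memo(sprintf("shift|%s|%.10f", dist, delta), {
    d <- latent_distribution(dist)
    index_at <- function(b)
      stats::integrate(function(z) d$p(b + z) * d$d(z),
                       d$support[1], d$support[2],
                       rel.tol = 1e-10, abs.tol = 1e-12)$value
    width <- 20 * sqrt(d$var)
    root <- tryCatch(
      stats::uniroot(function(b) index_at(b) - delta, c(-width, width),
                     tol = 1e-10),
      error = function(e)
        lw_stop(sprintf("shift calibration failed for %s at delta = %g: %s",
                        dist, delta, conditionMessage(e)), "lw_calibration"))
    if (abs(index_at(root$root) - delta) > 1e-6)
      lw_stop("shift calibration did not reach the 1e-6 tolerance",
              "lw_calibration")
    root$root
  })
}

# variance of h(shift + zeta) under the latent distribution; closed form for
# the identity (shift-invariant), adaptive quadrature otherwise
signal_variance <- function(dist, h_spec = list(type = "identity"),
                            shift = 0) {
  if ((h_spec$type %||% "identity") == "identity")
    return(latent_distribution(dist)$var)
  memo(sprintf("sigvar|%s|%s|%s|%.10f", dist, h_spec$type, h_spec$df, shift), {
    d <- latent_distribution(dist)
    mom <- function(k)
      stats::integrate(function(z) transform_h(shift + z, h_spec)^k * d$d(z),
                       d$support[1], d$support[2],
                       rel.tol = 1e-9, abs.tol = 1e-12)$value
    mom(2) - mom(1)^2
  })
}

#' Error standard deviation matching a target reliability
#'
#' Given the latent distribution, the measurement function `h` and a target
#' reliability, returns the error standard deviation
#' `sd = sqrt(var(h(eta)) * (1 - rel) / rel)` that makes the indicator
#' `Y = h(eta) + e` attain that reliability. `var(h(eta))` is exact for the
#' identity link and computed by deterministic quadrature otherwise.
#'
#' @inheritParams calibrate_shift
#' @param h_spec measurement-function spec, see [transform_h()].
#' @param reliability target reliability in (0, 1].
#' @param shift location shift of the latent variable (used when the group
#'   whose reliability is being calibrated has a shifted latent mean and `h`
#'   is nonlinear).
#' @return the error standard deviation (0 when `reliability = 1`).
#' @examples
#' calibrate_error_sd("normal", reliability = 0.8)  # 0.5
#' @export
calibrate_error_sd <- function(dist, h_spec = list(type = "identity"),
                               reliability, shift = 0) {
  if (!is.finite(reliability) || reliability <= 0 || reliability > 1)
    lw_stop("reliability must lie in (0, 1]", "lw_bad_input")
  if (reliability == 1) return(0)
  sqrt(signal_variance(dist, h_spec, shift) *
         (1 - reliability) / reliability)
}
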