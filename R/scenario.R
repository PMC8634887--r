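#' Define one simulation scenario
#'
#' A scenario is one cell of the Monte Carlo grid: a latent distribution, a
#' linear or nonlinear measurement function, an indicator reliability, equal
#' group sizes, a measurement-error setting, and a hypothesis. Three
#' indicators measure one latent factor. The error settings are:
#'
#' * setting 1 — correctly specified: identical normal error laws in both
#'   groups;
#' * setting 2 — the group 2 error variances are inflated so every
#'   indicator's reliability in group 2 is 5 percentage points below
#'   group 1's;
#' * setting 3 — equal error variances, but group 2 errors are Laplace while
#'   group 1 errors are normal;
#' * setting 4 — correctly specified, but the third indicator's reliability
#'   is only 0.20 in both groups.
#'
#' Under the alternative hypothesis the group 2 latent mean is shifted so the
#' latent probabilistic index `P(eta < eta*)` equals `delta` (default 0.65, a
#' medium effect); under the null the groups share one distribution.
#'
#' @param latent_dist `"normal"`, `"t5"`, `"laplace"` or `"exponential"`.
#' @param linearity `"linear"` (all three indicators linear) or `"nonlinear"`
#'   (indicator 1 linear, indicators 2 and 3 probit-of-t with df 1 and 3).
#' @param reliability target indicator reliability, 0.80 or 0.60 by
#'   convention (any value in (0, 1] is accepted).
#' @param m,n group sizes (the study grid uses m = n in 15, 50, 100).
#' @param setting error setting 1-4.
#' @param hypothesis `"null"` or `"alternative"`.
#' @param delta probabilistic index under the alternative.
#' @param alpha nominal test level carried along for power summaries.
#' @return object of class `wmw_scenario` (a validated list).
#' @export
wmw_scenario <- function(latent_dist = c("normal", "t5", "laplace",
                                         "exponential"),
                         linearity = c("linear", "nonlinear"),
                         reliability = 0.80, m = 50, n = m, setting = 1,
                         hypothesis = c("null", "alternative"),
                         delta = 0.65, alpha = 0.05) {
  latent_dist <- match.arg(latent_dist)
  linearity <- match.arg(linearity)
  hypothesis <- match.arg(hypothesis)
  stopifnot(reliability > 0, reliability <= 1, m >= 2, n >= 2,
            setting %in% 1:4, delta > 0, delta < 1,
            alpha > 0, alpha < 1)
  if (setting == 2 && reliability <= 0.05)
    lw_stop("setting 2 needs reliability > 0.05", "lw_bad_input")
  structure(list(latent_dist = latent_dist, linearity = linearity,
                 reliability = reliability, m = as.integer(m),
                 n = as.integer(n), setting = as.integer(setting),
                 hypothesis = hypothesis,
                 delta = if (hypothesis == "null") 0.5 else delta,
                 alpha = alpha, n_indicators = 3L),
            class = "wmw_scenario")
}

#' @export
print.wmw_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: %s latent, %s h, reliability %.2f, m = %d, n = %d, setting %d, %s (delta = %.2f)\n",
    x$latent_dist, x$linearity, x$reliability, x$m, x$n, x$setting,
    x$hypothesis, x$delta))
  invisible(x)
}

scenario_key <- function(sc)
  with(sc, sprintf("%s|%s|%.3f|%d|%d|%d|%s", latent_dist, linearity,
                   reliability, m, n, setting, hypothesis))

# per-indicator measurement-function specs for a scenario
scenario_h_specs <- function(sc) {
  if (sc$linearity == "linear")
    rep(list(list(type = "identity")), 3L)
  else
    list(list(type = "identity"),
         list(type = "t_cdf_probit", df = 1),
         list(type = "t_cdf_probit", df = 3))
}

#' Deterministic calibration of a scenario
#'
#' Computes, once per scenario, everything the data generator needs: the
#' latent shift `beta_star` matching the scenario's probabilistic index, the
#' per-indicator target reliabilities (setting 4 lowers indicator 3 to 0.20),
#' and the per-group, per-indicator error standard deviations. Reliabilities
#' are defined against the variance of the signal `h_p(eta)` actually
#' entering each indicator, so nonlinear scenarios hit their targets exactly.
#' Setting 2 solves for the group 2 error sd that puts each group 2
#' reliability 5 percentage points below group 1's (using the shifted latent
#' distribution's signal variance); setting 3 keeps the group 1 variances but
#' marks the group 2 error law as Laplace.
#'
#' @param scenario a [wmw_scenario()].
#' @return list with `beta_star`, `h_specs`, `rel` (length 3), `sd1`, `sd2`
#'   (length-3 error sds per group) and `err2_dist` (`"normal"` or
#'   `"laplace"`).
#' @export
scenario_calibration <- function(scenario) {
  stopifnot(inherits(scenario, "wmw_scenario"))
  memo(paste0("scen|", scenario_key(scenario)), {
    sc <- scenario
    h_specs <- scenario_h_specs(sc)
    rel <- rep(sc$reliability, 3L)
    if (sc$setting == 4L) rel[3L] <- 0.20
    beta_star <- calibrate_shift(sc$latent_dist, sc$delta)
    sd1 <- vapply(1:3, function(p)
      calibrate_error_sd(sc$latent_dist, h_specs[[p]], rel[p], shift = 0),
      numeric(1))
    sd2 <- sd1
    err2_dist <- "normal"
    if (sc$setting == 2L) {
      rel2 <- pmax(rel - 0.05, 1e-3)
      sd2 <- vapply(1:3, function(p)
        calibrate_error_sd(sc$latent_dist, h_specs[[p]], rel2[p],
                           shift = beta_star), numeric(1))
    } else if (sc$setting == 3L) {
      err2_dist <- "laplace"
    }
    list(beta_star = beta_star, h_specs = h_specs, rel = rel,
         sd1 = sd1, sd2 = sd2, err2_dist = err2_dist)
  })
}

#' Simulate an indicator panel from a scenario
#'
#' Draws one dataset from the scenario's data-generating process: latent
#' values `eta = zeta` (group 1) and `eta* = beta* + zeta*` (group 2) with
#' `zeta, zeta*` i.i.d. from the latent distribution, and indicators
#' `Y_p = h_p(eta) + e_p` with independent errors at the calibrated standard
#' deviations (normal errors everywhere except group 2 of setting 3, whose
#' errors are Laplace with matched variance). Fully reproducible given the
#' seed; the caller's RNG stream is untouched.
#'
#' @param scenario a [wmw_scenario()].
#' @param seed integer seed.
#' @param calibration optional precomputed [scenario_calibration()] (saves
#'   recomputation inside replication loops).
#' @return an [indicator_panel()] with group labels `"group1"`, `"group2"`.
#' @export
simulate_panel <- function(scenario, seed = NULL, calibration = NULL) {
  stopifnot(inherits(scenario, "wmw_scenario"))
  cal <- calibration %||% scenario_calibration(scenario)
  d <- latent_distribution(scenario$latent_dist)
  m <- scenario$m; n <- scenario$n
  with_seed(seed, {
    eta1 <- d$r(m)
    eta2 <- cal$beta_star + d$r(n)
    draw_err <- function(k, sd, law) {
      if (sd == 0) return(numeric(k))
      if (law == "normal") stats::rnorm(k, sd = sd)
      else rlaplace(k, scale = sd / sqrt(2))   # Laplace variance 2 b^2
    }
    vals <- vapply(1:3, function(p) {
      c(transform_h(eta1, cal$h_specs[[p]]) +
          draw_err(m, cal$sd1[p], "normal"),
        transform_h(eta2, cal$h_specs[[p]]) +
          draw_err(n, cal$sd2[p], cal$err2_dist))
    }, numeric(m + n))
    colnames(vals) <- paste0("ind", 1:3)
    indicator_panel(vals, rep(c("group1", "group2"), c(m, n)))
  })
}

#' Build the full simulation grid
#'
#' Expands the study grid — 4 latent distributions x 2 measurement-function
#' shapes x 2 reliabilities x 3 group sizes, each crossed with error settings
#' 1-4 — into a list of [wmw_scenario()] objects.
#'
#' @param latent_dist,linearity,reliability,group_size,setting vectors of
#'   levels to cross (defaults give the 192-cell grid).
#' @param hypothesis `"null"` or `"alternative"` (crossed as well if both
#'   given).
#' @param delta alternative probabilistic index.
#' @return list of `wmw_scenario` objects.
#' @export
scenario_grid <- function(latent_dist = c("normal", "t5", "laplace",
                                          "exponential"),
                          linearity = c("linear", "nonlinear"),
                          reliability = c(0.80, 0.60),
                          group_size = c(15L, 50L, 100L),
                          setting = 1:4,
                          hypothesis = "alternative",
                          delta = 0.65) {
  cells <- expand.grid(latent_dist = latent_dist, linearity = linearity,
                       reliability = reliability, group_size = group_size,
                       setting = setting, hypothesis = hypothesis,
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    with(cells[i, ], wmw_scenario(latent_dist, linearity, reliability,
                                  m = group_size, setting = setting,
                                  hypothesis = hypothesis, delta = delta)))
}
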