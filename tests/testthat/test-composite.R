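test_that("standardization gives pooled mean 0, variance 1 and is affine-invariant", {
  pan <- make_factor_panel(60, seed = 3)
  std <- standardize(pan)
  expect_equal(unname(colMeans(std$values)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(std$values, 2, var)), rep(1, 3),
               tolerance = 1e-12)
  pan2 <- pan
  pan2$values[, 1] <- 2.5 * pan2$values[, 1] - 7
  expect_equal(standardize(pan2)$values[, 1], std$values[, 1])

  pan3 <- pan
  pan3$values[, 2] <- 4
  expect_error(standardize(pan3), class = "lw_constant_indicator")
})

test_that("mean composite is the average of standardized indicators", {
  pan <- make_factor_panel(40, seed = 5)
  comp <- mean_composite(pan)
  expect_equal(comp$values, rowMeans(standardize(pan)$values))
  expect_equal(comp$weights$strategy, "mean")
  expect_equal(comp$weights$weights, rep(1 / sqrt(3), 3))

  # single indicator: composite equals the standardized indicator
  p1 <- indicator_panel(pan$values[, 1, drop = FALSE], pan$group)
  expect_equal(mean_composite(p1)$values,
               drop(standardize(p1)$values))

  # duplicated indicator: composite equals the standardized column
  y <- pan$values[, 1]
  pd <- indicator_panel(cbind(y, y, y), pan$group)
  expect_equal(mean_composite(pd)$values, c(scale(y)))
})

test_that("composite reliability formula matches hand-worked moments", {
  # 3 standardized indicators, pairwise covariance 0.8, each reliability 0.8
  S <- matrix(0.8, 3, 3); diag(S) <- 1
  psi <- rep(0.2, 3)
  expect_equal(composite_reliability(c(1, 1, 1), S, psi), 7.2 / 7.8)
  # single-indicator weight vector returns that indicator's reliability
  expect_equal(composite_reliability(c(0, 1, 0), S, psi), 0.8)
  # scale invariance
  a <- c(0.2, 0.5, 0.3)
  expect_equal(composite_reliability(2 * a, S, psi),
               composite_reliability(a, S, psi))
  expect_error(composite_reliability(c(0, 0, 0), S, psi),
               class = "lw_degenerate_weights")
})

test_that("exchangeable indicators get equal maximal-reliability weights", {
  pan <- make_factor_panel(4000, err_sd = rep(0.5, 3), seed = 9)
  comp <- max_reliable_composite(pan, estimate_error_variances(pan))
  w <- comp$weights$weights
  expect_equal(w, rep(1 / sqrt(3), 3), tolerance = 0.05)
  expect_equal(sum(w^2), 1)
  expect_gt(mean(w), 0)
})

test_that("maximal-reliability weights beat the grid-search oracle's field", {
  fm <- factor_moments(c(0.8, 0.8, 0.2))
  best_grid <- grid_search_reliability(fm$S, fm$psi, step = 0.01)
  # population-moment route through the estimates object
  est <- structure(list(pooled_cov = fm$S, error_variance = fm$psi,
                        reliability = 1 - fm$psi,
                        truncation_flags = rep(FALSE, 3)),
                   class = "measurement_estimates")
  pan <- exact_cov_panel(fm$S, 500, seed = 21)
  comp <- max_reliable_composite(pan, est)
  achieved <- composite_reliability(comp$weights$weights, fm$S, fm$psi)
  expect_gte(achieved, best_grid - 1e-4)
  # the low-reliability indicator is down-weighted
  expect_lt(abs(comp$weights$weights[3]), abs(comp$weights$weights[1]))
})

test_that("an indicator with enormous error variance gets weight near zero", {
  fm <- factor_moments(c(0.8, 0.8, 0.8))
  psi <- fm$psi
  psi[3] <- 1e6
  est <- structure(list(pooled_cov = fm$S, error_variance = psi,
                        reliability = c(0.8, 0.8, 0),
                        truncation_flags = rep(FALSE, 3)),
                   class = "measurement_estimates")
  pan <- exact_cov_panel(fm$S, 300, seed = 22)
  comp <- max_reliable_composite(pan, est)
  expect_lt(abs(comp$weights$weights[3]), 1e-2)
})

test_that("eigen solution matches direct numerical maximization", {
  for (s in 1:8) {
    fm <- random_factor_instance(1000 + s)
    rel_of <- function(a) -composite_reliability(a, fm$S, fm$psi)
    opt <- optim(c(1, 1, 1) / sqrt(3), rel_of, method = "BFGS",
                 control = list(reltol = 1e-14))
    est <- structure(list(pooled_cov = fm$S, error_variance = fm$psi,
                          reliability = 1 - fm$psi,
                          truncation_flags = rep(FALSE, 3)),
                     class = "measurement_estimates")
    pan <- exact_cov_panel(fm$S, 250, seed = s)
    comp <- max_reliable_composite(pan, est)
    achieved <- composite_reliability(comp$weights$weights, fm$S, fm$psi)
    expect_equal(achieved, -opt$value, tolerance = 1e-8)
  }
})

test_that("maximal reliability dominates both mean composite and best indicator", {
  for (s in 1:5) {
    pan <- make_factor_panel(500, err_sd = runif(3, 0.3, 1.2), seed = 300 + s)
    est <- estimate_error_variances(pan)
    mx <- max_reliable_composite(pan, est)
    mn <- mean_composite(pan, estimates = est)
    expect_gte(mx$weights$est_reliability,
               mn$weights$est_reliability - 1e-10)
    expect_gte(mx$weights$est_reliability, max(est$reliability) - 1e-6)
  }
})

test_that("rank test is invariant to the weight normalization convention", {
  pan <- make_factor_panel(100, err_sd = c(0.4, 0.8, 0.6), shift = 0.4,
                           seed = 31)
  est <- estimate_error_variances(pan)
  comp <- max_reliable_composite(pan, est)
  g <- comp$group == "group1"
  pi1 <- probabilistic_index(comp$values[g], comp$values[!g])
  scaled <- 5 * comp$values     # any positive rescaling of the weights
  pi2 <- probabilistic_index(scaled[g], scaled[!g])
  expect_identical(pi1, pi2)
})
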