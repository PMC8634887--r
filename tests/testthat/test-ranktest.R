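test_that("probabilistic index counts pairs with the mid-tie rule", {
  expect_equal(probabilistic_index(c(1, 2), c(3, 4)), 1)
  expect_equal(probabilistic_index(c(1, 1), c(1, 1)), 0.5)
  expect_equal(probabilistic_index(c(1, 3, 5), c(2, 4, 6)), 6 / 9)
  expect_error(probabilistic_index(numeric(0), 1), class = "lw_empty_group")
})

test_that("rank-based index equals brute-force pair enumeration", {
  set.seed(17)
  for (i in 1:20) {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    x <- sample(1:6, m, replace = TRUE)   # heavy ties on purpose
    y <- sample(1:6, n, replace = TRUE)
    expect_equal(probabilistic_index(x, y), pi_bruteforce(x, y))
    # antisymmetry (pair counts partition all m*n cross pairs)
    expect_equal(probabilistic_index(x, y), 1 - probabilistic_index(y, x),
                 tolerance = 1e-15)
  }
})

test_that("standardized statistic uses the tie-free null sd", {
  st <- wmw_statistic(c(1, 2), c(3, 4))
  expect_equal(st$sigma0, sqrt(5 / 48))
  expect_equal(st$u, 0.5 / sqrt(5 / 48))
  expect_equal(wmw_statistic(rnorm(50), rnorm(50))$sigma0,
               sqrt(101 / 30000))
  # pi = 0.5 centers u at zero
  expect_equal(wmw_statistic(c(1, 2, 3), c(1, 2, 3))$u, 0)
})

test_that("exact p-values match full enumeration and the reference oracle", {
  expect_equal(wmw_pvalue(c(1, 2), c(3, 4), method = "exact"), 2 / 6)
  set.seed(23)
  for (i in 1:15) {
    m <- sample(3:5, 1); n <- sample(3:5, 1)
    x <- rnorm(m); y <- rnorm(n) + runif(1, -1, 1)
    p_exact <- wmw_pvalue(x, y, method = "exact")
    p_ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_exact, p_ref, tolerance = 1e-12)
    # one-sided tails are complementary on the attainable support
    p_l <- wmw_pvalue(x, y, method = "exact", alternative = "less")
    p_g <- wmw_pvalue(x, y, method = "exact", alternative = "greater")
    expect_gte(p_l + p_g, 1)    # both include the observed atom
  }
  expect_error(wmw_pvalue(rnorm(10), rnorm(10), method = "exact"),
               class = "lw_enumeration_too_large")
  expect_error(wmw_pvalue(c(1, 1, 2), c(2, 3), method = "exact"),
               class = "lw_ties_present")
})

test_that("exhaustive permutation reproduces the exact p-value", {
  set.seed(5)
  x <- rnorm(4); y <- rnorm(4) + 1
  p_exact <- wmw_pvalue(x, y, method = "exact")
  p_perm <- wmw_pvalue(x, y, method = "permutation", n_perm = choose(8, 4))
  expect_identical(p_perm, p_exact)
})

test_that("seeded permutation p-values are reproducible bit for bit", {
  set.seed(77)
  x <- rnorm(12); y <- rnorm(15) + 0.8
  p1 <- wmw_pvalue(x, y, method = "permutation", n_perm = 500, seed = 42)
  p2 <- wmw_pvalue(x, y, method = "permutation", n_perm = 500, seed = 42)
  p3 <- wmw_pvalue(x, y, method = "permutation", n_perm = 500, seed = 43)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  # permutation leaves the caller's RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  invisible(wmw_pvalue(x, y, method = "permutation", n_perm = 200, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("normal approximation agrees with permutation in large samples", {
  set.seed(31)
  x <- rnorm(50); y <- rnorm(50) + 0.3
  p_norm <- wmw_pvalue(x, y, method = "normal")
  p_perm <- wmw_pvalue(x, y, method = "permutation", n_perm = 10000,
                       seed = 8)
  expect_lt(abs(p_norm - p_perm), 0.02)
})

test_that("index and exact p-value are invariant to monotone transforms", {
  set.seed(41)
  x <- rnorm(5); y <- rnorm(5) + 0.7
  f <- function(v) exp(3 * v) - 2
  expect_identical(probabilistic_index(x, y),
                   probabilistic_index(f(x), f(y)))
  expect_identical(wmw_pvalue(x, y, method = "exact"),
                   wmw_pvalue(f(x), f(y), method = "exact"))
})

test_that("exact p-values are uniform on their attainable support under the null", {
  # all C(8,4) assignments of the ranks 1..8; P(p <= c) must equal c at
  # every attainable value c
  splits <- utils::combn(8, 4)
  pv <- apply(splits, 2, function(ix)
    wmw_pvalue((1:8)[ix], (1:8)[-ix], method = "exact"))
  for (cc in unique(pv))
    expect_equal(mean(pv <= cc + 1e-12), cc, tolerance = 1e-12)
})

test_that("latent rank test reduces to the plain test for one indicator", {
  set.seed(51)
  y <- c(rnorm(25), rnorm(25) + 0.9)
  pan <- indicator_panel(matrix(y, ncol = 1), rep(c("a", "b"), each = 25))
  res <- latent_wmw_test(pan, strategy = "mean", method = "normal")
  expect_equal(res$pi_hat, probabilistic_index(y[1:25], y[26:50]))
  expect_equal(res$p_value,
               wmw_pvalue(y[1:25], y[26:50], method = "normal"))
})

test_that("identical group multisets give the exact null identity", {
  v <- matrix(rnorm(60), 20, 3)
  pan <- indicator_panel(rbind(v, v), rep(c("a", "b"), each = 20))
  res <- latent_wmw_test(pan, strategy = "mean", method = "normal")
  expect_equal(res$pi_hat, 0.5)
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("mean and max-rel strategies nearly agree under equal reliabilities", {
  sc <- wmw_scenario("normal", "linear", 0.8, m = 500,
                     hypothesis = "alternative")
  pan <- simulate_panel(sc, seed = 99)
  r_mean <- latent_wmw_test(pan, "mean", method = "normal")
  r_max <- latent_wmw_test(pan, "max_rel", method = "normal")
  expect_lt(abs(r_mean$pi_hat - r_max$pi_hat), 0.02)
})

test_that("strategy and orientation arguments are validated and honored", {
  pan2 <- indicator_panel(matrix(rnorm(80), 40, 2),
                          rep(c("a", "b"), each = 20))
  expect_error(latent_wmw_test(pan2, strategy = "max_rel"),
               class = "lw_unsupported_design")
  set.seed(3)
  v <- matrix(rnorm(120), 40, 3); v[21:40, ] <- v[21:40, ] + 1
  pan <- indicator_panel(v, rep(c("a", "b"), each = 20))
  ref <- indicator_panel(v, rep(c("a", "b"), each = 20), reference = "b")
  r1 <- latent_wmw_test(pan, "mean", method = "normal")
  r2 <- latent_wmw_test(ref, "mean", method = "normal")
  expect_equal(r2$pi_hat, 1 - r1$pi_hat)
  expect_equal(r2$p_value, r1$p_value)
})
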