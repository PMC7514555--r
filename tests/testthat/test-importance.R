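test_that("the shape proposal density is log-concave on the data", {
  s <- guinea_r1_sample()
  grid <- seq(0.05, 5, length.out = 1000)
  lf <- log_f2(grid, s, prior_spec(1, 1))
  d2 <- diff(diff(lf))
  expect_true(all(d2 < 0))
})

test_that("the grid-normalised proposal matches quadrature normalisation", {
  s <- guinea_r1_sample()
  pri <- prior_spec(0, 0)
  g <- pffcens:::.f2_grid(s, pri)
  # oracle: normalising constant by adaptive quadrature of exp(log f2)
  peak <- max(log_f2(g$grid, s, pri))
  Z <- integrate(function(a) exp(log_f2(a, s, pri) - peak),
                 g$grid[1], g$grid[length(g$grid)], rel.tol = 1e-10)$value
  cdf_or <- vapply(c(0.5, 1, 1.5, 2), function(q) {
    integrate(function(a) exp(log_f2(a, s, pri) - peak),
              g$grid[1], q, rel.tol = 1e-10)$value / Z
  }, 0)
  cdf_grid <- stats::approx(g$grid, g$cdf, xout = c(0.5, 1, 1.5, 2))$y
  expect_equal(cdf_grid, cdf_or, tolerance = 1e-4)
})

test_that("weights are uniform when the censoring exponents vanish", {
  n <- 15
  sc <- censoring_scheme(1, n, rep(0L, n))
  s <- simulate_pff(sc, iwd_params(2, 1), seed = 21)
  d <- draw_posterior(s, prior_spec(1, 1), M = 200, seed = 22)
  expect_equal(d$weights, rep(1 / 200, 200), tolerance = 1e-14)
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_true(all(d$alpha > 0) && all(d$lambda > 0))
})

test_that("draws are reproducible from the seed and weights normalised", {
  s <- guinea_r1_sample()
  d1 <- draw_posterior(s, prior_spec(0, 0), M = 500, seed = 5)
  d2 <- draw_posterior(s, prior_spec(0, 0), M = 500, seed = 5)
  expect_identical(d1$alpha, d2$alpha)
  expect_identical(d1$weights, d2$weights)
  expect_equal(sum(d1$weights), 1, tolerance = 1e-12)
})

test_that("point estimates reduce correctly in degenerate and identity cases", {
  s <- guinea_r1_sample()
  d1 <- draw_posterior(s, prior_spec(0, 0), M = 1, seed = 9)
  v <- c(alpha = d1$alpha, lambda = d1$lambda,
         entropy = iwd_entropy(d1$alpha, d1$lambda))
  for (loss in list(loss_spec("self"), loss_spec("linex", p = 0.5),
                    loss_spec("gelf", q = 2))) {
    expect_equal(unname(is_estimate(d1, loss)), unname(v), tolerance = 1e-10)
  }
  d <- draw_posterior(s, prior_spec(0, 0), M = 2000, seed = 10)
  expect_equal(is_estimate(d, loss_spec("gelf", q = -1)),
               is_estimate(d, loss_spec("self")), tolerance = 1e-12)
  tg_small <- c("alpha", "entropy")   # O(1) posterior variances
  li <- is_estimate(d, loss_spec("linex", p = 1e-5), tg_small)
  expect_true(all(abs(li - is_estimate(d, loss_spec("self"), tg_small)) <
                    1e-3))
  est <- vapply(c(0.25, 0.5, 1, 2), function(p) {
    is_estimate(d, loss_spec("linex", p = p), "alpha")
  }, 0)
  expect_true(all(diff(est) < 0))
})

test_that("unweighted sampling matches the exact posterior on complete data", {
  # k = 1, R = 0: Q == 1, so the sampler draws from the posterior itself
  n <- 20
  sc <- censoring_scheme(1, n, rep(0L, n))
  s <- simulate_pff(sc, iwd_params(2, 1), seed = 31)
  pm <- posterior_mean_quadrature(s, a = 1, b = 1)
  d <- draw_posterior(s, prior_spec(1, 1), M = 2e4, seed = 32)
  se <- stats::sd(d$alpha) / sqrt(d$M)
  expect_equal(unname(is_estimate(d, loss_spec("self"), "alpha")),
               unname(pm["alpha"]), tolerance = 4 * se / pm["alpha"])
})

test_that("the HPD scan returns the minimal-width interval", {
  # exhaustive two-candidate case: (1,2) and (2,3) tie, first one wins
  d <- structure(list(alpha = c(1, 2, 3), lambda = c(1, 1, 1),
                      weights = rep(1 / 3, 3), M = 3L, ess = 3),
                 class = "pff_posterior")
  ci <- hpd_interval(d, "alpha", level = 2 / 3)
  expect_equal(c(ci$lower, ci$upper), c(1, 2))
  ci_full <- hpd_interval(d, "alpha", level = 0.999)
  expect_equal(c(ci_full$lower, ci_full$upper), c(1, 3))
  expect_error(hpd_interval(d, "alpha", level = 1.2), "in \\(0, 1\\)")
})

test_that("HPD intervals are never wider than equal-tailed ones", {
  s <- guinea_r1_sample()
  for (r in 1:30) {
    d <- draw_posterior(s, prior_spec(0, 0), M = 1000, seed = 4000 + r)
    h <- hpd_interval(d, "entropy", 0.95)
    e <- equal_tail_interval(d, "entropy", 0.95)
    expect_lte(h$upper - h$lower, e$upper - e$lower + 1e-12)
  }
})

test_that("the HPD interval covers the weighted posterior mode bin", {
  s <- guinea_r1_sample()
  d <- draw_posterior(s, prior_spec(0, 0), M = 1e4, seed = 61)
  v <- pffcens:::.posterior_target(d, "entropy")
  br <- seq(min(v), max(v), length.out = 51)
  bin <- cut(v, br, include.lowest = TRUE)
  wmass <- tapply(d$weights, bin, sum)
  mode_bin <- which.max(wmass)
  ci <- hpd_interval(d, "entropy", 0.95)
  expect_lte(ci$lower, br[mode_bin + 1])
  expect_gte(ci$upper, br[mode_bin])
})

test_that("the sampler enforces its preconditions", {
  sc1 <- censoring_scheme(1, 1, 0L)
  s1 <- pff_sample(2.5, sc1)
  expect_error(draw_posterior(s1, prior_spec(1, 1), M = 10), "m >= 2")
  s <- guinea_r1_sample()
  expect_error(draw_posterior(s, prior_spec(1, 1), M = 0), "at least 1")
  expect_error(log_f2(-1, s), "positive")
})
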