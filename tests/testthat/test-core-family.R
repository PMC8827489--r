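test_that("Marshall-Olkin tilt: identity, boundary preservation, arithmetic", {
  g <- seq(0, 1, by = 0.1)
  expect_equal(mo_cdf(1, g), g)                      # alpha = 1 is the identity
  for (a in c(0.2, 1, 7)) {
    expect_equal(mo_cdf(a, 0), 0)
    expect_equal(mo_cdf(a, 1), 1)
    expect_true(all(diff(mo_cdf(a, g)) > 0))
  }
  expect_equal(mo_cdf(2, 0.5), 1 / 3)                # 0.5 / (2 - 0.5)
  expect_error(mo_cdf(-1, 0.5), "alpha")
})

test_that("Weibull-G transform: anchor points and monotonicity", {
  expect_equal(weibullg_cdf(1, 1, 1 - exp(-1)), 1 - exp(-1))
  expect_equal(weibullg_cdf(2, 2, 1 - exp(-2)), 1 - exp(-1))
  expect_equal(weibullg_cdf(3, 0.5, 0), 0)
  expect_equal(weibullg_cdf(3, 0.5, 1), 1)           # limit, not an error
  g <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(weibullg_cdf(1.7, 0.6, g)) > 0))
})

test_that("family cdf is the composition of the two generators", {
  # x kept where the baseline cdf is representably below 1: the composed
  # path loses the tail once G rounds to 1, the direct path does not
  x <- c(0.1, 0.4, 1, 2.2)
  for (bl in sweep_baselines()) {
    for (i in seq_len(nrow(sweep_params))) {
      p <- sweep_params[i, ]
      d <- mowg_dist(p$alpha, p$c, p$beta, bl)
      expect_equal(pmowg(x, d),
                   mo_cdf(p$alpha, weibullg_cdf(p$c, p$beta, bl$cdf(x, bl$tau))),
                   tolerance = 1e-12)
    }
  }
})

test_that("reductions: alpha = 1 gives Weibull-G; unit generators give the baseline", {
  x <- c(0.2, 0.9, 3)
  bl <- baseline_exponential(1)
  d1 <- mowg_dist(1, 1.8, 0.7, bl)
  expect_equal(pmowg(x, d1), weibullg_cdf(1.8, 0.7, bl$cdf(x, bl$tau)),
               tolerance = 1e-14)
  for (lam in c(0.5, 2)) {
    d <- mowg_dist(1, 1, 1, baseline_exponential(lam))
    expect_equal(pmowg(x, d), stats::pexp(x, lam), tolerance = 1e-14)
    expect_equal(dmowg(x, d), stats::dexp(x, lam), tolerance = 1e-12)
  }
  expect_equal(pmowg(log(2), mowg_dist(1, 1, 1, baseline_exponential(1))), 0.5)
  expect_equal(pmowg(1, mowg_dist(2, 1, 1, baseline_exponential(1))),
               (1 - exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("support convention and boundary evaluation", {
  d <- mowg_dist(0.4, 2, 1, baseline_weibull(1.5, 1))
  expect_equal(pmowg(c(-1, 0), d), c(0, 0))
  expect_equal(dmowg(-0.5, d), 0)
  expect_equal(pmowg(1e8, d), 1)
  # density pole at the origin when the effective power is below one
  dlow <- mowg_dist(1, 0.5, 1, baseline_exponential(1))
  expect_identical(dmowg(0, dlow), Inf)
  expect_equal(dmowg(0, mowg_dist(1, 1, 1, baseline_exponential(1))), 1)
})

test_that("density normalizes to 1 and differentiates the cdf", {
  for (bl in sweep_baselines()) {
    for (i in seq_len(nrow(sweep_params))) {
      p <- sweep_params[i, ]
      d <- mowg_dist(p$alpha, p$c, p$beta, bl)
      expect_equal(quad_norm(function(x) dmowg(x, d)), 1, tolerance = 1e-6)
    }
  }
  d <- mowg_dist(0.5, 2, 1, baseline_exponential(1))
  for (x0 in c(0.3, 0.7, 1.4))
    expect_equal(dmowg(x0, d), fd(function(x) pmowg(x, d), x0),
                 tolerance = 1e-4)
})

test_that("quantile: corrected inversion round-trips through the cdf", {
  pgrid <- seq(0.01, 0.99, by = 0.01)
  for (bl in sweep_baselines()) {
    for (i in seq_len(nrow(sweep_params))) {
      pr <- sweep_params[i, ]
      d <- mowg_dist(pr$alpha, pr$c, pr$beta, bl)
      expect_lt(max(abs(pmowg(qmowg(pgrid, d), d) - pgrid)), 1e-8)
      expect_equal(qmowg(0, d), 0)
    }
  }
  # hand-inverted point: alpha = 2, unit generators, Exp(1)
  d2 <- mowg_dist(2, 1, 1, baseline_exponential(1))
  expect_equal(qmowg(0.5, d2), -log(1 / 3), tolerance = 1e-10)
  expect_error(qmowg(1.2, d2), "p")
})

test_that("median equals the 0.5 quantile and solves cdf = 0.5", {
  d1 <- mowg_dist(1, 1, 1, baseline_exponential(1))
  expect_equal(mowg_median(d1), log(2), tolerance = 1e-12)
  d2 <- mowg_dist(2, 1, 1, baseline_exponential(1))
  expect_equal(mowg_median(d2), qmowg(0.5, d2))
  d3 <- mowg_dist(0.3, 2.2, 0.8, baseline_weibull(1.4, 2))
  expect_equal(pmowg(mowg_median(d3), d3), 0.5, tolerance = 1e-10)
})

test_that("hazard: h * S = f, exponential reduction is constant", {
  d <- mowg_dist(0.7, 1.6, 1.2, baseline_weibull(2, 1))
  x <- c(0.2, 0.8, 1.5, 3)
  expect_equal(hmowg(x, d) * pmowg(x, d, lower.tail = FALSE), dmowg(x, d),
               tolerance = 1e-10)
  expect_true(all(hmowg(x, d) >= 0))
  dexp_red <- mowg_dist(1, 1, 2, baseline_exponential(3))
  expect_equal(hmowg(c(0.5, 1, 4), dexp_red), rep(3 / 2, 3), tolerance = 1e-10)
})

test_that("inversion sampling: deterministic, correct location and law", {
  d <- mowg_dist(1, 1, 1, baseline_exponential(1))
  expect_identical(rmowg(100, d, seed = 7), rmowg(100, d, seed = 7))
  x <- rmowg(1e5, d, seed = 3)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))        # Exp(1) mean 1, sd 1
  d2 <- mowg_dist(0.4, 1.8, 0.9, baseline_weibull(1.3, 1))
  ks <- suppressWarnings(stats::ks.test(rmowg(4000, d2, seed = 5),
                                        function(q) pmowg(q, d2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("parameter validation rejects non-positive generator values", {
  bl <- baseline_exponential(1)
  expect_error(mowg_dist(0, 1, 1, bl), "alpha")
  expect_error(mowg_dist(1, -2, 1, bl), "'c'")
  expect_error(mowg_dist(1, 1, NA, bl), "beta")
  expect_error(baseline_exponential(-1), "rate")
  p <- generator_params(3, 1, 1)
  expect_equal(alpha_bar(p), -2)
})
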