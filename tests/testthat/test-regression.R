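test_that("log-lifetime density is the change-of-variables image of MOW-W", {
  p <- lmoww_params(2, 1.5, 1, 0.8, 0)
  mu <- 0.4
  # X ~ MOW-W(alpha, c, beta, gamma = 1/sigma, delta = e^mu) => Y = log X
  d <- mowg_dist(p$alpha, p$c, p$beta,
                 baseline_weibull(1 / p$sigma, exp(mu)))
  set.seed(5)
  y <- stats::rnorm(10, mu, 1)
  expect_equal(lmoww_logpdf(y, mu, p), dmowg(exp(y), d, log = TRUE) + y,
               tolerance = 1e-10)
  # survival side of the same identity
  expect_equal(lmoww_logsf(y, mu, p),
               pmowg(exp(y), d, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-10)
})

test_that("log-lifetime density normalizes over the real line", {
  p <- lmoww_params(2, 1.5, 1, 0.8, 0)
  v <- stats::integrate(function(y) exp(lmoww_logpdf(y, 0, p)), -Inf, Inf,
                        rel.tol = 1e-9)$value
  expect_equal(v, 1, tolerance = 1e-6)
  # standardized error density carries no 1/sigma factor
  vz <- stats::integrate(function(z) lmoww_zpdf(z, p), -Inf, Inf,
                         rel.tol = 1e-9)$value
  expect_equal(vz, 1, tolerance = 1e-6)
})

test_that("unit generators reduce to the smallest-extreme-value density", {
  p <- lmoww_params(1, 1, 1, 0.7, 0)
  y <- c(-1, 0, 0.5)
  mu <- 0.2
  z <- (y - mu) / 0.7
  expect_equal(lmoww_logpdf(y, mu, p), -log(0.7) + z - exp(z),
               tolerance = 1e-12)
  # survival anchors: S(0) = e^-1 at standard parameters; S -> 1 far left
  p1 <- lmoww_params(1, 1, 1, 1, 0)
  expect_equal(exp(lmoww_logsf(0, 0, p1)), exp(-1), tolerance = 1e-12)
  expect_equal(lmoww_logsf(-40, 0, p1), 0, tolerance = 1e-12)
})

test_that("censored likelihood: reductions, hand value, and both forms agree", {
  p1 <- lmoww_params(1, 1, 1, 1, 0.0)
  V <- matrix(1, 2, 1)
  # one event and one censored observation at y = 0: log f + log S = -2
  expect_equal(censored_loglik(c(0, 0), c(1, 0), V, p1), -2, tolerance = 1e-12)
  # all-event and all-censored reductions
  set.seed(8)
  y <- stats::rnorm(12)
  expect_equal(censored_loglik(y, rep(1, 12), matrix(1, 12, 1), p1),
               sum(lmoww_logpdf(y, 0, p1)), tolerance = 1e-12)
  expect_equal(censored_loglik(y, rep(0, 12), matrix(1, 12, 1), p1),
               sum(lmoww_logsf(y, 0, p1)), tolerance = 1e-12)
  # compact vs expanded algebraic forms on random inputs
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    V2 <- cbind(1, stats::rbinom(n, 1, 0.5))
    pr <- lmoww_params(exp(stats::rnorm(1)), exp(stats::rnorm(1, 0, 0.3)),
                       exp(stats::rnorm(1, 0, 0.3)), exp(stats::rnorm(1, 0, 0.3)),
                       stats::rnorm(2))
    yy <- stats::rnorm(n, drop(V2 %*% pr$tau), pr$sigma)
    ev <- stats::rbinom(n, 1, 0.7)
    expect_equal(censored_loglik(yy, ev, V2, pr, form = "compact"),
                 censored_loglik(yy, ev, V2, pr, form = "expanded"),
                 tolerance = 1e-10)
  }
  # rank-deficient design rejected before any optimization
  expect_error(censored_loglik(y, rep(1, 12), cbind(1, 1)[rep(1, 12), ],
                               lmoww_params(1, 1, 1, 1, c(0, 0))),
               "rank deficient")
})

test_that("synthetic cohort: calibration, determinism, degenerate cases", {
  p <- lmoww_params(2, 1.5, 1, 0.8, c(3.5, 0.6))
  coh <- simulate_censored_cohort(5000, p, censoring_rate = 0.2, seed = 1)
  expect_lt(abs(attr(coh, "censoring_achieved") - 0.2), 0.03)
  expect_identical(coh, simulate_censored_cohort(5000, p, censoring_rate = 0.2,
                                                 seed = 1))
  all_ev <- simulate_censored_cohort(200, p, censoring_rate = 0, seed = 2)
  expect_true(all(all_ev$event == 1))
  expect_error(simulate_censored_cohort(100, p, censoring_rate = 1), "censoring_rate")
})

test_that("uncensored draws follow the stated survival function", {
  p <- lmoww_params(2, 1.5, 1, 0.8, c(3.5, 0))   # single arm effect zero
  coh <- simulate_censored_cohort(8000, p, censoring_rate = 0, seed = 6)
  for (y0 in c(2.8, 3.5, 4.2)) {
    emp <- mean(coh$y > y0)
    theo <- exp(lmoww_logsf(y0, 3.5, p))
    expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / 8000) + 1e-3)
  }
})

test_that("nested log-Weibull fit agrees with survreg", {
  p <- lmoww_params(2, 1.5, 1, 0.8, c(3.5, 0.6))
  coh <- simulate_censored_cohort(500, p, censoring_rate = 0.2, seed = 11)
  fit <- fit_lmoww(coh$time, coh$event, covariates = coh["arm"],
                   fixed = c(alpha = 1, c = 1, beta = 1), seed = 2)
  sr <- survival::survreg(survival::Surv(time, event) ~ arm, data = coh,
                          dist = "weibull")
  # survreg reports the time-scale likelihood; ours is on the log scale
  adj <- sum(coh$y[coh$event == 1])
  expect_equal(fit$negloglik, -sr$loglik[2] - adj, tolerance = 1e-4)
  expect_equal(unname(fit$tau), unname(stats::coef(sr)), tolerance = 1e-4)
  expect_equal(fit$params$sigma, sr$scale, tolerance = 1e-4)
})

test_that("input contracts of the regression fitter", {
  p <- lmoww_params(1, 1, 1, 0.8, c(1, 0.3))
  coh <- simulate_censored_cohort(60, p, censoring_rate = 0.1, seed = 3)
  expect_error(fit_lmoww(coh$time, rep(0, 60), covariates = coh["arm"]),
               "no events")
  expect_error(fit_lmoww(-coh$time, coh$event), "positive")
  expect_error(fit_lmoww(coh$time, coh$event, fixed = c(bogus = 1)), "pin")
})
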