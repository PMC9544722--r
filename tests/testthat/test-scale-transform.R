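test_that("log-link transform matches closed forms and numeric integration", {
  ## pure Poisson: mean 1, V_P 1, no additive variance
  z <- transform_poisson_log(0, 0, 0)
  expect_equal(z$mean, 1)
  expect_equal(z$v_p, 1)
  expect_equal(z$v_a_obs, 0)
  expect_equal(z$h2, 0)

  ## frozen values verified against the quadrature oracle below
  z <- transform_poisson_log(0, 0.2, 0.3)
  expect_equal(z$mean, exp(0.25), tolerance = 1e-12)
  expect_equal(z$mean, 1.2840254, tolerance = 1e-6)
  expect_equal(z$v_p, 2.3535855, tolerance = 1e-6)
  expect_equal(z$v_a_obs, 0.3297443, tolerance = 1e-6)
  expect_equal(z$h2, z$v_a_obs / z$v_p)

  ## independent oracle: Gauss-Hermite integration of the log-normal
  ## mixture mean and variance
  for (pars in list(c(0, 0.2, 0.3), c(1, 0.05, 0.4), c(-1, 0.6, 0.1))) {
    q <- statmod::gauss.quad.prob(80, dist = "normal", mu = pars[1],
                                  sigma = sqrt(pars[2] + pars[3]))
    lam <- exp(q$nodes)
    mean_o <- sum(q$weights * lam)
    vp_o <- mean_o + sum(q$weights * lam^2) - mean_o^2
    z <- transform_poisson_log(pars[1], pars[2], pars[3])
    expect_equal(z$mean, mean_o, tolerance = 1e-8)
    expect_equal(z$v_p, vp_o, tolerance = 1e-8)
  }

  expect_error(transform_poisson_log(800, 1, 0), "overflow|rescal")
})

test_that("logit transform matches degenerate case and Monte Carlo", {
  z <- transform_logit(0, 1e-14, 0)
  expect_equal(z$mean, 0.5, tolerance = 1e-6)
  expect_equal(z$v_p, 0.25, tolerance = 1e-6)
  expect_equal(z$v_a_obs / 1e-14, 0.0625, tolerance = 1e-4)

  ## va = 0 kills the additive variance regardless of the rest
  z0 <- transform_logit(1.3, 0, 0.7)
  expect_equal(z0$v_a_obs, 0)
  expect_equal(z0$h2, 0)

  ## Monte Carlo oracle at mu = 2, va = 0.5, v_other = 0.5
  set.seed(42)
  x <- rnorm(2e6, 2, 1)
  p_mc <- mean(plogis(x))
  psi_mc <- mean(dlogis(x))
  se_p <- sd(plogis(x)) / sqrt(2e6)
  se_psi <- sd(dlogis(x)) / sqrt(2e6)
  z <- transform_logit(2, 0.5, 0.5)
  expect_lt(abs(z$mean - p_mc), 3 * se_p)
  expect_lt(abs(z$v_a_obs - psi_mc^2 * 0.5), 3 * 2 * psi_mc * se_psi * 0.5 + 1e-6)
})

test_that("quadrature is stable under node doubling", {
  grid <- expand.grid(mu = c(-2, 0, 1, 3), va = c(0, 0.1, 1),
                      vo = c(0.05, 1, 4))
  for (i in seq_len(nrow(grid))) {
    z32 <- transform_logit(grid$mu[i], grid$va[i], grid$vo[i], nodes = 32)
    z64 <- transform_logit(grid$mu[i], grid$va[i], grid$vo[i], nodes = 64)
    expect_lt(abs(z32$mean - z64$mean), 1e-8)
    expect_lt(abs(z32$v_a_obs - z64$v_a_obs), 1e-8)
  }
})

test_that("data-scale invariants hold across a parameter grid", {
  grid <- expand.grid(mu = seq(-3, 3, by = 1.5), va = c(0, 0.05, 0.5, 2),
                      vo = c(0, 0.3, 1.5))
  for (i in seq_len(nrow(grid))) {
    for (fun in list(transform_poisson_log, transform_logit)) {
      z <- fun(grid$mu[i], grid$va[i], grid$vo[i])
      expect_gte(z$h2, 0)
      expect_lte(z$h2, 1)
      expect_gte(z$ia, 0)
      expect_equal(z$h2, z$v_a_obs / z$v_p)
    }
  }
  ## monotonicity: v_a_obs strictly increasing in va, all else fixed
  for (fun in list(transform_poisson_log, transform_logit)) {
    vas <- c(0.01, 0.05, 0.1, 0.3)
    out <- vapply(vas, function(v) fun(0.5, v, 0.4)$v_a_obs, 0)
    expect_true(all(diff(out) > 0))
  }
})

test_that("transform_posterior works per draw and summarizes correctly", {
  ## fabricate a fit object with constant draws: summaries equal the
  ## single transformed value
  draws <- matrix(rep(c(1.2, 0.06, 0.15, 0.3), each = 120), ncol = 4,
                  dimnames = list(NULL, c("(Intercept)", "v_animal",
                                          "v_cohort", "v_resid")))
  fit <- structure(list(draws = draws, family = "poisson",
                        layout = list(single = list(
                          intercept = "(Intercept)",
                          fixed = c(), va = "v_animal",
                          other = c("v_cohort", "v_resid"),
                          resid_fixed = 0))),
                   class = "fitqg_fit")
  tp <- transform_posterior(fit, "single")
  one <- transform_poisson_log(1.2, 0.06, 0.45)
  expect_equal(tp$summary["mean", "mode"], one$mean, tolerance = 1e-9)
  expect_equal(tp$summary["h2", "hpd_low"], one$h2, tolerance = 1e-9)
  expect_equal(unique(tp$draws$ia), one$ia, tolerance = 1e-12)

  ## component checks
  expect_error(transform_posterior(fit, "zi"), "zero-inflated")

  ## per-draw ratio arithmetic: a draw with v_a_obs 0.004 and v_p 0.119
  ## gives h2 ~ 0.0336, distinct from any ratio of summaries
  expect_equal(0.004 / 0.119, 0.0336, tolerance = 1e-3)
})
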