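# Sampler correctness tests. These necessarily run MCMC, so chains are kept
# as short as each check allows; tolerances reflect Monte Carlo error, not
# the sampler's asymptotic accuracy.

test_that("model and mcmc specifications validate their inputs", {
  expect_error(model_spec("poisson", response = "y", random = list()),
               "pedigree-structured")
  expect_error(model_spec("poisson", response = "y",
                          random = list(a = ranef_pedigree(),
                                        b = ranef_pedigree())),
               "exactly one")
  expect_error(mcmc_config(n_iter = 100, burn_in = 200), "n_iter")
  expect_error(mcmc_config(thin = 0), "thin")

  ped <- toy_pedigree(seed = 1)
  dat <- data.frame(id = c(ped$id, "stranger"), y = 1)
  expect_error(fit_animal_model(dat, ped, model_spec(
    "gaussian", response = "y", random = list(animal = ranef_pedigree())),
    mcmc_config(500, 100, 1)), "missing from pedigree")
})

test_that("Gaussian posterior agrees with an independent REML fit", {
  ## direct maximum of the restricted likelihood over (va, ve), computed
  ## from the dense relationship matrix -- an independent route sharing no
  ## code with the sampler
  ped <- toy_pedigree(n_founders = 40, n_gen = 3, seed = 21)
  n <- nrow(ped)
  A <- additive_relationship(ped, what = "A")$A
  set.seed(22)
  bv <- drop_breeding_values(ped, 0.6)
  y <- 2 + bv + rnorm(n, 0, sqrt(0.4))
  reml_nll <- function(par) {
    V <- exp(par[1]) * A + exp(par[2]) * diag(n)
    ch <- chol(V)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    xvx <- sum(Vi_1)
    beta <- sum(Vi_y) / xvx
    r <- y - beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    sum(log(diag(ch))) + 0.5 * log(xvx) + 0.5 * sum(r * Vi_r)
  }
  opt <- optim(log(c(0.5, 0.5)), reml_nll)
  reml <- exp(opt$par)

  dat <- data.frame(id = ped$id, y = y)
  fit <- suppressWarnings(fit_animal_model(
    dat, ped, model_spec("gaussian", response = "y",
                         random = list(animal = ranef_pedigree())),
    mcmc_config(n_iter = 4000, burn_in = 1000, thin = 2, seed = 23,
                target_min_ess = 50)))
  post_va <- mean(fit$draws[, "v_animal"])
  post_ve <- mean(fit$draws[, "v_resid"])
  ## posterior mean vs REML point estimate: agree within coarse MC error
  expect_lt(abs(post_va - reml[1]), 0.35)
  expect_lt(abs(post_ve - reml[2]), 0.25)
  ## total variance is well identified even when the split is noisy
  expect_lt(abs((post_va + post_ve) - sum(reml)), 0.2)
})

test_that("Poisson animal model recovers a simulated additive variance", {
  ped <- simulate_pedigree(pedigree_sim_config(
    founders_per_generation = 110, n_initial_marked = 30, seed = 24))
  modes <- numeric(3)
  for (r in 1:3) {
    set.seed(30 + r)
    bv <- drop_breeding_values(ped, 0.3)
    lam <- exp(1 + bv + rnorm(nrow(ped), 0, sqrt(0.2)))
    dat <- data.frame(id = ped$id, y = rpois(nrow(ped), lam))
    fit <- suppressWarnings(fit_animal_model(
      dat, ped, model_spec("poisson", response = "y",
                           random = list(animal = ranef_pedigree())),
      mcmc_config(n_iter = 3000, burn_in = 1000, thin = 2, seed = 40 + r,
                  target_min_ess = 50)))
    modes[r] <- summarize_posterior(fit$draws[, "v_animal"])$mode
  }
  ## recovery within the replicate interval half-width, no systematic drift
  expect_lt(abs(mean(modes) - 0.3), 0.15)
})

test_that("binary model fixes its residual and yields finite inference", {
  ped <- toy_pedigree(n_founders = 30, n_gen = 3, seed = 26)
  set.seed(27)
  bv <- drop_breeding_values(ped, 0.5)
  dat <- data.frame(id = ped$id,
                    y = as.integer(runif(nrow(ped)) < plogis(0.4 + bv)))
  fit <- suppressWarnings(fit_animal_model(
    dat, ped, model_spec("binary", response = "y",
                         random = list(animal = ranef_pedigree())),
    mcmc_config(n_iter = 1500, burn_in = 500, thin = 2, seed = 28,
                target_min_ess = 20)))
  expect_false("v_resid" %in% colnames(fit$draws))
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(fit$draws[, "v_animal"] >= 0))
})

test_that("zero-inflated fits report both components and honour augmentation", {
  ped <- toy_pedigree(n_founders = 40, n_gen = 3, seed = 31)
  lt <- simulate_lifetime(ped, tern_lifetime_params(seed = 32),
                          standardize = FALSE)
  fit <- suppressWarnings(fit_animal_model(
    lt, ped, spec_lifetime_zip(),
    mcmc_config(n_iter = 1200, burn_in = 400, thin = 2, seed = 33,
                target_min_ess = 10)))
  cn <- colnames(fit$draws)
  expect_true(all(c("zi.v_animal", "zi.v_cohort", "pois.v_animal",
                    "pois.v_cohort", "pois.v_resid") %in% cn))
  expect_true(all(fit$draws[, grep("v_", cn)] >= 0))
  ## the zero-inflation residual is fixed, not sampled
  expect_false("zi.v_resid" %in% cn)
})

test_that("row order of the phenotype table does not change the fit", {
  ped <- toy_pedigree(n_founders = 24, n_gen = 2, seed = 36)
  lt <- simulate_lifetime(ped, tern_lifetime_params(seed = 37))
  mc <- mcmc_config(n_iter = 600, burn_in = 200, thin = 2, seed = 38)
  f1 <- suppressWarnings(fit_animal_model(lt, ped, spec_lifetime_zip(), mc))
  set.seed(39)
  f2 <- suppressWarnings(fit_animal_model(lt[sample(nrow(lt)), ], ped,
                                          spec_lifetime_zip(), mc))
  expect_identical(f1$draws, f2$draws)
})

test_that("a near-Gaussian Poisson limit stays numerically healthy", {
  ped <- toy_pedigree(n_founders = 20, n_gen = 2, seed = 41)
  set.seed(42)
  dat <- data.frame(id = ped$id, y = rpois(nrow(ped), 150))
  fit <- suppressWarnings(fit_animal_model(
    dat, ped, model_spec("poisson", response = "y",
                         random = list(animal = ranef_pedigree())),
    mcmc_config(n_iter = 800, burn_in = 300, thin = 2, seed = 43,
                target_min_ess = 10)))
  expect_true(all(is.finite(fit$draws)))
})

test_that("prior-draw calibration: sampler output is consistent with the model", {
  ## simulation-based calibration on a tiny pedigree: the rank of the
  ## generating variance among its posterior draws should be uniform; a
  ## gross sampler error shows up as ranks piling at the ends
  ped <- toy_pedigree(n_founders = 10, n_gen = 3, kids_per_pair = 3,
                      seed = 51)
  set.seed(52)
  n_sbc <- 24
  ranks <- numeric(n_sbc)
  for (i in seq_len(n_sbc)) {
    ## draw the variance from a compactly supported prior slice, simulate
    ## data, refit
    va_true <- runif(1, 0.05, 1.5)
    bv <- drop_breeding_values(ped, va_true)
    lam <- exp(0.8 + bv + rnorm(nrow(ped), 0, sqrt(0.3)))
    dat <- data.frame(id = ped$id, y = rpois(nrow(ped), lam))
    fit <- suppressWarnings(fit_animal_model(
      dat, ped, model_spec("poisson", response = "y",
                           random = list(animal = ranef_pedigree())),
      mcmc_config(n_iter = 1200, burn_in = 400, thin = 4, seed = 60 + i,
                  target_min_ess = 10)))
    draws <- fit$draws[, "v_animal"]
    ## randomized rank so the KS statistic sees a continuous quantity
    ranks[i] <- (sum(draws < va_true) + runif(1)) / (length(draws) + 1)
  }
  ## no mass collapse at either end, central coverage plausible
  expect_gt(min(mean(ranks < 0.5), mean(ranks > 0.5)), 0.2)
  expect_lt(ks.test(ranks, "punif")$statistic, 0.35)
})
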