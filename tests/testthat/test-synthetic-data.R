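test_that("pedigree simulator is deterministic and structurally calibrated", {
  ped1 <- simulate_pedigree(pedigree_sim_config(seed = 7))
  ped2 <- simulate_pedigree(pedigree_sim_config(seed = 7))
  expect_identical(as.data.frame(ped1), as.data.frame(ped2))

  ## founders only with a single generation
  p0 <- simulate_pedigree(pedigree_sim_config(n_generations = 1, seed = 1))
  s0 <- summary(p0)
  expect_equal(s0$max_depth, 1)
  expect_equal(s0$n_fullsibs, 0)

  ## default config reproduces the study pedigree's structure within 20%:
  ## ~6290 records, depth 5, ~2417 paternities
  s <- summary(ped1)
  expect_lt(abs(s$n_records - 6290) / 6290, 0.2)
  expect_equal(s$max_depth, 5)
  expect_lt(abs(s$n_paternities - 2417) / 2417, 0.2)

  ## extinction is reported, not silent
  expect_error(simulate_pedigree(
    pedigree_sim_config(founders_per_generation = 0, n_initial_marked = 2,
                        recruitment_prob = 0.01, seed = 3)),
    "extinct|offspring")
})

test_that("gene dropping has the correct first and second moments", {
  ped <- toy_pedigree(seed = 3)
  expect_identical(unname(drop_breeding_values(ped, 0)), rep(0, nrow(ped)))
  expect_error(drop_breeding_values(ped, -1), "non-negative")

  ## founder variance over replicates
  f <- pedigree(sprintf("f%d", 1:5), NA, NA)
  set.seed(11)
  reps <- replicate(4000, drop_breeding_values(f, va = 0.6))
  v <- mean(apply(reps, 2, var))
  se <- sd(apply(reps, 2, var)) / sqrt(4000)
  expect_lt(abs(v - 0.6), 3 * se)

  ## covariance across a structured 10-individual pedigree equals va * A
  ped10 <- pedigree(c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
                    c(NA, NA, NA, "a", "a", "a", "d", "d", NA, "h"),
                    c(NA, NA, NA, "b", "b", "c", "c", "g", NA, "i"))
  A <- additive_relationship(ped10, what = "A")$A
  set.seed(12)
  reps <- replicate(6000, drop_breeding_values(ped10, va = 1))
  emp <- cov(t(reps))
  expect_lt(max(abs(emp - A)), 0.12)   # ~4 MC standard errors elementwise
})

test_that("lifetime simulator reproduces closed-form mixture moments", {
  n <- 1e5
  founders <- pedigree(sprintf("f%06d", seq_len(n)), NA, NA, cohort = 1)
  p <- trait_sim_params(mu_zi = qlogis(0.8714), mu_pois = log(5.62),
                        seed = 21)
  lt <- simulate_lifetime(founders, p, standardize = FALSE)
  zero_expect <- 0.8714 + (1 - 0.8714) * exp(-5.62)
  expect_lt(abs(mean(lt$fitness == 0) - zero_expect),
            3 * sqrt(zero_expect * (1 - zero_expect) / n))
  expect_lt(abs(mean(lt$fitness) - (1 - 0.8714) * 5.62), 0.025)

  ## structural-zero probability one: all zeros
  p1 <- trait_sim_params(mu_zi = 50, mu_pois = 1, seed = 22)
  expect_true(all(simulate_lifetime(founders[1:500, ], p1)$fitness == 0))

  ## determinism
  ped <- toy_pedigree(n_founders = 20, seed = 5)
  pars <- tern_lifetime_params(seed = 33)
  expect_identical(simulate_lifetime(ped, pars),
                   simulate_lifetime(ped, pars))
})

test_that("default lifetime parameters span the study's fitness range", {
  ped <- simulate_pedigree(pedigree_sim_config(seed = 19))
  lt <- simulate_lifetime(ped, tern_lifetime_params(seed = 20))
  expect_gte(max(lt$fitness), 20)
  expect_lt(mean(lt$fitness == 0) * 100 - 87.19, 2)
})

test_that("heritable latent values show the expected parent-offspring resemblance", {
  ped <- simulate_pedigree(pedigree_sim_config(
    founders_per_generation = 250, n_initial_marked = 60, seed = 14))
  va <- 0.8
  bv <- drop_breeding_values(ped, va, seed = 15)
  has_sire <- !is.na(ped$sire)
  off <- bv[has_sire]
  par <- bv[match(ped$sire[has_sire], ped$id)]
  ## cov(parent, offspring) = va / 2
  expect_lt(abs(cov(par, off) - va / 2) / (va / 2), 0.25)
})

test_that("inclusion filter implements the study rule", {
  tab <- data.frame(id = c("dead_young", "alive_young", "alive_old"),
                    hatch_year = c(2010, 2012, 2005),
                    fitness = c(0L, 2L, 5L),
                    status = c("dead", "alive", "alive"),
                    last_seen_year = c(2012, 2019, 2019))
  out <- apply_inclusion_filter(tab, study_end_year = 2019, min_age = 11)
  expect_setequal(out$id, c("dead_young", "alive_old"))
  expect_equal(out$status[out$id == "alive_old"], "alive")
})

test_that("annual simulator matches closed forms and its invariants", {
  n <- 4000
  founders <- pedigree(sprintf("f%05d", seq_len(n)), NA, NA, cohort = 1)
  ## zero-variance, no-age-effect ARS mean equals the truncation oracle
  p <- annual_sim_params(mu_ars = log(0.9), mu_aas = qlogis(0.8),
                         beta_age_ars = 0, beta_age_aas = 0, seed = 31)
  at <- simulate_annual(founders, p, ids = founders$id)
  oracle <- fitqg:::mean_pois_trunc(0.9, 3)
  expect_lt(abs(mean(at$ars) - oracle), 3 * sd(at$ars) / sqrt(nrow(at)))

  ## invariants: ars capped at 3, ages consecutive from 1, aas = 1 before
  ## the final year and 0 in it
  expect_true(all(at$ars <= 3))
  by_id <- split(at, at$id)
  one <- by_id[[which.max(vapply(by_id, nrow, 1L))]]
  expect_identical(one$age, seq_len(nrow(one)))
  expect_identical(one$aas, c(rep(1L, nrow(one) - 1), 0L))

  ## survival probability ~ 1: every individual reaches max age
  p2 <- annual_sim_params(mu_ars = 0, mu_aas = 30, max_age = 8, seed = 32)
  at2 <- simulate_annual(founders[1:200, ], p2, ids = founders$id[1:200])
  expect_true(all(tapply(at2$age, at2$id, max) == 8))

  ## determinism
  ped <- toy_pedigree(n_founders = 16, seed = 6)
  pars <- tern_annual_params(seed = 44)
  expect_identical(simulate_annual(ped, pars), simulate_annual(ped, pars))
})

test_that("fitness tables round-trip through delimited text", {
  ped <- toy_pedigree(n_founders = 10, seed = 8)
  lt <- simulate_lifetime(ped, tern_lifetime_params(seed = 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_table(lt, f)
  back <- read_fitness_table(f)
  expect_s3_class(back, "fitqg_lifetime_table")
  expect_equal(back$fitness, lt$fitness)
})
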