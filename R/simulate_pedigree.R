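#' Configuration for the pedigree simulator
#'
#' The simulator emulates a colonially breeding, serially monogamous study
#' population monitored over several generations: an initial cohort of
#' marked adults, a continual influx of unmarked immigrant breeders every
#' generation (genetic founders that never receive pedigree records, so
#' their offspring carry missing parent links), local recruitment of marked
#' fledglings into the breeding pool, and annual breeding in pairs rearing
#' up to three fledglings, with partial mate retention between years.
#'
#' Local recruits are site-faithful and hold longer breeding tenure than
#' transient immigrants (`tenure_ratio`), and pairs containing marked
#' (experienced local) breeders fledge more chicks (`success_ratio`), as
#' observed in long-term seabird colonies. Defaults are calibrated so that
#' five generations reproduce the structure of the study pedigree this
#' package emulates: roughly 6300 records, maximum depth five, roughly 2400
#' recorded paternities, and about three quarters of the breeding pool
#' consisting of immigrants in any given year.
#'
#' @param n_generations number of record generations (the marked founder
#'   cohort counts as generation 1).
#' @param founders_per_generation number of unmarked immigrant breeders
#'   entering the pool each generation.
#' @param recruitment_prob probability that a fledgling recruits into the
#'   next generation's breeding pool.
#' @param mean_breeding_years geometric-mean breeding tenure (years) of
#'   locals and immigrants.
#' @param n_initial_marked number of marked adults founding generation 1
#'   (these receive founder records; they play the role of the initially
#'   transponder-marked adults).
#' @param brood_prob baseline per-chick fledging probability; a pair-year
#'   rears `Binomial(3, brood_prob * a^m)` fledglings where `m` is the
#'   number of marked pair members and `a = sqrt(success_ratio)`.
#' @param tenure_ratio ratio of expected breeding tenure of local recruits
#'   to immigrants.
#' @param success_ratio per-capita fledging advantage of marked over
#'   unmarked breeders; together with `tenure_ratio` this controls the
#'   fraction of records with recorded parents.
#' @param mate_fidelity probability that a pair is retained to the next
#'   breeding year when both members are still active.
#' @param years_per_generation breeding years simulated within a generation.
#' @param seed integer seed; the same seed reproduces the pedigree exactly.
#' @return A list of class `fitqg_pedsim_config`.
#' @export
pedigree_sim_config <- function(n_generations = 5,
                                founders_per_generation = 1140,
                                recruitment_prob = 0.14,
                                mean_breeding_years = 3.3,
                                n_initial_marked = 180,
                                brood_prob = 0.205,
                                tenure_ratio = 2.3,
                                success_ratio = 3.1,
                                mate_fidelity = 0.6,
                                years_per_generation = 6,
                                seed = NULL) {
  cfg <- list(n_generations = as.integer(n_generations),
              founders_per_generation = as.integer(founders_per_generation),
              recruitment_prob = recruitment_prob,
              mean_breeding_years = mean_breeding_years,
              n_initial_marked = as.integer(n_initial_marked),
              brood_prob = brood_prob,
              tenure_ratio = tenure_ratio,
              success_ratio = success_ratio,
              mate_fidelity = mate_fidelity,
              years_per_generation = as.integer(years_per_generation),
              seed = seed)
  stopifnot(cfg$n_generations >= 1, cfg$founders_per_generation >= 0,
            cfg$n_initial_marked >= 1,
            cfg$recruitment_prob >= 0, cfg$recruitment_prob <= 1,
            cfg$brood_prob >= 0, cfg$brood_prob <= 1,
            cfg$mate_fidelity >= 0, cfg$mate_fidelity <= 1,
            cfg$mean_breeding_years > 0, cfg$tenure_ratio > 0,
            cfg$success_ratio > 0)
  class(cfg) <- "fitqg_pedsim_config"
  cfg
}

#' Simulate a multi-generation study pedigree
#'
#' Runs the breeding dynamics described in [pedigree_sim_config()]. Only
#' marked individuals (the initial adults and all locally hatched
#' fledglings) receive pedigree records; immigrant parents appear as missing
#' dam/sire fields. The `cohort` column holds the hatch year (an integer
#' year index running across generations), which downstream trait simulators
#' use for hatch-year effects.
#'
#' @param cfg a [pedigree_sim_config()].
#' @return A [pedigree()] object with a `sim_state` attribute that allows
#'   [extend_pedigree()] to continue the dynamics seamlessly.
#' @examples
#' ped <- simulate_pedigree(pedigree_sim_config(seed = 1))
#' summary(ped)
#' @export
simulate_pedigree <- function(cfg = pedigree_sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  state <- ped_sim_init(cfg)
  state <- ped_sim_run(state, cfg, cfg$n_generations - 1L)
  ped_sim_finish(state, cfg)
}

ped_sim_init <- function(cfg) {
  n0 <- cfg$n_initial_marked
  recs <- data.frame(id = sprintf("F%04d", seq_len(n0)),
                     dam = NA_character_, sire = NA_character_,
                     cohort = 1L, stringsAsFactors = FALSE)
  list(records = recs,
       pool_ids = recs$id,          # marked members of the current pool
       pool_sex = sample(c("F", "M"), n0, replace = TRUE),
       year = 1L, counter = n0)
}

## advance the breeding dynamics by n_gen generations
ped_sim_run <- function(state, cfg, n_gen) {
  if (n_gen < 1) return(state)
  m_local <- cfg$mean_breeding_years * sqrt(cfg$tenure_ratio)
  m_imm <- cfg$mean_breeding_years / sqrt(cfg$tenure_ratio)
  adv <- sqrt(cfg$success_ratio)
  for (g in seq_len(n_gen)) {
    n_loc <- length(state$pool_ids)
    n_imm <- cfg$founders_per_generation
    if (n_loc + n_imm < 2)
      stop("breeding pool went extinct; increase founders_per_generation ",
           "or recruitment_prob")
    ## breeder table: marked locals then unmarked immigrants
    marked <- c(rep(TRUE, n_loc), rep(FALSE, n_imm))
    sex <- c(state$pool_sex, sample(c("F", "M"), n_imm, replace = TRUE))
    ids <- c(state$pool_ids, rep(NA_character_, n_imm))
    tenure <- 1L + stats::rpois(n_loc + n_imm,
                                c(rep(m_local - 1, n_loc),
                                  rep(m_imm - 1, n_imm)))
    new_dam <- character(0); new_sire <- character(0); new_year <- integer(0)
    pair_f <- integer(0); pair_m <- integer(0)    # retained pairs
    for (y in seq_len(cfg$years_per_generation)) {
      act <- tenure >= y
      ## retain last year's pairs where both members remain active
      if (length(pair_f)) {
        keep <- act[pair_f] & act[pair_m] &
          stats::runif(length(pair_f)) < cfg$mate_fidelity
        pair_f <- pair_f[keep]; pair_m <- pair_m[keep]
      }
      fem <- setdiff(which(act & sex == "F"), pair_f)
      mal <- setdiff(which(act & sex == "M"), pair_m)
      np <- min(length(fem), length(mal))
      if (np > 0) {
        pair_f <- c(pair_f, sample(fem)[seq_len(np)])
        pair_m <- c(pair_m, sample(mal)[seq_len(np)])
      }
      if (!length(pair_f)) next
      p_pair <- pmin(1, cfg$brood_prob * adv^(marked[pair_f] + marked[pair_m]))
      nf <- stats::rbinom(length(pair_f), 3L, p_pair)
      keep <- nf > 0
      new_dam <- c(new_dam, rep(ids[pair_f[keep]], nf[keep]))
      new_sire <- c(new_sire, rep(ids[pair_m[keep]], nf[keep]))
      new_year <- c(new_year, rep(state$year + y, sum(nf)))
    }
    n_off <- length(new_dam)
    if (n_off == 0)
      stop("no offspring produced; increase brood_prob or pool size")
    off_ids <- sprintf("I%05d", state$counter + seq_len(n_off))
    state$counter <- state$counter + n_off
    state$records <- rbind(state$records,
                           data.frame(id = off_ids, dam = new_dam,
                                      sire = new_sire, cohort = new_year,
                                      stringsAsFactors = FALSE))
    recruited <- stats::runif(n_off) < cfg$recruitment_prob
    state$pool_ids <- off_ids[recruited]
    state$pool_sex <- sample(c("F", "M"), sum(recruited), replace = TRUE)
    state$year <- state$year + cfg$years_per_generation
  }
  state
}

ped_sim_finish <- function(state, cfg) {
  r <- state$records
  ped <- pedigree(id = r$id, dam = r$dam, sire = r$sire, cohort = r$cohort)
  attr(ped, "sim_state") <- state[c("pool_ids", "pool_sex", "year", "counter")]
  ped
}

#' Continue the breeding dynamics of a pedigree for extra generations
#'
#' Grows a pedigree by `extra_generations` further generations of the same
#' breeding dynamics, starting from its current breeding pool plus the usual
#' immigrant influx. The returned pedigree strictly contains the input
#' records. Used by the power study to ask how detection of small additive
#' genetic variances improves when a study is continued.
#'
#' If the pedigree was produced by [simulate_pedigree()] the simulator state
#' is resumed exactly; otherwise a breeding pool is reconstructed by
#' recruiting (at `cfg$recruitment_prob`) from the most recent cohorts.
#'
#' @param ped a [pedigree()] object.
#' @param extra_generations number of additional generations (0 returns the
#'   input unchanged).
#' @param cfg a [pedigree_sim_config()] governing the continued dynamics.
#' @return A [pedigree()] object.
#' @export
extend_pedigree <- function(ped, extra_generations, cfg = pedigree_sim_config()) {
  extra_generations <- as.integer(extra_generations)
  if (extra_generations < 0) stop("extra_generations must be >= 0")
  if (extra_generations == 0) return(ped)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  state <- attr(ped, "sim_state")
  if (is.null(state)) {
    yr <- max(ped$cohort, na.rm = TRUE)
    recent <- ped$id[!is.na(ped$cohort) &
                     ped$cohort > yr - cfg$years_per_generation]
    recruited <- recent[stats::runif(length(recent)) < cfg$recruitment_prob]
    state <- list(pool_ids = recruited,
                  pool_sex = sample(c("F", "M"), length(recruited),
                                    replace = TRUE),
                  year = yr, counter = nrow(ped))
  }
  state$records <- as.data.frame(ped)[, c("id", "dam", "sire", "cohort")]
  state <- ped_sim_run(state, cfg, extra_generations)
  ped_sim_finish(state, cfg)
}
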