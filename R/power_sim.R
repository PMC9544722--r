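#' Configuration for the simulation-based power study
#'
#' The power study asks: given a pedigree and the zero-inflated fitness
#' distribution of the study population, how well can the animal model
#' recover a known, simulated latent additive genetic variance, and how
#' often is it detected (lower 95% HPD bound above `detection_threshold`)?
#' For every value in `va_grid` and every replicate, breeding values are
#' gene dropped, a lifetime-fitness table is simulated from the model's own
#' generative process (the zero-inflation latent includes the unit residual
#' the fitted model fixes), the zero-inflated Poisson animal model is
#' refitted, and the posterior of the target component's additive genetic
#' variance is summarized.
#'
#' @param pedigree a [pedigree()] object, or a [pedigree_sim_config()] from
#'   which one is generated (seeded from `seed`).
#' @param component which component carries the simulated variance:
#'   `"zi"` (zero-inflation) or `"pois"` (Poisson).
#' @param va_grid latent additive genetic variances to simulate. For the
#'   Poisson component a target evolvability `IA` maps to a latent
#'   variance via `va = log(1 + IA)` (the log-link identity
#'   `IA = exp(va) - 1`); see [ia_to_latent_va()].
#' @param n_replicates simulate-and-refit replicates per grid value.
#' @param detection_threshold detection rule: lower 95% HPD bound of the
#'   latent variance exceeds this value.
#' @param extra_generations continue the pedigree by this many generations
#'   (the extended-study scenario) before simulating.
#' @param mcmc an [mcmc_config()] used for every refit.
#' @param min_ess replicates whose target-parameter ESS falls below this are
#'   flagged and excluded from the aggregates.
#' @param trait_overrides named list passed on to [tern_lifetime_params()]
#'   (non-simulated quantities stay at their calibrated defaults).
#' @param ped_config [pedigree_sim_config()] used when `pedigree` is a
#'   config and for `extend_pedigree()`.
#' @param seed master seed; all replicate seeds derive from it.
#' @export
power_study_config <- function(pedigree = pedigree_sim_config(),
                               component = c("zi", "pois"),
                               va_grid = c(0, 0.01, 0.05, 0.10),
                               n_replicates = 100,
                               detection_threshold = 1e-4,
                               extra_generations = 0,
                               mcmc = mcmc_config(),
                               min_ess = 50,
                               trait_overrides = list(),
                               ped_config = pedigree_sim_config(),
                               seed = 1) {
  component <- match.arg(component)
  stopifnot(all(va_grid >= 0), detection_threshold > 0, n_replicates >= 1)
  out <- list(pedigree = pedigree, component = component, va_grid = va_grid,
              n_replicates = as.integer(n_replicates),
              detection_threshold = detection_threshold,
              extra_generations = as.integer(extra_generations),
              mcmc = mcmc, min_ess = min_ess,
              trait_overrides = trait_overrides, ped_config = ped_config,
              seed = seed)
  class(out) <- "fitqg_power_config"
  out
}

#' Map a target evolvability to a latent-scale additive variance
#'
#' Under the log link the data-scale evolvability of a latent additive
#' variance `va` is `IA = exp(va) - 1` (mean-standardized variance of a
#' log-normal), so a target evolvability corresponds to
#' `va = log(1 + IA)`.
#'
#' @param ia target evolvability (mean-standardized additive variance).
#' @export
ia_to_latent_va <- function(ia) log(1 + ia)

#' Run the simulation-based power study
#'
#' @param cfg a [power_study_config()].
#' @param verbose print one line per replicate.
#' @return An object of class `fitqg_power_result`: `replicates` (per-run
#'   posterior mode, HPD bounds, detection flag, ESS, convergence flag) and
#'   `aggregate` (per grid value: mean posterior mode, mean HPD bounds,
#'   detection count, replicates used).
#' @export
run_power_study <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "fitqg_power_config"))
  set.seed(cfg$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(cfg$va_grid) * cfg$n_replicates * 2),
                  ncol = 2)
  ped <- if (inherits(cfg$pedigree, "fitqg_pedigree")) cfg$pedigree
         else simulate_pedigree(cfg$pedigree)
  if (cfg$extra_generations > 0)
    ped <- extend_pedigree(ped, cfg$extra_generations, cfg$ped_config)

  target <- if (cfg$component == "zi") "zi.v_animal" else "pois.v_animal"
  spec <- spec_lifetime_zip()
  rows <- list()
  k <- 0L
  for (va in cfg$va_grid) {
    for (rep in seq_len(cfg$n_replicates)) {
      k <- k + 1L
      ov <- cfg$trait_overrides
      ov$seed <- seeds[k, 1]
      ov$v_resid_zi <- 1            # match the fitted model's zi latent
      ov[[if (cfg$component == "zi") "va_zi" else "va_pois"]] <- va
      pars <- do.call(tern_lifetime_params, ov)
      lt <- simulate_lifetime(ped, pars, standardize = FALSE)
      mc <- cfg$mcmc
      mc$seed <- seeds[k, 2]
      fit <- suppressWarnings(fit_animal_model(lt, ped, spec, mc))
      s <- summarize_posterior(fit$draws[, target])
      ess <- fit$diagnostics[target, "ess"]
      ok <- is.na(ess) || ess >= cfg$min_ess
      rows[[k]] <- data.frame(va = va, replicate = rep, mode = s$mode,
                              hpd_low = s$hpd_low, hpd_high = s$hpd_high,
                              detected = s$hpd_low > cfg$detection_threshold,
                              ess = ess, converged = ok)
      if (verbose)
        message(sprintf("va %.3f rep %d: mode %.4f [%.4f, %.4f]%s", va, rep,
                        s$mode, s$hpd_low, s$hpd_high,
                        if (ok) "" else " (excluded)"))
    }
  }
  repl <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(repl[repl$converged, ],
                                     repl$va[repl$converged]), function(d) {
    data.frame(va = d$va[1], n_used = nrow(d),
               mean_mode = mean(d$mode), mean_hpd_low = mean(d$hpd_low),
               mean_hpd_high = mean(d$hpd_high),
               detection_count = sum(d$detected))
  }))
  rownames(agg) <- NULL
  out <- list(replicates = repl, aggregate = agg, config = cfg,
              n_pedigree = nrow(ped))
  class(out) <- "fitqg_power_result"
  out
}

#' @export
print.fitqg_power_result <- function(x, ...) {
  cat("Power study (", x$config$component, " component, pedigree n = ",
      x$n_pedigree, ", ", x$config$n_replicates, " replicates)\n", sep = "")
  agg <- x$aggregate
  agg$detection <- sprintf("%d/%d", agg$detection_count, agg$n_used)
  print(agg)
  invisible(x)
}

#' Write power-study tables as delimited text
#' @param x a `fitqg_power_result`.
#' @param dir output directory (created if needed).
#' @export
write_power_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$replicates, file.path(dir, "replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$aggregate, file.path(dir, "aggregate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
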