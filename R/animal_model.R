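#' Model specification for a fitness animal model
#'
#' Describes the response, error family, fixed effects and random terms of
#' a univariate animal model. Three families are supported for fitness
#' data, plus a Gaussian family used for internal validation against
#' restricted-likelihood fits:
#' \describe{
#'   \item{`zipoisson`}{zero-inflated overdispersed Poisson: a logit-link
#'     zero-inflation component whose latent residual variance is fixed to
#'     1 (overdispersion of a structural-zero process is unidentifiable,
#'     so it is pinned, as is conventional for zero-inflated animal
#'     models) and a log-link Poisson component whose
#'     residual/overdispersion variance is estimated. Random terms apply
#'     to both components (independently) unless restricted via
#'     `applies`.}
#'   \item{`poisson`}{log link, overdispersion residual estimated.}
#'   \item{`binary`}{logit link, residual variance fixed to 1.}
#'   \item{`gaussian`}{identity link, residual estimated.}
#' }
#'
#' @param family error family (see Details).
#' @param response name of the response column in the phenotype table.
#' @param fixed right-hand-side formula of fixed effects (intercept always
#'   included), e.g. `~ status` or `~ I(age - 1)`; `NULL` for intercept
#'   only.
#' @param random named list of random terms created by [ranef_pedigree()]
#'   or [ranef_iid()]. Exactly one pedigree-structured term is required.
#' @return A list of class `fitqg_model_spec`.
#' @export
model_spec <- function(family = c("zipoisson", "poisson", "binary", "gaussian"),
                       response, fixed = NULL, random = list()) {
  family <- match.arg(family)
  stopifnot(is.character(response), length(response) == 1)
  if (!is.null(fixed)) stopifnot(inherits(fixed, "formula"))
  if (is.null(names(random)) && length(random))
    stop("random terms must be named")
  n_ped <- sum(vapply(random, function(t) t$type == "pedigree", TRUE))
  if (n_ped != 1)
    stop("exactly one pedigree-structured random term is required")
  out <- list(family = family, response = response, fixed = fixed,
              random = random)
  class(out) <- "fitqg_model_spec"
  out
}

#' Random-term descriptors
#'
#' `ranef_pedigree()` declares the additive genetic term: individual
#' identity linked to the pedigree through the inverse additive relationship
#' matrix. `ranef_iid()` declares an independent (identity-covariance) term
#' over the levels of a column, e.g. hatch-year, observation year, or
#' individual identity for permanent-environment effects.
#'
#' @param column column of the phenotype table holding the grouping factor
#'   (for the pedigree term, the individual id; default `"id"`).
#' @param applies for zero-inflated models, which components the term
#'   enters: `"both"` (default), `"zi"` or `"pois"`.
#' @export
ranef_pedigree <- function(column = "id", applies = "both") {
  list(type = "pedigree", column = column, applies = applies)
}

#' @rdname ranef_pedigree
#' @export
ranef_iid <- function(column, applies = "both") {
  list(type = "iid", column = column, applies = applies)
}

#' Canned model specifications for the three fitness analyses
#'
#' `spec_lifetime_zip()`: zero-inflated Poisson model of lifetime fitness
#' with alive/dead status as fixed effect and additive genetic plus
#' hatch-year random intercepts on both components. `spec_annual_ars()`:
#' Poisson model of annual reproductive success with a linear age effect
#' and additive genetic, permanent-environment and year random intercepts.
#' `spec_annual_aas()`: the binary analogue for adult annual survival.
#'
#' @export
spec_lifetime_zip <- function() {
  model_spec("zipoisson", response = "fitness", fixed = ~ status,
             random = list(animal = ranef_pedigree("id"),
                           cohort = ranef_iid("hatch_year")))
}

#' @rdname spec_lifetime_zip
#' @export
spec_annual_ars <- function() {
  model_spec("poisson", response = "ars", fixed = ~ I(age - 1),
             random = list(animal = ranef_pedigree("id"),
                           pe = ranef_iid("id"),
                           year = ranef_iid("year")))
}

#' @rdname spec_lifetime_zip
#' @export
spec_annual_aas <- function() {
  model_spec("binary", response = "aas", fixed = ~ I(age - 1),
             random = list(animal = ranef_pedigree("id"),
                           pe = ranef_iid("id"),
                           year = ranef_iid("year")))
}

#' MCMC configuration
#'
#' Chain length, burn-in (the study convention is a minimum of 5000
#' iterations), thinning, seed, the effective-sample-size target below
#' which a convergence warning is emitted, and the prior settings.
#'
#' Random-term variances get the parameter-expanded prior family: a half-t
#' with `nu` degrees of freedom (default 1, i.e. half-Cauchy) and scale
#' `t_scale` on the standard-deviation scale, the distribution induced by a
#' 1-df scaled Gaussian working parameter; it is heavy tailed yet finite at
#' zero, which matters for near-boundary variance components. Estimated
#' residual variances get a weakly informative inverse-Wishart
#' (`resid_nu`, `resid_V`); fixed effects get diffuse Gaussians with
#' variance `beta_V`.
#'
#' @param n_iter total iterations.
#' @param burn_in discarded iterations (adaptation of the latent-update
#'   and variance-update step sizes happens only here).
#' @param thin retain every `thin`-th draw.
#' @param seed integer seed.
#' @param target_min_ess warn if any parameter's ESS falls below this.
#' @param var_substeps collapsed variance-update proposals per sweep;
#'   more substeps improve variance-component mixing per iteration at the
#'   cost of one sparse factorization each.
#' @param prior named list overriding any of `nu`, `t_scale`,
#'   `resid_nu`, `resid_V`, `beta_V`.
#' @export
mcmc_config <- function(n_iter = 15000, burn_in = 5000, thin = 10,
                        seed = NULL, target_min_ess = 1000,
                        var_substeps = 2, prior = list()) {
  pr <- list(nu = 1, t_scale = 1, resid_nu = 0.002, resid_V = 1,
             beta_V = 1e8)
  pr[names(prior)] <- prior
  cfg <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin), seed = seed,
              target_min_ess = target_min_ess,
              var_substeps = as.integer(var_substeps), prior = pr)
  stopifnot(cfg$n_iter > cfg$burn_in, cfg$burn_in >= 0, cfg$thin >= 1,
            cfg$var_substeps >= 1)
  class(cfg) <- "fitqg_mcmc_config"
  cfg
}

#' Fit a Bayesian animal model by MCMC
#'
#' The sampler alternates three blocks with the correct stationary
#' distribution:
#' \enumerate{
#'   \item element-wise random-walk Metropolis updates of the non-Gaussian
#'     latent values (conditionally independent given the location effects,
#'     carried out as a single vectorized step);
#'   \item a collapsed Metropolis update of all variance components from
#'     their marginal posterior given the latent field, with every location
#'     effect (fixed effects, breeding values, other random effects)
#'     integrated out analytically through a sparse Cholesky factorization
#'     of the mixed-model equations -- collapsing removes the notorious
#'     ridge between a variance component and its effect vector that makes
#'     single-record animal models mix slowly;
#'   \item a joint Gaussian draw of all location effects from their full
#'     conditional, reusing the accepted factorization, with the additive
#'     genetic effects structured by the sparse inverse additive
#'     relationship matrix.
#' }
#' Proposal step sizes (latent updates and log-variance walk) are adapted
#' during burn-in only (target acceptance 0.44 and 0.30).
#'
#' For the zero-inflated Poisson family the structural-zero indicators are
#' imputed by data augmentation each iteration; positive counts are never
#' structural zeros, and zero counts are structural with posterior odds
#' `p / ((1-p) exp(-lambda))`.
#'
#' @param data phenotype table (a lifetime or annual table, or any data
#'   frame with the response, covariates and an `id` column).
#' @param ped a [pedigree()] containing every phenotyped individual.
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_config()].
#' @param verbose print progress.
#' @return An object of class `fitqg_fit`: retained draws (variance
#'   components on the latent scale, fixed effects), per-parameter
#'   diagnostics, Metropolis acceptance rates, and the layout needed by
#'   [transform_posterior()].
#' @export
fit_animal_model <- function(data, ped, spec, mcmc = mcmc_config(),
                             verbose = FALSE) {
  stopifnot(inherits(spec, "fitqg_model_spec"),
            inherits(mcmc, "fitqg_mcmc_config"))
  if (!spec$response %in% names(data))
    stop("response column '", spec$response, "' not found")
  if (!all(data$id %in% ped$id))
    stop("phenotyped individual(s) missing from pedigree: ",
         paste(utils::head(setdiff(data$id, ped$id), 5), collapse = ", "))
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  ## canonical internal ordering: results do not depend on input row order
  ord <- order(match(data$id, ped$id),
               if ("year" %in% names(data)) data$year else seq_len(nrow(data)))
  data <- data[ord, , drop = FALSE]
  y <- data[[spec$response]]
  n <- length(y)
  if (spec$family %in% c("zipoisson", "poisson") && any(y < 0))
    stop("count response must be non-negative")
  if (spec$family == "binary" && !all(y %in% 0:1))
    stop("binary response must be 0/1")

  Ainv <- additive_relationship(ped, what = "Ainv")$Ainv
  X <- if (is.null(spec$fixed)) matrix(1, n, 1,
                                       dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(spec$fixed, data = data)
  if (nrow(X) != n) stop("missing values in fixed-effect covariates")

  components <- if (spec$family == "zipoisson") c("zi", "pois") else "single"
  comps <- lapply(components, function(cn) {
    build_component(cn, spec, data, ped, Ainv, X, y, mcmc)
  })
  names(comps) <- components

  n_retain <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  draw_names <- unlist(lapply(comps, function(cp) cp$par_names))
  draws <- matrix(NA_real_, n_retain, length(draw_names),
                  dimnames = list(NULL, draw_names))
  z <- if (spec$family == "zipoisson") as.integer(y == 0) else NULL

  r <- 0L
  for (it in seq_len(mcmc$n_iter)) {
    adapt <- it <= mcmc$burn_in
    if (spec$family == "zipoisson") {
      z <- update_zip_indicator(y, comps$zi$l, comps$pois$l)
      comps$zi$obs_data <- z
      comps$pois$observed <- z == 0L
    }
    for (cn in components) {
      comps[[cn]] <- gibbs_sweep(comps[[cn]], mcmc$prior, adapt)
    }
    if (!adapt && (it - mcmc$burn_in) %% mcmc$thin == 0) {
      r <- r + 1L
      draws[r, ] <- unlist(lapply(comps, collect_params))
    }
    if (verbose && it %% 1000 == 0)
      message("iteration ", it, "/", mcmc$n_iter)
  }

  if (n_retain >= 100) {
    diag <- chain_diagnostics(draws)
    low <- rownames(diag)[diag$ess < mcmc$target_min_ess & !diag$degenerate]
    if (length(low))
      warning("effective sample size below ", mcmc$target_min_ess, " for: ",
              paste(sprintf("%s (%.0f)", low, diag[low, "ess"]),
                    collapse = ", "))
  } else {
    diag <- data.frame(ess = rep(NA_real_, ncol(draws)),
                       autocorr_lag1 = NA_real_, heidel_pass = NA,
                       degenerate = NA, row.names = colnames(draws))
  }
  layout <- lapply(comps, function(cp) cp$layout)
  out <- list(draws = draws, family = spec$family, layout = layout,
              diagnostics = diag,
              accept_rate = vapply(comps, function(cp) cp$accept_rate, 0),
              spec = spec, mcmc = mcmc, n_obs = n,
              ped_ids = ped$id)
  class(out) <- "fitqg_fit"
  out
}

## set up the state of one model component
build_component <- function(cn, spec, data, ped, Ainv, X, y, mcmc) {
  n <- nrow(data)
  link <- if (cn == "zi" || spec$family == "binary") "logit"
          else if (spec$family == "gaussian") "identity" else "log"
  resid_estimated <- link %in% c("log", "identity")
  terms <- spec$random
  if (spec$family == "zipoisson")
    terms <- terms[vapply(terms, function(t)
      t$applies %in% c("both", cn), TRUE)]

  Zs <- list(); Ginvs <- list()
  for (nm in names(terms)) {
    tm <- terms[[nm]]
    col <- data[[tm$column]]
    if (is.null(col)) stop("random-term column '", tm$column, "' not found")
    if (tm$type == "pedigree") {
      lev <- ped$id
      Ginvs[[nm]] <- Ainv
    } else {
      lev <- sort(unique(col))
      Ginvs[[nm]] <- Matrix::Diagonal(length(lev), x = rep(1, length(lev)))
    }
    j <- match(col, lev)
    Zs[[nm]] <- Matrix::sparseMatrix(i = seq_len(n), j = j,
                                     x = 1, dims = c(n, length(lev)))
  }
  M <- methods::as(do.call(cbind, c(list(Matrix::Matrix(X, sparse = TRUE)),
                                    Zs)), "CsparseMatrix")
  p <- ncol(X)
  q <- vapply(Zs, ncol, 0L)
  blk <- split(seq_len(p + sum(q)),
               rep(c("beta", names(terms)), c(p, q)))
  Tm <- Matrix::crossprod(M)

  prefix <- if (cn == "single") "" else paste0(cn, ".")
  vnames <- paste0(prefix, "v_", names(terms))
  par_names <- c(paste0(prefix, colnames(X)), vnames,
                 if (resid_estimated) paste0(prefix, "v_resid"))
  ped_term <- names(terms)[vapply(terms, function(t)
    t$type == "pedigree", TRUE)]
  fixed_cols <- paste0(prefix, colnames(X))
  names(fixed_cols) <- colnames(X)
  layout <- list(intercept = paste0(prefix, "(Intercept)"),
                 fixed = fixed_cols[colnames(X) != "(Intercept)"],
                 va = paste0(prefix, "v_", ped_term),
                 other = c(setdiff(vnames, paste0(prefix, "v_", ped_term)),
                           if (resid_estimated) paste0(prefix, "v_resid")),
                 resid_fixed = if (resid_estimated) 0 else 1)

  ## initial latent values
  obs_data <- if (cn == "zi") as.integer(y == 0) else y
  l <- switch(link,
              log = log(pmax(y, 0.5)),
              logit = stats::qlogis(0.15 + 0.7 * obs_data),
              identity = as.numeric(y))
  ## fixed-pattern template for the mixed-model equations
  ## C = T/ve (or T_omega) + beta prior + sum_k Ginv_k / v_k, assembled by
  ## direct writes into the x slot: S4 sparse arithmetic per iteration
  ## costs more than the factorization itself
  N <- p + sum(q)
  native_key <- function(m, off = 0L) {
    m <- methods::as(m, "CsparseMatrix")
    (rep.int(seq_len(ncol(m)), diff(m@p)) - 1 + off) * N + (m@i + off)
  }
  offs <- c(0L, cumsum(q)[-length(q)]) + p
  names(offs) <- names(terms)
  gx <- list(); gkey <- list()
  for (nm in names(terms)) {
    G <- methods::as(Ginvs[[nm]], "CsparseMatrix")   # upper-symmetric
    gx[[nm]] <- G@x
    gkey[[nm]] <- native_key(G, offs[nm])
  }
  tkey <- native_key(Tm)
  bkey <- (seq_len(p) - 1) * N + (seq_len(p) - 1)
  allkey <- c(tkey, bkey, unlist(gkey))
  C0 <- Matrix::sparseMatrix(i = (allkey %% N) + 1,
                             j = (allkey %/% N) + 1,
                             x = 1, dims = c(N, N), symmetric = TRUE)
  ckey <- native_key(C0)
  maps <- list(t = match(tkey, ckey), beta = match(bkey, ckey),
               g = lapply(gkey, match, ckey))

  cp <- list(name = cn, link = link, y = y, obs_data = obs_data,
             observed = rep(TRUE, n), resid_estimated = resid_estimated,
             M = M, Mt = Matrix::t(M), Tm = Tm, blk = blk, Ginvs = Ginvs,
             terms = terms, p = p, q = q,
             C0 = C0, maps = maps, gx = gx,
             theta = numeric(p + sum(q)),
             v = stats::setNames(rep(0.1, length(terms)), names(terms)),
             substeps = mcmc$var_substeps,
             ve = if (resid_estimated) 0.5 else 1,
             l = l, m = rep(0, n), chol = NULL, logdet = NULL,
             step = 0.8, step_v = 0.6,
             vs_chol = NULL,                  # adapted proposal factor
             v_hist = matrix(NA_real_, mcmc$burn_in,
                             length(terms) + resid_estimated),
             v_hist_n = 0L,
             acc = 0, try = 0, accept_rate = NA_real_,
             par_names = par_names, layout = layout)
  st <- variance_state(cp, mcmc$prior, cp$v, cp$ve)
  if (is.null(st)) stop("initial mixed-model equations not positive definite")
  cp$chol <- st$chol; cp$logdet <- st$logdet
  cp
}

## write the mixed-model-equation values into the fixed-pattern template
assemble_C <- function(cp, v, tx, eps) {
  xs <- numeric(length(cp$C0@x))
  xs[cp$maps$t] <- tx
  xs[cp$maps$beta] <- xs[cp$maps$beta] + eps
  for (nm in names(cp$gx))
    xs[cp$maps$g[[nm]]] <- xs[cp$maps$g[[nm]]] + cp$gx[[nm]] / v[nm]
  C <- cp$C0
  C@x <- xs
  C
}

## factorize the mixed-model equations for a given set of variances;
## returns NULL if numerically non-positive-definite (proposal rejected)
variance_state <- function(cp, prior, v, ve) {
  C <- assemble_C(cp, v, cp$Tm@x / ve, 1 / prior$beta_V)
  ch <- tryCatch({
    if (is.null(cp$chol)) Matrix::Cholesky(C, LDL = FALSE)
    else Matrix::update(cp$chol, C)
  }, error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ## determinant() of a CHMfactor returns log det of the Cholesky factor
  ld <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                           sqrt = TRUE)$modulus)
  list(chol = ch, logdet = ld)
}

## log marginal likelihood of the latent field l with all location effects
## integrated out: l ~ N(0, M G M' + ve I), evaluated via the Woodbury
## identity on the sparse mixed-model equations. The quadratic form
## b'C^{-1}b is computed as ||L^{-1} P b||^2 (two triangular passes).
marginal_loglik <- function(cp, st, v, ve, b, ll2) {
  n <- length(cp$l)
  t1 <- as.numeric(Matrix::solve(st$chol,
                                 Matrix::solve(st$chol, b / ve,
                                               system = "P"),
                                 system = "L"))
  quad <- ll2 / ve - sum(t1^2)
  -0.5 * (n * log(ve) + sum(cp$q * log(v)) + st$logdet + quad)
}

## log prior densities: half-t(nu, t_scale) on the sd scale for term
## variances, weak inverse-Wishart for estimated residuals
log_prior_v <- function(v, prior) {
  sum(stats::dt(sqrt(v) / prior$t_scale, df = prior$nu, log = TRUE) -
        log(prior$t_scale) - 0.5 * log(v))
}

log_prior_ve <- function(ve, prior) {
  a <- prior$resid_nu / 2
  b <- prior$resid_nu * prior$resid_V / 2
  -(a + 1) * log(ve) - b / ve
}

## one sweep of a component. Logit links use the Polya-Gamma blocked
## sampler; log/identity links use Metropolis latent updates with a
## collapsed variance step given the latent field.
gibbs_sweep <- function(cp, prior, adapt) {
  if (cp$link == "logit") return(sweep_logit_pg(cp, prior, adapt))
  n <- length(cp$l)
  ## 1. latent values: vectorized element-wise random-walk Metropolis,
  ##    repeated a few times per sweep; unobserved elements (structural
  ##    zeros) are refreshed from their prior.
  if (cp$link == "log") {
    for (rep in 1:3) {
      prop <- cp$l + stats::rnorm(n, 0, cp$step)
      ## Gaussian prior ratio written out (normalizing constants cancel)
      logr <- loglik_vec(cp, prop) - loglik_vec(cp, cp$l) +
        ((cp$l - cp$m)^2 - (prop - cp$m)^2) / (2 * cp$ve)
      acc <- log(stats::runif(n)) < logr
      upd <- cp$observed & acc
      cp$l[upd] <- prop[upd]
    }
    if (any(!cp$observed))
      cp$l[!cp$observed] <- stats::rnorm(sum(!cp$observed),
                                         cp$m[!cp$observed], sqrt(cp$ve))
    if (adapt) {
      rate <- mean(acc[cp$observed])
      cp$step <- cp$step * exp(0.6 * (rate - 0.44))
    } else {
      cp$acc <- cp$acc + sum(acc[cp$observed])
      cp$try <- cp$try + sum(cp$observed)
      cp$accept_rate <- cp$acc / max(cp$try, 1)
    }
  } else {
    cp$l <- as.numeric(cp$y)
  }
  b <- as.numeric(cp$Mt %*% cp$l)
  ll2 <- sum(cp$l^2)

  ## 2. collapsed variance update: joint random-walk on the log variances
  ##    (and log residual variance where estimated), location effects
  ##    marginalized out, repeated a few times per latent refresh. The
  ##    proposal covariance is adapted during burn-in (Haario-style)
  ##    because variance components and the residual are strongly
  ##    anticorrelated and an isotropic walk crawls on the ridge.
  K <- length(cp$v)
  nd <- K + cp$resid_estimated
  lb <- log(1e-10)
  st_cur <- list(chol = cp$chol, logdet = cp$logdet)
  ml_cur <- marginal_loglik(cp, st_cur, cp$v, cp$ve, b, ll2) +
    log_prior_v(cp$v, prior) + sum(log(cp$v)) +
    if (cp$resid_estimated) log_prior_ve(cp$ve, prior) + log(cp$ve) else 0
  for (sub in seq_len(cp$substeps)) {
    cur <- c(log(pmax(cp$v, 1e-12)), if (cp$resid_estimated) log(cp$ve))
    eps <- if (is.null(cp$vs_chol)) stats::rnorm(nd, 0, cp$step_v) else
      cp$step_v * as.numeric(cp$vs_chol %*% stats::rnorm(nd))
    prop <- cur + eps
    prop <- ifelse(prop < lb, 2 * lb - prop, prop)  # reflect at the floor
    v_new <- stats::setNames(exp(prop[seq_len(K)]), names(cp$v))
    ve_new <- if (cp$resid_estimated) exp(prop[K + 1]) else cp$ve
    st_new <- variance_state(cp, prior, v_new, ve_new)
    accepted <- FALSE
    if (!is.null(st_new)) {
      ml_new <- marginal_loglik(cp, st_new, v_new, ve_new, b, ll2) +
        log_prior_v(v_new, prior) + sum(log(v_new)) +
        if (cp$resid_estimated) log_prior_ve(ve_new, prior) + log(ve_new)
        else 0
      if (is.finite(ml_new) && log(stats::runif(1)) < ml_new - ml_cur) {
        cp$v <- v_new; cp$ve <- ve_new
        cp$chol <- st_new$chol; cp$logdet <- st_new$logdet
        ml_cur <- ml_new
        accepted <- TRUE
      }
    }
    if (adapt) cp$step_v <- cp$step_v * exp(0.25 * (accepted - 0.3))
  }
  if (adapt) {
    cp$v_hist_n <- cp$v_hist_n + 1L
    cp$v_hist[cp$v_hist_n, ] <- c(log(pmax(cp$v, 1e-12)),
                                  if (cp$resid_estimated) log(cp$ve))
    if (cp$v_hist_n >= 250 && cp$v_hist_n %% 100 == 0) {
      S <- stats::cov(cp$v_hist[seq_len(cp$v_hist_n), , drop = FALSE]) +
        diag(1e-4, nd)
      first <- is.null(cp$vs_chol)
      cp$vs_chol <- t(chol(S)) * (2.38 / sqrt(nd))
      if (first) cp$step_v <- 1
    }
  }

  ## 3. joint conditional draw of fixed effects and random-effect vectors
  mu <- as.numeric(Matrix::solve(cp$chol, b / cp$ve, system = "A"))
  w <- stats::rnorm(length(mu))
  dev <- Matrix::solve(cp$chol, w, system = "Lt")
  dev <- as.numeric(Matrix::solve(cp$chol, dev, system = "Pt"))
  cp$theta <- mu + dev
  cp$m <- as.numeric(cp$M %*% cp$theta)
  cp
}

## Polya-Gamma blocked sweep for Bernoulli-logit components (zero-inflation
## indicator, binary survival). Given the PG weights omega, every Gaussian
## quantity -- latent values, the unit residual, fixed and random effects --
## is marginalized analytically, so the collapsed variance update conditions
## only on (data, omega). This removes the slow coupling through the latent
## field that throttles variance mixing when the Bernoulli data are weakly
## informative. Blocks: omega | l; variances | data, omega (marginal
## Metropolis with adaptive proposal); locations | variances, omega; latent
## values | locations, omega.
sweep_logit_pg <- function(cp, prior, adapt) {
  n <- length(cp$l)
  kappa <- cp$obs_data - 0.5
  ## 1. PG weights
  omega <- .rpg_vec(cp$l)
  ## working weights of the marginal working-response model:
  ## kappa/omega ~ N(m, 1/omega + ve), both terms bounded as omega -> 0
  W <- omega / (1 + omega * cp$ve)
  Wr <- kappa / (1 + omega * cp$ve)
  M2 <- cp$M
  M2@x <- M2@x * sqrt(W)[M2@i + 1L]
  Tw <- Matrix::crossprod(M2)
  if (length(Tw@x) != length(cp$maps$t))
    stop("internal error: working crossprod pattern changed")
  b <- as.numeric(Matrix::crossprod(cp$M, Wr))

  marg <- function(st, v) {
    t1 <- as.numeric(Matrix::solve(st$chol,
                                   Matrix::solve(st$chol, b, system = "P"),
                                   system = "L"))
    -0.5 * (sum(cp$q * log(v)) + st$logdet - sum(t1^2))
  }
  st_cur <- variance_state_pg(cp, prior, cp$v, Tw)
  if (is.null(st_cur)) stop("mixed-model equations not positive definite")
  ## 2. collapsed variance update (adaptive log-scale walk as in
  ##    gibbs_sweep), repeated a few times per PG refresh: the expensive
  ##    parts shared across sub-steps (PG draw, working crossprod) are
  ##    already in hand, and the variance chain is the slowest-mixing part
  ##    of the model
  K <- length(cp$v)
  ml_cur <- marg(st_cur, cp$v) + log_prior_v(cp$v, prior) + sum(log(cp$v))
  lb <- log(1e-10)
  for (sub in seq_len(cp$substeps)) {
    cur <- log(pmax(cp$v, 1e-12))
    eps <- if (is.null(cp$vs_chol)) stats::rnorm(K, 0, cp$step_v) else
      cp$step_v * as.numeric(cp$vs_chol %*% stats::rnorm(K))
    prop <- ifelse(cur + eps < lb, 2 * lb - (cur + eps), cur + eps)
    v_new <- stats::setNames(exp(prop), names(cp$v))
    st_new <- variance_state_pg(cp, prior, v_new, Tw)
    accepted <- FALSE
    if (!is.null(st_new)) {
      ml_new <- marg(st_new, v_new) + log_prior_v(v_new, prior) +
        sum(log(v_new))
      if (is.finite(ml_new) && log(stats::runif(1)) < ml_new - ml_cur) {
        cp$v <- v_new
        st_cur <- st_new
        ml_cur <- ml_new
        accepted <- TRUE
      }
    }
    if (adapt) cp$step_v <- cp$step_v * exp(0.25 * (accepted - 0.3))
  }
  if (adapt) {
    cp$v_hist_n <- cp$v_hist_n + 1L
    cp$v_hist[cp$v_hist_n, ] <- log(pmax(cp$v, 1e-12))
    if (cp$v_hist_n >= 250 && cp$v_hist_n %% 100 == 0) {
      S <- stats::cov(cp$v_hist[seq_len(cp$v_hist_n), , drop = FALSE]) +
        diag(1e-4, K)
      first <- is.null(cp$vs_chol)
      cp$vs_chol <- t(chol(S)) * (2.38 / sqrt(K))
      if (first) cp$step_v <- 1
    }
  }
  cp$chol <- st_cur$chol; cp$logdet <- st_cur$logdet

  ## 3. locations | variances, omega
  mu <- as.numeric(Matrix::solve(cp$chol, b, system = "A"))
  w <- stats::rnorm(length(mu))
  dev <- Matrix::solve(cp$chol, w, system = "Lt")
  dev <- as.numeric(Matrix::solve(cp$chol, dev, system = "Pt"))
  cp$theta <- mu + dev
  cp$m <- as.numeric(cp$M %*% cp$theta)

  ## 4. latent values | locations, omega (exact Gaussian); with no latent
  ##    residual the latent IS the linear predictor
  if (cp$ve == 0) {
    cp$l <- cp$m
  } else {
    prec <- omega + 1 / cp$ve
    cp$l <- stats::rnorm(n, (kappa + cp$m / cp$ve) / prec, sqrt(1 / prec))
  }
  cp$accept_rate <- 1
  cp
}

## mixed-model equations with heteroscedastic working weights (PG sweep)
variance_state_pg <- function(cp, prior, v, Tw) {
  C <- assemble_C(cp, v, Tw@x, 1 / prior$beta_V)
  ch <- tryCatch({
    if (is.null(cp$chol)) Matrix::Cholesky(C, LDL = FALSE)
    else Matrix::update(cp$chol, C)
  }, error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ld <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                           sqrt = TRUE)$modulus)
  list(chol = ch, logdet = ld)
}

## data log-likelihood of latent values, vectorized (0 where unobserved)
loglik_vec <- function(cp, l) {
  out <- numeric(length(l))
  o <- cp$observed
  if (cp$link == "logit") {
    out[o] <- cp$obs_data[o] * l[o] - log1p(exp(l[o]))
  } else {
    out[o] <- cp$y[o] * l[o] - exp(l[o])
  }
  out
}

## posterior update of structural-zero indicators
update_zip_indicator <- function(y, l_zi, l_pois) {
  z <- integer(length(y))
  zero <- y == 0
  p <- stats::plogis(l_zi[zero])
  lam <- exp(l_pois[zero])
  pr <- p / (p + (1 - p) * exp(-lam))
  z[zero] <- as.integer(stats::runif(sum(zero)) < pr)
  z
}

## reported parameters: fixed effects, term variances, residual variance
collect_params <- function(cp) {
  vals <- c(cp$theta[cp$blk$beta], cp$v[names(cp$terms)],
            if (cp$resid_estimated) cp$ve)
  stats::setNames(vals, cp$par_names)
}

#' @export
print.fitqg_fit <- function(x, ...) {
  cat("Animal model fit (", x$family, "), ", nrow(x$draws),
      " retained draws, ", x$n_obs, " observations\n", sep = "")
  vs <- grep("^v_|\\.v_", colnames(x$draws), value = TRUE)
  for (v in vs) {
    s <- summarize_posterior(x$draws[, v])
    cat(sprintf("  %-16s mode %8.4f  95%% HPD [%.4f, %.4f]  ESS %.0f\n", v,
                s$mode, s$hpd_low, s$hpd_high, x$diagnostics[v, "ess"]))
  }
  invisible(x)
}

#' Posterior summary table of a fitted model
#'
#' @param object a `fitqg_fit`.
#' @param ... unused.
#' @return Data frame of posterior mode, 95% HPD bounds, mean, ESS, lag-1
#'   autocorrelation and Heidelberger-Welch pass for every parameter.
#' @export
summary.fitqg_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(colnames(object$draws), function(cn) {
    s <- summarize_posterior(object$draws[, cn])
    data.frame(parameter = cn, mode = s$mode, hpd_low = s$hpd_low,
               hpd_high = s$hpd_high, mean = s$mean)
  }))
  cbind(out, object$diagnostics[out$parameter, ])
}
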