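#' Latent- to data-scale conversion of quantitative genetic parameters
#'
#' Generalized linear animal models estimate variance components on the
#' latent (link) scale. Evolutionary inference, however, concerns the data
#' (observed) scale: the population mean, phenotypic variance \eqn{V_P},
#' additive genetic variance \eqn{V_A}, heritability \eqn{h^2 = V_A/V_P} and
#' evolvability \eqn{I_A = V_A/\bar{z}^2}. These functions integrate the
#' inverse link over the latent Gaussian distribution
#' \eqn{N(\mu, \sigma^2)} with \eqn{\sigma^2 = V_A + V_{other}}.
#'
#' For the log link the integrals have closed forms: the mean is
#' \eqn{\bar\lambda = e^{\mu + \sigma^2/2}}, the phenotypic variance is
#' \eqn{\bar\lambda + \bar\lambda^2 (e^{\sigma^2} - 1)} (Poisson plus
#' log-normal mixing variance), and the data-scale additive variance is
#' \eqn{\Psi^2 V_A} with \eqn{\Psi = \bar\lambda} (the average derivative of
#' the inverse link). For the logit link the integrals are evaluated by
#' Gauss-Hermite quadrature.
#'
#' @param mu latent intercept (fixed effects at their reference level or
#'   averaged out).
#' @param va latent additive genetic variance.
#' @param v_other sum of the remaining latent variances (cohort/year,
#'   permanent environment, residual -- including any residual variance
#'   fixed by the model, e.g. the unit logit residual).
#' @return A list of class `fitqg_data_scale` with elements `mean`, `v_p`,
#'   `v_a_obs`, `h2`, `ia`.
#' @examples
#' transform_poisson_log(0, va = 0.2, v_other = 0.3)
#' transform_logit(2, va = 0.5, v_other = 0.5)
#' @export
transform_poisson_log <- function(mu, va, v_other) {
  check_latent(mu, va, v_other)
  s2 <- va + v_other
  if (mu + s2 / 2 > 350 || s2 > 350)
    stop("latent mean/variance too large: exp() would overflow; ",
         "rescale the trait")
  lam <- exp(mu + s2 / 2)
  v_p <- lam + lam^2 * (exp(s2) - 1)
  v_a_obs <- lam^2 * va
  data_scale(lam, v_p, v_a_obs)
}

#' @rdname transform_poisson_log
#' @param nodes number of Gauss-Hermite quadrature nodes (doubled
#'   internally to verify convergence).
#' @param tol maximum allowed change in any output under node doubling.
#' @export
transform_logit <- function(mu, va, v_other, nodes = 32, tol = 1e-8) {
  check_latent(mu, va, v_other)
  s2 <- va + v_other
  f <- function(k) {
    q <- statmod::gauss.quad.prob(k, dist = "normal", mu = mu,
                                  sigma = sqrt(max(s2, 0)))
    c(p = sum(q$weights * stats::plogis(q$nodes)),
      psi = sum(q$weights * stats::dlogis(q$nodes)))
  }
  if (s2 == 0) {
    est <- c(p = stats::plogis(mu), psi = stats::dlogis(mu))
  } else {
    ## escalate the node count until doubling leaves the result unchanged
    k <- nodes
    est <- f(k)
    repeat {
      est2 <- f(2 * k)
      if (max(abs(est - est2)) <= tol) { est <- est2; break }
      k <- 2 * k
      est <- est2
      if (k > 1024)
        stop("Gauss-Hermite quadrature did not converge under node ",
             "doubling; increase `nodes` or rescale the latent parameters")
    }
  }
  p <- est[["p"]]
  data_scale(p, p * (1 - p), est[["psi"]]^2 * va)
}

check_latent <- function(mu, va, v_other) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu),
            is.numeric(va), length(va) == 1, va >= 0,
            is.numeric(v_other), length(v_other) == 1, v_other >= 0)
}

data_scale <- function(mean, v_p, v_a_obs) {
  out <- list(mean = mean, v_p = v_p, v_a_obs = v_a_obs,
              h2 = if (v_p > 0) v_a_obs / v_p else 0,
              ia = if (mean != 0) v_a_obs / mean^2 else Inf)
  class(out) <- "fitqg_data_scale"
  out
}

#' @export
print.fitqg_data_scale <- function(x, ...) {
  cat(sprintf("data scale: mean %.4g  V_P %.4g  V_A %.4g  h2 %.4g  I_A %.4g\n",
              x$mean, x$v_p, x$v_a_obs, x$h2, x$ia))
  invisible(x)
}

#' Transform posterior draws to the data scale and summarize
#'
#' Applies the appropriate link transform draw by draw to the retained MCMC
#' samples of a fitted animal model, then summarizes every data-scale
#' quantity by its kernel-density posterior mode and 95% highest posterior
#' density interval. Ratios (heritability, evolvability) are computed per
#' draw -- never from summarized numerators and denominators -- so the
#' reported mode of a ratio is the mode of the ratio's posterior.
#'
#' The latent intercept used is the model intercept, i.e. fixed effects are
#' evaluated at their reference level (dead individuals; age at its first
#' value for annual models). Alternatively `at` can supply a named vector of
#' fixed-effect values at which to evaluate the latent mean.
#'
#' @param fit a `fitqg_fit` object from [fit_animal_model()].
#' @param component `"zi"` or `"pois"` for zero-inflated Poisson fits,
#'   `"single"` for Poisson/binary fits.
#' @param at optional named vector of fixed-effect covariate values defining
#'   the evaluation point of the latent intercept.
#' @return A list of class `fitqg_data_scale_posterior`: `draws` (a data
#'   frame with per-draw `mean`, `v_p`, `v_a_obs`, `h2`, `ia`) and `summary`
#'   (per-quantity posterior mode, HPD bounds and mean).
#' @export
transform_posterior <- function(fit, component = c("single", "zi", "pois"),
                                at = NULL) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "fitqg_fit"))
  if (fit$family == "zipoisson" && component == "single")
    stop("zero-inflated fits have two components; choose 'zi' or 'pois'")
  if (fit$family != "zipoisson" && component != "single")
    stop("component '", component, "' only exists in zero-inflated fits")
  link <- if (component == "pois" || fit$family == "poisson") "log" else "logit"
  layout <- fit$layout[[if (component == "single") "single" else component]]
  d <- fit$draws
  mu <- d[, layout$intercept]
  if (!is.null(at)) {
    for (nm in names(at)) {
      col <- layout$fixed[nm]
      if (is.na(col)) stop("no fixed effect named '", nm, "'")
      mu <- mu + d[, col] * at[[nm]]
    }
  }
  va <- d[, layout$va]
  v_other <- layout$resid_fixed
  for (col in layout$other) v_other <- v_other + d[, col]
  tfun <- if (link == "log") transform_poisson_log else transform_logit
  rows <- lapply(seq_along(mu), function(i) {
    z <- tfun(mu[i], va[i], v_other[i])
    c(mean = z$mean, v_p = z$v_p, v_a_obs = z$v_a_obs, h2 = z$h2, ia = z$ia)
  })
  draws <- as.data.frame(do.call(rbind, rows))
  summ <- do.call(rbind, lapply(draws, function(x) {
    s <- summarize_posterior(x)
    data.frame(mode = s$mode, hpd_low = s$hpd_low, hpd_high = s$hpd_high,
               mean = s$mean)
  }))
  out <- list(draws = draws, summary = summ, component = component,
              link = link)
  class(out) <- "fitqg_data_scale_posterior"
  out
}

#' @export
print.fitqg_data_scale_posterior <- function(x, ...) {
  cat("Data-scale posterior (", x$component, " component, ", x$link,
      " link)\n", sep = "")
  print(round(x$summary, 4))
  invisible(x)
}

## mean of plogis(N(mu, s2)); used for calibrating simulator intercepts
logit_mean <- function(mu, s2, nodes = 64) {
  if (s2 <= 0) return(stats::plogis(mu))
  q <- statmod::gauss.quad.prob(nodes, dist = "normal", mu = mu,
                                sigma = sqrt(s2))
  sum(q$weights * stats::plogis(q$nodes))
}

## solve logit_mean(mu, s2) = target for mu
logit_mean_inverse <- function(target, s2) {
  stopifnot(target > 0, target < 1)
  stats::uniroot(function(m) logit_mean(m, s2) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}
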