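---
title: "Quantitative genetics of fitness in a pedigreed wild population: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of fitness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitqg)
```

## The scientific problem

Additive genetic variance in fitness ($V_A$) is the quantity that Fisher's
fundamental theorem places at the centre of adaptive evolution: the expected
per-generation change in mean fitness equals the additive genetic variance
in relative fitness. Estimating $V_A$ of fitness in the wild is notoriously
hard: lifetime fitness is strongly non-Gaussian (most individuals leave no
recruits), pedigrees are shallow and incomplete, and the expected effect
sizes are small.

`fitqg` implements the full analysis pipeline for a long-term colonial
seabird study system: a pedigree of roughly six thousand individuals across
five generations, lifetime fitness measured as the number of local
fledglings produced by a locally hatched fledgling, and two annual
components — annual reproductive success (ARS, fledglings per year, at most
three) and adult annual survival (AAS, a 0/1 trait). The package provides

* pedigree utilities (validation, pruning to phenotyped individuals and
  their ancestors, relatedness summaries, the additive relationship matrix
  `A` and its sparse inverse);
* Bayesian animal models for zero-inflated Poisson, Poisson and binary
  responses, fitted by MCMC;
* conversion of latent-scale posteriors to data-scale population mean,
  $V_P$, $V_A$, heritability $h^2 = V_A/V_P$ and evolvability
  $I_A = V_A/\bar z^2$;
* a calibrated synthetic-data generator and a simulation-based power
  analysis for the detectability of small $V_A$.

## Models

### Lifetime fitness: zero-inflated Poisson

Lifetime fitness $y_i$ is modelled as a mixture of two processes.
Individual $i$ is a *structural zero* (it never recruits into the breeding
population) with probability $p_i$; otherwise it produces a Poisson number
of fledglings:

$$ y_i \sim \begin{cases} 0 & \text{with probability } p_i\\
\mathrm{Poisson}(\lambda_i) & \text{otherwise,}\end{cases}\qquad
\mathrm{logit}(p_i) = \ell^{zi}_i,\quad \log(\lambda_i) = \ell^{pois}_i. $$

Each latent value is a linear mixed model
$\ell = X\beta + a + c \,(+\, e)$ with fixed effects $\beta$ (intercept and
alive/dead status at the end of the study), an additive genetic effect
$a \sim N(0, V_A A)$ structured by the pedigree, a hatch-year (cohort)
effect $c$, and for the Poisson component an overdispersion residual $e$
whose variance is estimated. The zero-inflation latent's residual variance
is fixed to 1: overdispersion of a structural-zero process is not
identifiable from single binary realizations, so it is pinned, as is
conventional for zero-inflated animal models. No covariance between the
two components is modelled. The two components of the spec are fitted with
independent random effects, matching the analysis the package reproduces.

### Annual components

ARS uses a log-link Poisson model and AAS a logit-link binary model with
the residual variance fixed to one. Both include the intercept and a
linear age effect (age 1–23; the intercept refers to age 1) as fixed
effects, plus additive genetic, permanent-environment (individual identity
not linked to the pedigree) and observation-year random intercepts.

### Priors

Variance components carry the parameter-expanded prior family: a half-$t$
with `nu` degrees of freedom (default 1, i.e. half-Cauchy) and scale
`t_scale` (default 1) on the standard-deviation scale — the distribution
induced by a scaled 1-df Gaussian working parameter. It is heavy-tailed
yet finite at zero, the standard weakly informative choice for
near-boundary variance components. Estimated residual variances get a
nearly flat inverse-Wishart (`resid_nu = 0.002`), and fixed effects
diffuse Gaussians. The original study states that parameter-expanded
priors were used but does not print the constants, so these defaults are
documented stand-ins, exposed in `mcmc_config(prior = ...)` so prior
sensitivity can be examined directly.

## The sampler

Single-record animal models mix notoriously slowly under naive Gibbs
sampling because each variance component rides a ridge with its effect
vector. `fitqg` therefore uses collapsed updates throughout:

* **Logit components** (zero-inflation and binary survival) use
  Pólya-Gamma augmentation. Given PG weights $\omega_i$, the whole
  Gaussian hierarchy — latent values, the fixed unit residual, fixed and
  random effects — is integrated out analytically through one sparse
  Cholesky factorization of the mixed-model equations, so variance
  components are updated by a Metropolis step on their *marginal*
  posterior given only the data and $\omega$. Locations and latents are
  then redrawn exactly. The PG(1, z) sampler (alternating-series rejection
  method) is implemented in C++.
* **Log-link components** update the latent field by vectorized
  element-wise random-walk Metropolis (the element updates are
  conditionally independent given the locations), and variance components
  by a Metropolis step on their marginal posterior given the latent field,
  again with all location effects integrated out sparsely.
* The log-variance proposals use an adaptive (Haario-type) covariance
  learned during burn-in only, with a reflecting floor at $10^{-10}$;
  latent-update step sizes adapt during burn-in only (target acceptance
  0.44). After burn-in every proposal distribution is frozen, so the chain
  is a fixed-kernel Markov chain with the correct stationary distribution.
* For the zero-inflated family the structural-zero indicators are imputed
  each sweep: positive counts are never structural, zero counts are
  structural with posterior odds $p_i / \{(1-p_i)e^{-\lambda_i}\}$.

Convergence is monitored by effective sample size (spectral estimator),
lag-1 autocorrelation of the retained draws, and a Heidelberger–Welch
stationarity test (Cramér–von Mises statistic of the Brownian bridge of
partial sums, with the spectral density at zero estimated from the final
half of the chain, following the original procedure — estimating it from
the whole chain lets a mean drift mask itself). Posterior point estimates
are kernel-density modes (Gaussian kernel, Silverman's rule-of-thumb
bandwidth, argmax restricted to the observed draw range) and 95% highest
posterior density intervals.

## Latent- to data-scale conversion

Latent-scale variance components are converted to the observed scale by
integrating the inverse link over the latent Gaussian
$N(\mu, \sigma^2)$, $\sigma^2 = V_A + V_{other}$, where $V_{other}$ sums
cohort/year, permanent-environment and (fixed or estimated) residual
variances:

* log link (closed forms): mean $\bar\lambda = e^{\mu + \sigma^2/2}$,
  $V_P = \bar\lambda + \bar\lambda^2(e^{\sigma^2} - 1)$,
  $V_A^{obs} = \bar\lambda^2 V_A$;
* logit link (Gauss–Hermite quadrature, 32 nodes by default, with a
  node-doubling convergence check that escalates the node count before
  failing): mean $\bar p = \int \mathrm{logistic}(x)\,\phi(x)\,dx$,
  $V_P = \bar p(1-\bar p)$, $V_A^{obs} = \Psi^2 V_A$ with
  $\Psi = \int \mathrm{logistic}'(x)\,\phi(x)\,dx$.

`transform_posterior()` applies the transform to *every retained draw* and
summarizes afterwards, so ratios such as $h^2$ and $I_A$ are genuine
posterior functionals, never ratios of summaries. Fixed effects are
evaluated at their reference level (dead individuals; age 1) by default;
the `at` argument moves the evaluation point, because the choice of
evaluation point is not dictated by the method itself and deserves to be
explicit.

## The synthetic-data generator

The generator emulates the study system closely enough that every part of
the pipeline can be exercised, calibrated and power-analysed without the
field data.

**Pedigree.** A colony is founded by a cohort of marked adults; every
generation an influx of unmarked immigrant breeders joins the pool (the
study population is immigration-dominated, with roughly three quarters of
breeders being immigrants in any year). Only marked birds — the initial
adults and all locally hatched fledglings — receive pedigree records, so
offspring of immigrants carry missing parent links, exactly as in a
transponder-based colony study. Locals hold longer breeding tenure than
transient immigrants and experienced (marked) pairs fledge more chicks,
which calibrates the fraction of records with known parents; pairs are
retained between years with probability 0.6 (serial monogamy with partial
mate fidelity). Default rates reproduce the study pedigree's published
structure: roughly 6300 records, maximum depth five generations, about
2400–2600 recorded paternities/maternities, about 2000 full-sib pairs and
8000–9000 half-sib pairs per parental sex.

**Breeding values** are gene dropped: founders from $N(0, V_A)$,
non-founders as the mid-parent value plus a Mendelian deviation with
variance $\tfrac{1}{2}V_A\{1 - (F_s + F_d)/2\}$; an unknown parent
contributes a fresh phantom-founder draw. Across replicates the dropped
values have covariance $V_A A$ exactly.

**Lifetime fitness** is generated from the zero-inflated Poisson process
above. The default parameter set is *calibrated*: the structural-zero
probability and the conditional Poisson mean are solved jointly (by
quadrature and a fixed-point sweep) so that the marginal moments match the
study's raw values — 87.19% zeros and mean 0.72 fledglings — for any
choice of the variance parameters. Default variances are small additive
variances (the study estimated them near zero), a moderate hatch-year
variance, and enough overdispersion that successful recruits span the
observed 0–29 fledgling range.

**Annual tables** simulate each breeder from age 1: survival each year
from the AAS latent (death forced at age 23), one ARS record per year
truncated at three fledglings. The intercepts are solved so the expected
*row means* equal the study's raw means (0.70 and 0.85), integrating the
survivorship-induced age distribution and the ARS truncation by
quadrature.

**Moment standardization.** With only a few dozen cohorts and years, the
sampled means of grouped effects would otherwise dominate the Monte Carlo
error of the calibrated moments. By default the generator therefore
applies scalar standardizing shifts to grouped effects (exact weighted
data-scale means) and draws the structural-zero count by a systematic
probability-proportional-to-size scheme, which leaves between-group
variances and all individual-level genetic structure untouched. For
likelihood-exact work — parameter-recovery simulations in particular —
`standardize = FALSE` gives the pure generative model with fully
independent draws; the power study uses that mode.

**What is not emulated:** dispersal and immigration genetics, density
dependence, mate choice, sex-specific fitness, spatial structure, and
observation error in parentage. Passing tests on synthetic data therefore
demonstrate correctness of the estimation machinery under the stated
generative model, not robustness to these real-data complications.

## The power study

`run_power_study()` reproduces the simulation-based power analysis: for
each value in a grid of latent additive variances and each replicate,
breeding values are gene dropped on a fixed pedigree, a lifetime-fitness
table is simulated from the model's own generative process, the
zero-inflated Poisson animal model is refitted, and the posterior of the
target component's $V_A$ is summarized. A replicate *detects* $V_A$ when
the lower 95% HPD bound exceeds $10^{-4}$. Replicates whose target-series
effective sample size falls below a configurable floor are flagged and
excluded from aggregates (and reported). `extend_pedigree()` continues
the breeding dynamics for extra generations to ask how power grows with
study duration. For the Poisson component a target evolvability maps to a
latent variance via $V_A = \log(1 + I_A)$, the exact log-link identity.

## Numerical choices and known limitations

* Chain lengths: the study convention is burn-in at least 5000 and
  effective sizes above 1000, which the defaults follow. The test suite
  and the acceptance script run reduced chains (roughly 2600–4000
  iterations) and reduced replicate counts on one CPU; the affected checks
  document their sizes.
* Posterior modes of near-boundary variance components deserve caution.
  Under the parameter-expanded prior the marginal prior density of a
  variance diverges as $v^{-1/2}$ at zero, so whenever the likelihood is
  weak the posterior piles against the boundary and the kernel-density
  mode depends on bandwidth and on the information content of the data.
  In the simulate-and-refit experiments at the problem sizes used here,
  mean recovered modes for small simulated variances of the
  zero-inflation component systematically undershoot the simulated value
  — single-record binary observations at an 87% zero rate carry Fisher
  information of only about 0.11 per observation about their logit
  latent, so several thousand records cannot pin a latent variance of
  0.05 against a heavy zero-spike prior. Full posterior summaries (HPD
  intervals) are the more honest report in this regime, and the package
  prints them alongside every mode.
* The KDE mode is restricted to the observed draw range, which prevents
  the bandwidth from pushing a boundary mode to an impossible value
  (negative variance, $h^2 > 1$).
* All randomness flows from explicit seeds; fits canonicalize the row
  order of the phenotype table internally, so row permutations do not
  change results.

## A worked example

```{r example, eval = FALSE}
ped <- simulate_pedigree(pedigree_sim_config(seed = 1))
summary(ped)

lt  <- simulate_lifetime(ped, tern_lifetime_params(seed = 2))
fit <- fit_animal_model(lt, ped, spec_lifetime_zip(),
                        mcmc_config(n_iter = 15000, burn_in = 5000,
                                    thin = 10, seed = 3))
summary(fit)
transform_posterior(fit, "zi")    # data-scale mean, V_P, V_A, h2, I_A
transform_posterior(fit, "pois")
```
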