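#' Gene-drop breeding values down a pedigree
#'
#' Simulates additive genetic (breeding) values by gene dropping: founders
#' draw from `Normal(0, va)`; each non-founder receives the mean of its
#' parents' values plus an independent Mendelian sampling deviation with
#' variance `va/2 * (1 - (F_sire + F_dam)/2)`. An unknown parent contributes
#' a fresh 0-mean founder draw (phantom founder), so individuals with
#' unknown parents remain unbiased with the correct marginal variance.
#'
#' Over replicates the covariance of the dropped values equals `va * A`,
#' with `A` the additive relationship matrix.
#'
#' @param ped a [pedigree()] object (topologically sorted by construction).
#' @param va additive genetic variance (>= 0).
#' @param seed optional integer seed.
#' @return Named numeric vector of breeding values, one per pedigree record.
#' @export
drop_breeding_values <- function(ped, va, seed = NULL) {
  if (!is.numeric(va) || length(va) != 1 || is.na(va) || va < 0)
    stop("va must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  bv <- numeric(n)
  if (va == 0) { names(bv) <- ped$id; return(bv) }
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  Fcoef <- inbreeding_ml(di, si)
  founder <- is.na(di) & is.na(si)
  bv[founder] <- stats::rnorm(sum(founder), 0, sqrt(va))
  for (i in which(!founder)) {
    ps <- if (!is.na(si[i])) c(bv[si[i]], Fcoef[si[i]]) else
      c(stats::rnorm(1, 0, sqrt(va)), 0)
    pd <- if (!is.na(di[i])) c(bv[di[i]], Fcoef[di[i]]) else
      c(stats::rnorm(1, 0, sqrt(va)), 0)
    mend_var <- 0.5 * va * (1 - (ps[2] + pd[2]) / 2)
    bv[i] <- 0.5 * (ps[1] + pd[1]) + stats::rnorm(1, 0, sqrt(mend_var))
  }
  names(bv) <- ped$id
  bv
}
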