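#' Construct and validate a pedigree
#'
#' A pedigree is a table of individuals with (possibly unknown) dam and sire
#' links and an optional hatch cohort. On construction the records are
#' validated (unique ids, acyclicity, cohort ordering), parents that are
#' referenced but have no record of their own are inserted as founders, and
#' the records are sorted topologically so that parents always precede
#' offspring.
#'
#' Unknown parents are treated as unrelated, non-inbred founders drawn from
#' the base population; in an immigration-driven study population this is the
#' natural convention because immigrant breeders are never marked and so
#' never appear as records.
#'
#' @param id character vector of individual identifiers.
#' @param dam,sire character vectors of parental identifiers; `NA` for
#'   unknown.
#' @param cohort integer hatch year (or generation index); `NA` allowed.
#' @return An object of class `fitqg_pedigree`: a data frame with columns
#'   `id`, `dam`, `sire`, `cohort`, topologically sorted.
#' @examples
#' ped <- pedigree(id = c("f1", "f2", "x"), dam = c(NA, NA, "f1"),
#'                 sire = c(NA, NA, "f2"), cohort = c(1, 1, 2))
#' summary(ped)
#' @export
pedigree <- function(id, dam = NA, sire = NA, cohort = NA) {
  id <- as.character(id)
  n <- length(id)
  dam <- rep_len(as.character(dam), n)
  sire <- rep_len(as.character(sire), n)
  cohort <- rep_len(as.integer(cohort), n)
  if (anyNA(id)) stop("individual ids must not be missing")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))

  ## parents referenced but never listed become founders
  parents <- unique(stats::na.omit(c(dam, sire)))
  phantom <- setdiff(parents, id)
  if (length(phantom)) {
    warning(length(phantom), " parent id(s) had no record of their own; ",
            "inserted as founders: ", paste(utils::head(phantom, 5), collapse = ", "),
            if (length(phantom) > 5) ", ..." else "")
    id <- c(id, phantom)
    dam <- c(dam, rep(NA_character_, length(phantom)))
    sire <- c(sire, rep(NA_character_, length(phantom)))
    cohort <- c(cohort, rep(NA_integer_, length(phantom)))
    n <- length(id)
  }

  ord <- ped_topological_order(id, dam, sire)
  ped <- data.frame(id = id[ord], dam = dam[ord], sire = sire[ord],
                    cohort = cohort[ord], stringsAsFactors = FALSE)

  ## offspring cannot hatch before either known parent
  ci <- ped$cohort
  for (p in c("dam", "sire")) {
    pc <- ci[match(ped[[p]], ped$id)]
    bad <- which(!is.na(pc) & !is.na(ci) & ci < pc)
    if (length(bad))
      stop("cohort of ", ped$id[bad[1]], " precedes cohort of its ", p)
  }
  class(ped) <- c("fitqg_pedigree", "data.frame")
  ped
}

## Kahn topological sort; errors with an explicit cycle if one exists.
ped_topological_order <- function(id, dam, sire) {
  n <- length(id)
  di <- match(dam, id)
  si <- match(sire, id)
  indeg <- integer(n)
  indeg[!is.na(di)] <- indeg[!is.na(di)] + 1L
  indeg[!is.na(si)] <- indeg[!is.na(si)] + 1L
  ## children[[p]] = offspring rows of parent p
  kids <- c(which(!is.na(di)), which(!is.na(si)))
  pars <- c(di[!is.na(di)], si[!is.na(si)])
  children <- split(kids, factor(pars, levels = seq_len(n)))
  ord <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in children[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    cyc <- ped_find_cycle(left, di, si)
    stop("pedigree contains a cycle: ", paste(id[cyc], collapse = " -> "))
  }
  ord
}

ped_find_cycle <- function(left, di, si) {
  v <- left[1]
  seen <- integer(0)
  repeat {
    seen <- c(seen, v)
    nxt <- if (!is.na(di[v]) && di[v] %in% left) di[v] else si[v]
    if (nxt %in% seen) return(c(seen[which(seen == nxt):length(seen)], nxt))
    v <- nxt
  }
}

#' Read a pedigree from a delimited text file
#'
#' The file must have a header naming the id, dam, sire and (optionally)
#' cohort columns. Field separator is sniffed from the header (tab, comma or
#' semicolon; whitespace otherwise). Missing parents may be encoded by empty
#' fields, `NA`, or a configurable sentinel such as `"0"`.
#'
#' @param path path to the file.
#' @param id,dam,sire,cohort column names in the file.
#' @param missing character vector of sentinel values meaning "unknown".
#' @return A [pedigree()] object, topologically sorted.
#' @export
read_pedigree <- function(path, id = "id", dam = "dam", sire = "sire",
                          cohort = "cohort", missing = c("", "NA", "0", "*")) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
         else if (grepl(";", header)) ";" else ""
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (col in c(id, dam, sire)) {
    if (!col %in% names(d)) stop("column '", col, "' not found in ", path)
  }
  clean <- function(x) { x[x %in% missing] <- NA_character_; x }
  co <- if (cohort %in% names(d)) suppressWarnings(as.integer(clean(d[[cohort]]))) else NA
  pedigree(id = clean(d[[id]]), dam = clean(d[[dam]]),
           sire = clean(d[[sire]]), cohort = co)
}

#' Write a pedigree to a delimited text file
#' @param ped a [pedigree()] object.
#' @param path output path.
#' @param sep field separator.
#' @export
write_pedigree <- function(ped, path, sep = "\t") {
  utils::write.table(as.data.frame(ped), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Restricts the pedigree to the union of the phenotyped individuals and all
#' of their ancestors, preserving parent links among retained records. This
#' is the standard pruning applied before fitting an animal model: records
#' that are neither phenotyped nor ancestral carry no information about the
#' additive genetic variance.
#'
#' The operation is idempotent: pruning an already-pruned pedigree with the
#' same phenotyped set returns it unchanged.
#'
#' @param ped a [pedigree()] object.
#' @param phenotyped_ids character vector of phenotyped individual ids; must
#'   all be present in the pedigree.
#' @return A [pedigree()] object containing exactly the ancestor closure.
#' @export
prune_to_phenotyped <- function(ped, phenotyped_ids) {
  phenotyped_ids <- unique(as.character(phenotyped_ids))
  if (length(phenotyped_ids) == 0) stop("phenotyped set is empty")
  miss <- setdiff(phenotyped_ids, ped$id)
  if (length(miss)) stop("phenotyped id(s) not in pedigree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  keep <- ped$id %in% phenotyped_ids
  ## reverse topological sweep: a record is kept if any offspring is kept
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(di[i])) keep[di[i]] <- TRUE
      if (!is.na(si[i])) keep[si[i]] <- TRUE
    }
  }
  out <- ped[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fitqg_pedigree", "data.frame")
  out
}

#' Summarize pedigree structure
#'
#' Computes the record count, generation depth (longest parent chain;
#' founders have depth 1), numbers of paternities and maternities (records
#' with a known sire or dam), and sibling pair counts. Sibling counts are
#' counts of unordered pairs: full-sib pairs share both named parents, and
#' the paternal (maternal) half-sib counts are pairs sharing the named sire
#' (dam) *including* full-sib pairs, so the full-sib count can never exceed
#' either. Users comparing against per-individual sibling conventions should
#' note the pair convention.
#'
#' @param object a [pedigree()] object.
#' @param ... unused.
#' @return A list of class `fitqg_pedigree_summary` with elements
#'   `n_records`, `max_depth`, `n_paternities`, `n_maternities`,
#'   `n_fullsibs`, `n_paternal_halfsib_pairs_incl_full`,
#'   `n_maternal_halfsib_pairs_incl_full`.
#' @export
summary.fitqg_pedigree <- function(object, ...) {
  ped <- object
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  depth <- rep(1L, nrow(ped))
  for (i in seq_len(nrow(ped))) {  # parents precede offspring
    pd <- c(if (!is.na(di[i])) depth[di[i]], if (!is.na(si[i])) depth[si[i]])
    if (length(pd)) depth[i] <- max(pd) + 1L
  }
  pair_count <- function(keys) {
    keys <- keys[!is.na(keys)]
    if (!length(keys)) return(0)
    sum(choose(table(keys), 2))
  }
  both <- !is.na(ped$dam) & !is.na(ped$sire)
  out <- list(
    n_records = nrow(ped),
    max_depth = if (nrow(ped)) max(depth) else 0L,
    n_paternities = sum(!is.na(ped$sire)),
    n_maternities = sum(!is.na(ped$dam)),
    n_fullsibs = pair_count(ifelse(both, paste(ped$dam, ped$sire, sep = "\r"), NA)),
    n_paternal_halfsib_pairs_incl_full = pair_count(ped$sire),
    n_maternal_halfsib_pairs_incl_full = pair_count(ped$dam)
  )
  class(out) <- "fitqg_pedigree_summary"
  out
}

#' @export
print.fitqg_pedigree_summary <- function(x, ...) {
  cat("Pedigree summary\n")
  cat("  records:            ", x$n_records, "\n")
  cat("  max depth:          ", x$max_depth, "generations\n")
  cat("  paternities:        ", x$n_paternities, "\n")
  cat("  maternities:        ", x$n_maternities, "\n")
  cat("  full-sib pairs:     ", x$n_fullsibs, "\n")
  cat("  paternal sib pairs: ", x$n_paternal_halfsib_pairs_incl_full, "(incl. full)\n")
  cat("  maternal sib pairs: ", x$n_maternal_halfsib_pairs_incl_full, "(incl. full)\n")
  invisible(x)
}

#' @export
print.fitqg_pedigree <- function(x, n = 10, ...) {
  cat("<fitqg_pedigree> ", nrow(x), " records (",
      sum(is.na(x$dam) & is.na(x$sire)), " founders)\n", sep = "")
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more records\n")
  invisible(x)
}

#' Additive relationship structure of a pedigree
#'
#' Computes the additive (numerator) relationship matrix A by the recursive
#' tabular method, per-individual inbreeding coefficients F, and/or the
#' sparse inverse of A assembled directly from pedigree links
#' (Henderson-style rules with inbreeding, using Meuwissen-Luo coefficients),
#' without ever forming the dense A when only the inverse is requested.
#'
#' @param ped a [pedigree()] object (topologically sorted by construction).
#' @param what which pieces to return: `"Ainv"` (default), `"A"` or
#'   `"both"`.
#' @return A list of class `fitqg_relatedness` with elements `ids`, `F`
#'   (inbreeding coefficients), and, depending on `what`, `A` (dense base
#'   matrix) and `Ainv` (sparse `dsCMatrix`).
#' @examples
#' ped <- pedigree(c("d", "s", "x", "y"), c(NA, NA, "d", "d"),
#'                 c(NA, NA, "s", "s"))
#' additive_relationship(ped, what = "A")$A  # full sibs: a = 0.5
#' @export
additive_relationship <- function(ped, what = c("Ainv", "A", "both")) {
  what <- match.arg(what)
  n <- nrow(ped)
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  Fcoef <- inbreeding_ml(di, si)

  out <- list(ids = ped$id, F = Fcoef)
  if (what %in% c("A", "both")) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      if (i > 1) {
        j <- seq_len(i - 1L)
        aij <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                      (if (!is.na(d)) A[j, d] else 0))
        A[j, i] <- A[i, j] <- aij
      }
      A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    }
    dimnames(A) <- list(ped$id, ped$id)
    if (max(abs(diag(A) - (1 + Fcoef))) > 1e-10)
      stop("inconsistent inbreeding coefficients; pedigree may be corrupt")
    out$A <- A
  }
  if (what %in% c("Ainv", "both")) {
    ## Mendelian sampling variance d_i, with unknown parents as non-inbred
    ## founders contributing variance 1/4 each
    Fs <- ifelse(is.na(si), NA, Fcoef[si])
    Fd <- ifelse(is.na(di), NA, Fcoef[di])
    dvec <- 1 -
      ifelse(is.na(Fs), 0, 0.25 * (1 + Fs)) -
      ifelse(is.na(Fd), 0, 0.25 * (1 + Fd))
    if (any(dvec <= 0))
      stop("non-positive Mendelian sampling variance; pedigree may be corrupt")
    w <- 1 / dvec
    ii <- list(); jj <- list(); xx <- list()
    add <- function(i, j, x) {
      k <- length(ii) + 1L
      ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
    }
    idx <- seq_len(n)
    add(idx, idx, w)
    hs <- !is.na(si); hd <- !is.na(di)
    add(idx[hs], si[hs], -0.5 * w[hs]); add(si[hs], idx[hs], -0.5 * w[hs])
    add(idx[hd], di[hd], -0.5 * w[hd]); add(di[hd], idx[hd], -0.5 * w[hd])
    add(si[hs], si[hs], 0.25 * w[hs])
    add(di[hd], di[hd], 0.25 * w[hd])
    b <- hs & hd
    add(si[b], di[b], 0.25 * w[b]); add(di[b], si[b], 0.25 * w[b])
    Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                 x = unlist(xx), dims = c(n, n),
                                 dimnames = list(ped$id, ped$id), symmetric = FALSE)
    out$Ainv <- methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
  }
  class(out) <- "fitqg_relatedness"
  out
}

## Meuwissen & Luo (1992) inbreeding coefficients via the A = LDL'
## decomposition: a_ii = sum_j L_ij^2 D_j, F_i = a_ii - 1. L_i. is obtained
## by tracing ancestors of i (each ancestor j receives half the coefficient
## of each of its descendants on the path). No dense A is ever formed;
## cost is O(|ancestors|^2 log) per individual, cheap for shallow pedigrees.
inbreeding_ml <- function(di, si) {
  n <- length(di)
  Fcoef <- numeric(n)
  ## Mendelian sampling variance of j given parents' F (parents precede j)
  mendelian_d <- function(j) {
    s <- si[j]; d <- di[j]
    1 - (if (!is.na(s)) 0.25 * (1 + Fcoef[s]) else 0) -
        (if (!is.na(d)) 0.25 * (1 + Fcoef[d]) else 0)
  }
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(si[i]) || is.na(di[i])) next  # unknown parent => F = 0
    ## ancestor closure of i (including i), then accumulate L coefficients
    anc <- i
    frontier <- i
    while (length(frontier)) {
      p <- unique(stats::na.omit(c(si[frontier], di[frontier])))
      frontier <- setdiff(p, anc)
      anc <- c(anc, frontier)
    }
    anc <- sort(anc, decreasing = TRUE)
    v[anc] <- 0
    v[i] <- 1
    aii <- 0
    for (j in anc) {
      if (v[j] == 0) next
      if (!is.na(si[j])) v[si[j]] <- v[si[j]] + v[j] / 2
      if (!is.na(di[j])) v[di[j]] <- v[di[j]] + v[j] / 2
      aii <- aii + v[j]^2 * mendelian_d(j)
    }
    Fcoef[i] <- aii - 1
  }
  Fcoef
}
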