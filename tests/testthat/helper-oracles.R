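# Independent brute-force oracles used across the test files. These are
# deliberately naive implementations (recursion, enumeration) that share no
# code with the package internals.

# kinship coefficient by direct recursion on the pedigree;
# additive relatedness a_ij = 2 * kinship(i, j)
oracle_kinship <- function(ped) {
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  n <- nrow(ped)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      a <- max(i, j); b <- min(i, j)   # a is younger (topological order)
      0.5 * (phi(si[a], b) + phi(di[a], b))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in 1:i) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# ancestor closure by naive repeated expansion
oracle_ancestor_closure <- function(ped, ids) {
  keep <- ids
  repeat {
    parents <- with(ped, c(dam[id %in% keep], sire[id %in% keep]))
    parents <- setdiff(parents[!is.na(parents)], keep)
    if (!length(parents)) break
    keep <- c(keep, parents)
  }
  sort(keep)
}

# sibling pair counts by enumerating all unordered pairs
oracle_sib_pairs <- function(ped) {
  n <- nrow(ped)
  fs <- ph <- mh <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    same_sire <- !is.na(ped$sire[i]) && !is.na(ped$sire[j]) &&
      ped$sire[i] == ped$sire[j]
    same_dam <- !is.na(ped$dam[i]) && !is.na(ped$dam[j]) &&
      ped$dam[i] == ped$dam[j]
    if (same_sire) ph <- ph + 1L
    if (same_dam) mh <- mh + 1L
    if (same_sire && same_dam) fs <- fs + 1L
  }
  list(full = fs, paternal = ph, maternal = mh)
}

# random valid pedigree: each individual may draw parents from earlier ones
random_pedigree <- function(n, p_known = 0.7, seed = 1) {
  set.seed(seed)
  id <- sprintf("x%03d", seq_len(n))
  dam <- sire <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < p_known) dam[i] <- id[sample.int(i - 1, 1)]
    if (runif(1) < p_known) {
      cand <- setdiff(seq_len(i - 1), match(dam[i], id))
      if (length(cand)) sire[i] <- id[sample(cand, 1)]
    }
  }
  pedigree(id, dam, sire)
}

# a small pedigree used by several sampler tests
toy_pedigree <- function(n_founders = 6, n_gen = 3, kids_per_pair = 3,
                         seed = 1) {
  set.seed(seed)
  id <- sprintf("f%d", seq_len(n_founders))
  dam <- sire <- rep(NA_character_, n_founders)
  cohort <- rep(1L, n_founders)
  pool <- id
  cnt <- n_founders
  for (g in seq_len(n_gen - 1)) {
    np <- length(pool) %/% 2
    kids_d <- kids_s <- kids_id <- character(0)
    for (k in seq_len(np)) {
      pair <- sample(pool, 2)
      kid_n <- rpois(1, kids_per_pair - 1) + 1
      kids_id <- c(kids_id, sprintf("g%d_%d_%d", g, k, seq_len(kid_n)))
      kids_d <- c(kids_d, rep(pair[1], kid_n))
      kids_s <- c(kids_s, rep(pair[2], kid_n))
    }
    id <- c(id, kids_id); dam <- c(dam, kids_d); sire <- c(sire, kids_s)
    cohort <- c(cohort, rep(g + 1L, length(kids_id)))
    pool <- kids_id
  }
  pedigree(id, dam, sire, cohort)
}
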