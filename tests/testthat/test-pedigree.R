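test_that("pedigree construction validates, sorts and inserts phantom founders", {
  ## child listed before parents: order invariance after topological sort
  p1 <- pedigree(c("kid", "mum", "dad"), c("mum", NA, NA), c("dad", NA, NA))
  p2 <- pedigree(c("mum", "dad", "kid"), c(NA, NA, "mum"), c(NA, NA, "dad"))
  expect_identical(p1[order(p1$id), ], p2[order(p2$id), ])
  expect_true(match("kid", p1$id) > max(match(c("mum", "dad"), p1$id)))

  expect_error(pedigree(c("a", "a"), NA, NA), "duplicate")
  expect_error(pedigree(c("a", "b"), c("b", "a"), c(NA, NA)), "cycle")
  expect_error(pedigree(c("a", "b"), c(NA, "a"), c(NA, NA),
                        cohort = c(5, 3)), "cohort")

  ## a sire with no own record becomes a founder, with a warning
  expect_warning(p3 <- pedigree(c("a", "b"), c(NA, "a"), c(NA, "ghost")),
                 "founder")
  expect_equal(nrow(p3), 3)
  expect_true(is.na(p3$sire[p3$id == "ghost"]))
})

test_that("read_pedigree round-trips and honours missing-value sentinels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdam\tsire\tcohort",
               "m\t0\tNA\t1", "d\t\t0\t1", "k\tm\td\t2"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "fitqg_pedigree")
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$dam[ped$id %in% c("m", "d")])))
  expect_equal(ped$dam[ped$id == "k"], "m")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, f2, sep = ",")
  expect_identical(as.data.frame(read_pedigree(f2)), as.data.frame(ped))
})

test_that("prune_to_phenotyped keeps exactly the ancestor closure", {
  ## chain: only last phenotyped -> all retained
  chain <- pedigree(letters[1:5], c(NA, letters[1:4]), NA)
  expect_equal(nrow(prune_to_phenotyped(chain, "e")), 5)

  ## unphenotyped childless sibling is removed
  ped <- pedigree(c("f1", "f2", "kid1", "kid2"), c(NA, NA, "f1", "f1"),
                  c(NA, NA, "f2", "f2"))
  pruned <- prune_to_phenotyped(ped, c("kid1", "f1", "f2"))
  expect_setequal(pruned$id, c("f1", "f2", "kid1"))

  expect_error(prune_to_phenotyped(ped, character(0)), "empty")
  expect_error(prune_to_phenotyped(ped, "nobody"), "not in pedigree")

  ## random pedigrees: equality with brute-force closure, and idempotence
  for (seed in 1:4) {
    rped <- random_pedigree(50, seed = seed)
    set.seed(seed + 100)
    phen <- sample(rped$id, 10)
    pruned <- prune_to_phenotyped(rped, phen)
    expect_setequal(pruned$id, oracle_ancestor_closure(rped, phen))
    again <- prune_to_phenotyped(pruned, phen)
    expect_identical(as.data.frame(again), as.data.frame(pruned))
  }
})

test_that("pedigree summary counts match enumeration", {
  ## two founders with three joint offspring: C(3,2) = 3 pairs everywhere
  ped <- pedigree(c("f", "m", "k1", "k2", "k3"),
                  c(NA, NA, "f", "f", "f"), c(NA, NA, "m", "m", "m"))
  s <- summary(ped)
  expect_equal(s$n_paternities, 3)
  expect_equal(s$n_maternities, 3)
  expect_equal(s$n_fullsibs, 3)
  expect_equal(s$n_paternal_halfsib_pairs_incl_full, 3)
  expect_equal(s$n_maternal_halfsib_pairs_incl_full, 3)
  expect_equal(s$max_depth, 2)

  ## founders only
  s0 <- summary(pedigree(c("a", "b"), NA, NA))
  expect_equal(s0$max_depth, 1)
  expect_equal(s0$n_fullsibs + s0$n_paternities + s0$n_maternities, 0)

  ## random pedigrees vs brute-force pair enumeration
  for (seed in 1:3) {
    rped <- random_pedigree(80, seed = seed)
    s <- summary(rped)
    o <- oracle_sib_pairs(rped)
    expect_equal(s$n_fullsibs, o$full)
    expect_equal(s$n_paternal_halfsib_pairs_incl_full, o$paternal)
    expect_equal(s$n_maternal_halfsib_pairs_incl_full, o$maternal)
    expect_equal(s$n_paternities, sum(!is.na(rped$sire)))
    expect_true(s$n_fullsibs <= min(o$paternal, o$maternal))
  }
})

test_that("tabular A matches hand-worked and path-counting values", {
  ## parent-offspring 0.5, full sibs 0.5, half sibs 0.25
  ped <- pedigree(c("d", "s", "s2", "x", "y", "h"),
                  c(NA, NA, NA, "d", "d", "d"),
                  c(NA, NA, NA, "s", "s", "s2"))
  A <- additive_relationship(ped, what = "A")$A
  expect_equal(A["d", "x"], 0.5)
  expect_equal(A["x", "y"], 0.5)
  expect_equal(A["x", "h"], 0.25)
  expect_equal(unname(diag(A)), rep(1, 6))

  ## offspring of full-sib mating: F = 0.25, diagonal 1.25
  ped2 <- pedigree(c("d", "s", "x", "y", "z"), c(NA, NA, "d", "d", "x"),
                   c(NA, NA, "s", "s", "y"))
  rs <- additive_relationship(ped2, what = "both")
  expect_equal(rs$F[rs$ids == "z"], 0.25)
  expect_equal(rs$A["z", "z"], 1.25)

  ## unrelated founders -> identity
  expect_equal(additive_relationship(pedigree(letters[1:4], NA, NA),
                                     what = "A")$A,
               diag(4), ignore_attr = TRUE)

  ## random pedigrees <= 20: equality with 2x kinship recursion
  for (seed in 1:4) {
    rped <- random_pedigree(20, seed = seed)
    A <- additive_relationship(rped, what = "A")$A
    expect_equal(A, oracle_kinship(rped), tolerance = 1e-12)
  }
})

test_that("sparse A-inverse actually inverts A", {
  for (seed in 1:3) {
    rped <- random_pedigree(200, p_known = 0.8, seed = seed)
    rs <- additive_relationship(rped, what = "both")
    prod <- as.matrix(rs$Ainv %*% rs$A)
    expect_lt(max(abs(prod - diag(nrow(rped)))), 1e-8)
  }
})
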