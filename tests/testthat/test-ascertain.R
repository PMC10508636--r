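test_that("heterozygosity ascertainment keeps exactly dosage-1 sites", {
  calls <- rbind(c(1L, 0L), c(0L, 1L), c(2L, 1L), c(NA, 1L))
  gm <- make_gm(calls, pops = c("X", "Y"))
  id <- gm$ind$id[1]
  expect_equal(het_in_individual(gm, id)$keep, c(TRUE, FALSE, FALSE, FALSE))
  ## homozygous everywhere -> empty mask
  gm2 <- make_gm(rbind(c(0L, 1L), c(2L, 1L)), pops = c("X", "Y"))
  expect_equal(sum(het_in_individual(gm2, gm2$ind$id[1])$keep), 0)
  expect_error(het_in_individual(gm, "zzz"), "unknown individual")
})

test_that("panel unions are logical OR", {
  gm <- make_gm(matrix(0L, 7, 1), pops = "X")
  m1 <- site_mask(c(rep(TRUE, 3), rep(FALSE, 4)), "p1")
  m2 <- site_mask(c(rep(FALSE, 3), rep(TRUE, 4)), "p2")
  expect_equal(sum(union_panels(list(m1, m2))$keep), 7)
  empty <- site_mask(rep(FALSE, 7), "none")
  expect_equal(union_panels(list(m1, empty))$keep, m1$keep)
  expect_error(union_panels(list(m1, site_mask(TRUE, "short"))),
               "different matrices")
})

test_that("group polymorphism ascertainment pools non-missing calls", {
  calls <- rbind(c(0L, 0L, 0L),   # monomorphic ancestral
                 c(0L, 1L, 0L),   # polymorphic
                 c(2L, 2L, 2L),   # monomorphic derived
                 c(1L, NA, NA))   # single het, rest missing -> polymorphic
  gm <- make_gm(calls, pops = c("X", "X", "X"))
  m <- polymorphic_in_group(gm, gm$ind$id)
  expect_equal(m$keep, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(polymorphic_in_group(gm, character(0)), "empty")
})

test_that("heterozygous sites of a member are polymorphic in its group", {
  gm <- random_gm(300, c(X = 3, Y = 2), seed = 7)
  id <- gm$ind$id[gm$ind$pop == "X"][1]
  h <- het_in_individual(gm, id)$keep
  p <- polymorphic_in_group(gm, gm$ind$id[gm$ind$pop == "X"])$keep
  expect_true(all(p[h]))
})

test_that("MAF ascertainment folds to the minor allele with a strict threshold", {
  ## 25 diploids -> 50 chromosomes; derived copies 2/25/48/3
  ## -> frequencies 0.04 / 0.50 / 0.96 / 0.06
  gm <- make_gm(dosage_rows(c(2, 25, 48, 3), 25), pops = rep("X", 25))
  m <- maf_in_metapopulation(gm, "X", 0.05)
  expect_equal(m$keep, c(FALSE, TRUE, FALSE, TRUE))
  ## threshold 0 equals polymorphism in the pooled meta-population
  gm2 <- random_gm(200, c(X = 2, Y = 2), seed = 3)
  m0 <- maf_in_metapopulation(gm2, c("X", "Y"), 0)
  pg <- polymorphic_in_group(gm2, gm2$ind$id)
  expect_equal(m0$keep, pg$keep)
})

test_that("mutation-class masks agree with the site classes", {
  gm <- make_gm(matrix(0L, 3, 1), pops = "X",
                anc = c("A", "C", "A"), der = c("T", "T", "C"))
  expect_equal(atgc_only(gm)$keep, c(TRUE, FALSE, FALSE))
  expect_equal(transversions_only(gm)$keep, c(TRUE, FALSE, TRUE))
})

test_that("random thinning is exact, seeded and bounded", {
  gm <- make_gm(matrix(0L, 50, 1), pops = "X")
  m <- random_thin(gm, 10, seed = 5)
  expect_equal(sum(m$keep), 10)
  expect_identical(random_thin(gm, 10, seed = 5)$keep, m$keep)
  expect_false(identical(random_thin(gm, 10, seed = 6)$keep, m$keep))
  expect_equal(sum(random_thin(gm, 50, seed = 1)$keep), 50)
  expect_error(random_thin(gm, 51, seed = 1), "exceeds")
  ## thinning does not disturb the caller's RNG stream
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(random_thin(gm, 5, seed = 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("derived-frequency tail removal keeps the boundary", {
  ## 20 chromosomes with 0 / 10 / 19 / 20 derived copies
  ## -> DAF 0.00 / 0.50 / 0.95 (boundary, kept) / 1.00 (dropped)
  gm <- make_gm(dosage_rows(c(0, 10, 19, 20), 10), pops = rep("X", 10))
  m <- daf_tail_removal(gm, "X", 0.95)
  expect_equal(m$keep, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("fixed site lists match strictly on position and allele pair", {
  gm <- make_gm(matrix(0L, 3, 1), pops = "X",
                pos = c(100L, 200L, 300L),
                anc = c("A", "C", "G"), der = c("G", "T", "C"))
  lst <- file.path(tempdir(), "sites.tsv")
  ## empty list -> empty mask
  writeLines(character(0), lst)
  expect_equal(sum(fixed_site_list(gm, lst)$keep), 0)
  ## full list (allele order irrelevant) -> identity
  writeLines(c("1\t100\tG\tA", "1\t200\tC\tT", "1\t300\tG\tC"), lst)
  expect_true(all(fixed_site_list(gm, lst)$keep))
  ## allele mismatch at a matching position -> dropped with a warning
  writeLines(c("1\t100\tA\tG", "1\t200\tA\tG"), lst)
  expect_warning(m <- fixed_site_list(gm, lst), "allele mismatch")
  expect_equal(m$keep, c(TRUE, FALSE, FALSE))
})

test_that("masks are idempotent and invariant to individual order", {
  gm <- random_gm(200, c(X = 3, Y = 3), seed = 11)
  perm <- sample(ncol(gm$calls))
  gm2 <- gm
  gm2$calls <- gm$calls[, perm]
  gm2$ind <- gm$ind[perm, ]
  for (f in list(function(g) maf_in_metapopulation(g, c("X", "Y")),
                 function(g) polymorphic_in_group(g, g$ind$id[g$ind$pop == "X"]),
                 function(g) daf_tail_removal(g, "Y"))) {
    expect_identical(f(gm)$keep, f(gm2)$keep)
    sub <- apply_mask(gm, f(gm))
    expect_identical(f(sub)$keep[seq_len(n_sites(sub))],
                     rep(TRUE, n_sites(sub)))
  }
})
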