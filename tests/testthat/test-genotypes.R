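test_that("EIGENSTRAT round trip is bit-identical and codes map correctly", {
  gm <- make_gm(rbind(c(0L, 1L), c(2L, NA), c(1L, 0L)),
                pops = c("X", "Y"),
                anc = c("A", "C", "A"), der = c("T", "T", "G"))
  pre <- file.path(tempdir(), "rt")
  write_eigenstrat(gm, pre)
  ## missing is written as code 9
  expect_true(any(grepl("9", readLines(paste0(pre, ".geno")))))
  gm2 <- read_eigenstrat(pre)
  expect_identical(gm$calls, gm2$calls)
  expect_identical(gm$sites$pos, gm2$sites$pos)
  expect_identical(gm$sites$anc, gm2$sites$anc)
  expect_identical(gm$sites$der, gm2$sites$der)
  expect_identical(gm$ind$pop, gm2$ind$pop)
  ## second round trip equally stable
  pre2 <- file.path(tempdir(), "rt2")
  write_eigenstrat(gm2, pre2)
  expect_identical(readLines(paste0(pre, ".geno")), readLines(paste0(pre2, ".geno")))
})

test_that("EIGENSTRAT reader validates dimensions and codes", {
  gm <- make_gm(rbind(c(0L, 1L), c(2L, 0L)), pops = c("X", "Y"))
  pre <- file.path(tempdir(), "bad")
  write_eigenstrat(gm, pre)
  glines <- readLines(paste0(pre, ".geno"))
  writeLines(glines[-1], paste0(pre, ".geno"))
  expect_error(read_eigenstrat(pre), "geno rows")
  writeLines(c(glines[1], "37"), paste0(pre, ".geno"))
  expect_error(read_eigenstrat(pre), "unknown genotype code")
})

test_that("mutation classes partition biallelic SNPs", {
  gm <- make_gm(matrix(0L, 6, 1), pops = "X",
                anc = c("A", "G", "A", "C", "C", "G"),
                der = c("T", "C", "G", "T", "G", "T"))
  expect_equal(mutation_class(gm),
               c("AT/GC", "AT/GC", "transition", "transition",
                 "AT/GC", "transversion-other"))
  ## random allele pairs: classes exhaustive and mutually exclusive
  set.seed(1)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, 200, TRUE)
  der <- vapply(anc, function(a) sample(setdiff(bases, a), 1), "")
  gm2 <- make_gm(matrix(0L, 200, 1), pops = "X", anc = anc, der = unname(der))
  cl <- mutation_class(gm2)
  expect_true(all(cl %in% c("AT/GC", "transition", "transversion-other")))
  m <- apply_mask(gm2, atgc_only(gm2))
  expect_true(all(mutation_class(m) == "AT/GC"))
})

test_that("polarize relabels by the outgroup allele and drops unusable sites", {
  ## outgroup hom-derived at site 1 (flip), het at site 2 (drop),
  ## missing at site 3 (drop), hom-ancestral at site 4 (keep)
  calls <- rbind(c(2L, 1L, 0L), c(1L, 2L, 2L), c(NA, 1L, 1L), c(0L, 2L, 1L))
  gm <- make_gm(calls, pops = c("out", "X", "X"),
                anc = c("A", "A", "A", "A"), der = c("G", "G", "G", "G"))
  out_id <- gm$ind$id[gm$ind$pop == "out"]
  pg <- polarize(gm, out_id)
  expect_equal(n_sites(pg), 2)
  ## flipped site: dosages become 2 - d, alleles swapped
  expect_equal(unname(pg$calls[1, ]), c(0L, 1L, 2L))
  expect_equal(pg$sites$anc[1], "G")
  expect_equal(pg$sites$der[1], "A")
  ## untouched site
  expect_equal(unname(pg$calls[2, ]), c(0L, 2L, 1L))
  ## applying twice with the same outgroup is the same as once
  expect_identical(polarize(pg, out_id)$calls, pg$calls)
  expect_error(polarize(gm, "nobody"), "unknown individual")
})

test_that("block assignment follows per-chromosome floor arithmetic", {
  gm <- make_gm(matrix(0L, 4, 1), pops = "X",
                chrom = c("1", "1", "1", "2"),
                pos = c(1L, 3999999L, 4000001L, 100L))
  b <- assign_blocks(gm, 4e6)
  expect_equal(b$block, c(1L, 1L, 2L, 3L))
  ## two chromosomes of 100 Mb with sites everywhere -> 50 blocks
  pos <- seq(1, 1e8, by = 2e6)
  gm2 <- make_gm(matrix(0L, 2 * length(pos), 1), pops = "X",
                 chrom = rep(c("1", "2"), each = length(pos)),
                 pos = rep(pos, 2))
  expect_equal(assign_blocks(gm2, 4e6)$n_blocks, 50L)
  ## all sites within 1 Mb -> a single block
  gm3 <- make_gm(matrix(0L, 10, 1), pops = "X", pos = seq(1000L, 999000L,
                                                          length.out = 10))
  expect_equal(assign_blocks(gm3, 4e6)$n_blocks, 1L)
})

test_that("group-level missingness keeps sites with any called member", {
  calls <- rbind(c(NA, NA, 0L), # missing in all of X -> dropped
                 c(1L, NA, 0L), # one of two X called -> kept
                 c(0L, 1L, NA)) # Y missing -> dropped if Y listed
  gm <- make_gm(calls, pops = c("X", "X", "Y"))
  m <- filter_missing(gm, c("X", "Y"))
  expect_equal(m$keep, c(FALSE, TRUE, FALSE))
  ## empty population list keeps everything
  expect_true(all(filter_missing(gm, character(0))$keep))
  ## strict per-individual variant
  m2 <- filter_missing(gm, "X", level = "individual")
  expect_equal(m2$keep, c(FALSE, FALSE, TRUE))
  expect_error(filter_missing(gm, "Z"), "unknown population")
})

test_that("VCF import yields derived dosages for biallelic SNPs", {
  skip_if_not_installed("vcfR")
  vcf <- file.path(tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
    "1\t200\t.\tC\tT\t.\t.\t.\tGT\t1/1\t./.",
    "1\t300\t.\tG\tC\t.\t.\t.\tGT\t0|1\t1|1"), vcf)
  gm <- read_vcf_genotypes(vcf)
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(unname(gm$calls[, 1]), c(0L, 2L, 1L))
  expect_equal(unname(gm$calls[2, 2]), NA_integer_)
  expect_equal(gm$sites$pos, c(100L, 200L, 300L))
})

test_that("mask composition and provenance behave algebraically", {
  gm <- make_gm(matrix(c(0L, 1L, 2L, 1L), 4, 1), pops = "X")
  m1 <- site_mask(c(TRUE, TRUE, FALSE, TRUE), "a")
  m2 <- site_mask(c(TRUE, FALSE, FALSE, TRUE), "b")
  expect_equal(mask_and(m1, m2)$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sum(apply_mask(gm, m2)$calls), 0L + 1L)
  pv <- jsonlite::fromJSON(mask_provenance(m1))
  expect_equal(pv$n_kept, 3)
})
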