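test_that("the unbiased f2 estimator matches hand evaluation", {
  ## one site: pA = 0.5 from 4 chromosomes, pB = 0 from 4 chromosomes
  ## f2 = 0.25 - 0.5*0.5/3 - 0 = 1/6
  gm <- make_gm(rbind(c(1L, 1L, 0L, 0L)), pops = c("A", "A", "B", "B"))
  b <- assign_blocks(gm)
  f2b <- f2_blocks(gm, b)
  expect_equal(f2b$est[1, 1], 1 / 6, tolerance = 1e-12)
  ## fixation limit: pA = 1, pB = 0 with large n -> f2 -> 1
  gm2 <- make_gm(matrix(c(rep(2L, 20), rep(0L, 20)), 1), pops = rep(c("A", "B"),
                                                                    each = 20))
  f2b2 <- f2_blocks(gm2, assign_blocks(gm2))
  expect_equal(f2b2$est[1, 1], 1, tolerance = 1e-12)
})

test_that("identical samples give f2 centered near zero", {
  ## split one panmictic sample into two pseudo-populations: both are
  ## binomial draws from the same per-site frequencies, so f2 is null
  gm <- random_gm(4000, c(X = 8), seed = 2, n_chrom = 4)
  gm$ind$pop <- rep(c("A", "B"), 4)
  f2b <- f2_blocks(gm, assign_blocks(gm, 5e4))
  r <- f2_stat(f2b, "A", "B")
  expect_lt(abs(r$est), 3 * r$se + 1e-12)
})

test_that("f4 identities hold exactly per block", {
  gm <- random_gm(2000, c(A = 3, B = 3, C = 3, D = 3, E = 3), seed = 5)
  blocks <- assign_blocks(gm, 2e5)
  f2b <- f2_blocks(gm, blocks)
  f4ab <- f4(f2b, "A", "B", "A", "B")
  expect_equal(f4ab$blocks, f2_stat(f2b, "A", "B")$blocks, tolerance = 1e-14)
  expect_equal(f4(f2b, "A", "A", "C", "D")$blocks,
               rep(0, length(f4ab$blocks)))
  expect_equal(f4(f2b, "A", "B", "C", "D")$blocks,
               -f4(f2b, "B", "A", "C", "D")$blocks, tolerance = 1e-14)
  expect_equal(f4(f2b, "A", "B", "C", "D")$blocks,
               -f4(f2b, "A", "B", "D", "C")$blocks, tolerance = 1e-14)
  ## additivity: f4(A,B;C,D) + f4(A,B;D,E) = f4(A,B;C,E)
  expect_equal(f4(f2b, "A", "B", "C", "D")$blocks +
               f4(f2b, "A", "B", "D", "E")$blocks,
               f4(f2b, "A", "B", "C", "E")$blocks, tolerance = 1e-12)
  ## f3 is the shared-drift specialization
  expect_equal(f3(f2b, "A", "B", "C")$blocks,
               f4(f2b, "A", "B", "A", "C")$blocks, tolerance = 1e-14)
})

test_that("f2-combination equals the direct per-site f4 oracle", {
  gm <- random_gm(3000, c(A = 3, B = 3, C = 3, D = 3), seed = 9)
  blocks <- assign_blocks(gm, 2e5)
  f2b <- f2_blocks(gm, blocks)
  direct <- oracle_f4_blocks(gm, blocks, "A", "B", "C", "D")
  expect_equal(f4(f2b, "A", "B", "C", "D")$blocks, direct, tolerance = 1e-12)
})

test_that("weighted jackknife reduces to the classical formula", {
  ## equal values -> estimate c, SE 0
  jk <- jackknife(rep(3.2, 10), rep(5, 10))
  expect_equal(jk$est, 3.2)
  expect_equal(jk$se, 0)
  ## equal weights: jackknife SE of the mean equals s/sqrt(m) exactly
  set.seed(4)
  ratios <- replicate(100, {
    v <- rnorm(25)
    jackknife(v, rep(7, 25))$se / (sd(v) / sqrt(25))
  })
  expect_equal(max(abs(ratios - 1)), 0, tolerance = 1e-9)
  expect_error(jackknife(1, 1), "at least 2")
  ## covariance of a statistic with itself is its variance
  v1 <- rnorm(30); v2 <- rnorm(30); w <- runif(30, 10, 100)
  cv <- jackknife_cov(rbind(v1, v2), w)
  expect_equal(cv[1, 1], jackknife(v1, w)$se^2, tolerance = 1e-10)
  expect_equal(cv[2, 2], jackknife(v2, w)$se^2, tolerance = 1e-10)
  expect_equal(cv[1, 2], cv[2, 1])
})

test_that("Hudson FST behaves at the null and at fixation", {
  ## fixed difference at one site, large samples -> FST ~ 1
  gm <- make_gm(matrix(c(rep(2L, 20), rep(0L, 20)), 1),
                pops = rep(c("A", "B"), each = 20))
  expect_equal(fst_hudson(gm, "A", "B")$est, 1, tolerance = 1e-2)
  ## pooling subsamples of one deme -> FST within noise of 0
  gm2 <- random_gm(4000, c(X = 8), seed = 12, n_chrom = 4)
  gm2$ind$pop <- rep(c("A", "B"), 4)
  r <- fst_hudson(gm2, "A", "B", blocks = assign_blocks(gm2, 5e4))
  expect_lt(abs(r$est), 3 * r$se + 1e-12)
  ## zero denominator is an error
  gm3 <- make_gm(rbind(c(0L, 0L, 0L, 0L)), pops = c("A", "A", "B", "B"))
  expect_error(fst_hudson(gm3, "A", "B"), "denominator")
})

test_that("DAF spectra are hypergeometric projections", {
  ## all fixed ancestral -> all mass in bin 0
  gm <- make_gm(matrix(0L, 5, 12), pops = rep("X", 12))
  sp <- daf_spectrum(gm, "X", 20)
  expect_equal(sp$prop[1], 1)
  expect_equal(sum(sp$prop), 1)
  ## frequency 1/2 projected to 2 chromosomes: (1/4, 1/2, 1/4) in the
  ## without-replacement limit of a large sample
  gm2 <- make_gm(dosage_rows(20, 20), pops = rep("X", 20))
  sp2 <- daf_spectrum(gm2, "X", 2)
  ## exact: hypergeometric(20 of 40, draw 2) = (190, 400, 190)/780
  expect_equal(sp2$prop, c(190, 400, 190) / 780, tolerance = 1e-12)
  expect_equal(sp2$prop, c(0.25, 0.5, 0.25), tolerance = 0.03)
  ## projection to the full sample size returns the raw counts
  gm3 <- make_gm(dosage_rows(c(1, 3), 4), pops = rep("X", 4))
  sp3 <- daf_spectrum(gm3, "X", 8)
  expect_equal(sp3$prop, c(0, 0.5, 0, 0.5, rep(0, 5)))
  expect_error(daf_spectrum(gm3, "X", 9), "chromosomes")
})

test_that("the site cache reproduces f2_blocks under any mask", {
  gm <- random_gm(3000, c(A = 3, B = 3, C = 3), seed = 4)
  blocks <- assign_blocks(gm, 2e5)
  cache <- f2_site_cache(gm, blocks)
  for (s in 1:3) {
    msk <- random_thin(gm, 1200, seed = s)
    a <- f2_blocks(gm, blocks, mask = msk)
    b <- f2_blocks_masked(cache, msk)
    expect_equal(a$est, b$est, tolerance = 1e-12)
    expect_equal(a$block_sites, b$block_sites)
    expect_equal(a$pairs, b$pairs)
  }
  expect_equal(f2_blocks_masked(cache)$est, f2_blocks(gm, blocks)$est,
               tolerance = 1e-12)
})
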