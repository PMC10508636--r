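# Simulation tests run small genomes; the coalescent engine is exercised
# through the bundled driver exactly as in the analysis scripts.

test_that("simulation is deterministic given the seed", {
  model <- fast_tree_model(chrom_mb = 1)
  s1 <- simulate_model(model, seed = 77)
  s2 <- simulate_model(model, seed = 77)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$genotypes$sites, s2$genotypes$sites)
  s3 <- simulate_model(model, seed = 78)
  expect_false(identical(s1$genotypes$calls, s3$genotypes$calls))
})

test_that("panmictic diversity matches the neutral expectation 4*Ne*mu", {
  ne <- 10000
  model <- demographic_model(
    data.frame(name = "X", ne = ne), list(),
    data.frame(pop = "X", n = 5, time = 0),
    genome_spec(1, 4e6))
  pis <- vapply(1:6, function(s) {
    gm <- simulate_model(model, seed = 500 + s)$genotypes
    p <- oracle_freqs(gm, "X")
    n <- 10
    sum(2 * p * (1 - p) * n / (n - 1)) / 4e6
  }, numeric(1))
  expected <- 4 * ne * 1.25e-8
  mc_se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * mc_se + 0.02 * expected)
})

test_that("two subsamples of one population are exchangeable", {
  ne <- 10000
  model <- demographic_model(
    data.frame(name = "X", ne = ne), list(),
    data.frame(pop = "X", n = 8, time = 0),
    genome_spec(1, 3e6))
  gm <- simulate_model(model, seed = 31)$genotypes
  gm$ind$pop <- rep(c("A", "B"), 4)
  blocks <- assign_blocks(gm, 2.5e5)
  f2b <- f2_blocks(gm, blocks)
  r <- f2_stat(f2b, "A", "B")
  expect_lt(abs(r$est), 3 * r$se)
  fst <- fst_hudson(gm, "A", "B", blocks = blocks)
  expect_lt(abs(fst$est), 3 * fst$se)
})

test_that("diverged populations have positive f2 and symmetric f4 zero", {
  model <- fast_tree_model(chrom_mb = 3)
  sim <- simulate_model(model, seed = 90)
  gm <- sim$genotypes
  blocks <- assign_blocks(gm, 2.5e5)
  f2b <- f2_blocks(gm, blocks)
  expect_gt(f2_stat(f2b, "A", "C")$z, 3)
  ## on the true tree ((A,B),(C,O)) the cladality statistic is null
  expect_lt(abs(f4(f2b, "A", "B", "C", "O")$z), 4)
})

test_that("random-graph presets respect the stated parameter ranges", {
  alphas <- c(); gaps <- c(); og_times <- c()
  for (s in 1:25) {
    m <- preset_random_graph(9, 4, seed = s)
    pulses <- Filter(function(e) e$type == "pulse", m$events)
    splits <- Filter(function(e) e$type == "split", m$events)
    alphas <- c(alphas, vapply(pulses, `[[`, 0, "prop"))
    og <- Filter(function(e) "outgroup" %in% unlist(e["derived"]), splits)
    og_times <- c(og_times, og[[1]]$time)
    expect_length(pulses, 4)
    ## sizes within [2000, 40000] except the outgroup
    ne <- m$populations$ne[m$populations$name != "outgroup"]
    expect_true(all(ne >= 2000 & ne <= 40000))
    expect_equal(m$populations$ne[m$populations$name == "outgroup"], 1e5)
    ## event gaps between parent and child nodes
    tm <- m$times
    for (nd in names(tm)) expect_gte(tm[[nd]], 0)
    ## truth graph: 9 leaves, 4 admixture nodes
    expect_length(m$graph$leaves, 9)
    expect_length(m$graph$admix_nodes, 4)
  }
  expect_true(all(alphas >= 0.10 & alphas <= 0.40))
  expect_true(all(og_times == 40000))
  ## drifted-outgroup variant
  m2 <- preset_random_graph(10, 5, seed = 3, outgroup_ne = 1000)
  expect_equal(m2$populations$ne[m2$populations$name == "outgroup"], 1000)
  expect_length(m2$graph$leaves, 10)
  expect_length(m2$graph$admix_nodes, 5)
})

test_that("simple-tree preset encodes the bottleneck design", {
  m1 <- preset_simple_tree(1)
  expect_true(all(m1$populations$ne == 1e5))
  expect_equal(m1$samples$n, c(25, 25, 25, 10))
  m100 <- preset_simple_tree(100)
  expect_equal(m100$populations$ne[m100$populations$name == "A"], 1000)
  ab <- Filter(function(e) setequal(unlist(e["derived"]), c("A", "B")),
               m100$events)
  expect_equal(ab[[1]]$time, 1999)
  depth <- Filter(function(e) "O" %in% unlist(e["derived"]), m100$events)
  expect_equal(depth[[1]]$time, 4000)
  m4 <- preset_simple_tree(10000)
  expect_equal(m4$samples$n[m4$samples$pop == "A"], 10)
})

test_that("case-study preset encodes flow, sampling dates and truth graph", {
  m0 <- preset_case_study(0)
  expect_length(m0$graph$admix_nodes, 0)
  expect_false(any(vapply(m0$events, `[[`, "", "type") == "pulse"))
  m2 <- preset_case_study(0.02)
  expect_length(m2$graph$admix_nodes, 1)
  pulse <- Filter(function(e) e$type == "pulse", m2$events)[[1]]
  expect_equal(pulse$prop, 0.02)
  st <- m2$samples
  expect_equal(st$time[st$pop %in% c("nea1", "nea2", "den")],
               c(3790, 1700, 1700))
  expect_setequal(m2$graph$leaves,
                  c("chimp", "nea1", "nea2", "den", "afr1", "afr2",
                    "nonafr1", "nonafr2"))
})

test_that("the FST retention rule keeps close pairs and drops distant sets", {
  model <- fast_tree_model(chrom_mb = 1)
  sim <- simulate_model(model, seed = 55)
  ## threshold 1 always retains
  expect_true(retain_by_fst(sim, threshold = 1, exclude = character(0)))
  ## these populations are close (small Ne drift over few hundred gens)
  expect_true(retain_by_fst(sim, threshold = 0.15, exclude = character(0)))
  ## an impossible threshold rejects
  expect_false(retain_by_fst(sim, threshold = -1, exclude = character(0)))
})
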