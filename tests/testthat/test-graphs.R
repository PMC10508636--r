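two_leaf_graph <- function() {
  admixture_graph(data.frame(from = c("R", "R"), to = c("A", "B")))
}

test_that("expected f2 is the drift path sum on trees", {
  g <- two_leaf_graph()
  F2 <- expected_f2_matrix(g, c("R->A" = 0.03, "R->B" = 0.07))
  expect_equal(F2["A", "B"], 0.1)
  ## 4-leaf tree: additive path distances
  g4 <- admixture_graph(data.frame(
    from = c("R", "R", "X", "X", "Y", "Y"),
    to = c("A", "X", "B", "Y", "C", "D")))
  len <- c("R->A" = 0.05, "R->X" = 0.01, "X->B" = 0.04, "X->Y" = 0.02,
           "Y->C" = 0.03, "Y->D" = 0.06)
  F2 <- expected_f2_matrix(g4, len)
  expect_equal(F2["A", "B"], 0.05 + 0.01 + 0.04)
  expect_equal(F2["C", "D"], 0.09)
  expect_equal(F2["A", "D"], 0.05 + 0.01 + 0.02 + 0.06)
  expect_error(expected_f2_matrix(g4, len[-1]), "missing drift edge")
})

test_that("admixed leaves mix parental paths by the admixture proportion", {
  ## M draws alpha from the P1 side and 1 - alpha from the P2 side
  g <- admixture_graph(data.frame(
    from = c("R", "R", "P1", "P2", "M", "P1", "P2"),
    to = c("P1", "P2", "M", "M", "Mleaf", "L1", "L2")))
  al <- 0.3  # proportion from P1 (alphabetically first parent)
  len <- c("R->P1" = 0.02, "R->P2" = 0.08, "M->Mleaf" = 0.01,
           "P1->L1" = 0.005, "P2->L2" = 0.005)
  F2 <- expected_f2_matrix(g, len, alpha = c(M = al))
  ## hand-derived edge decomposition of f4(L1, L2; Mleaf, L2): the Mleaf
  ## lineage traverses the P1-side root edge with probability alpha and the
  ## P2-side with 1 - alpha, giving
  ##   alpha * (len(R->P1) + len(R->P2)) + len(P2->L2)
  f4_ml <- 0.5 * (F2["L1", "L2"] + F2["Mleaf", "L2"] -
                  F2["L1", "Mleaf"] - 0)
  expect_equal(f4_ml,
               al * (len[["R->P1"]] + len[["R->P2"]]) + len[["P2->L2"]],
               tolerance = 1e-12)
})

test_that("noise-free synthetic data is fitted exactly", {
  g4 <- admixture_graph(data.frame(
    from = c("R", "R", "X", "X", "Y", "Y"),
    to = c("A", "X", "B", "Y", "C", "D")))
  len <- c("R->A" = 0.05, "R->X" = 0.01, "X->B" = 0.04, "X->Y" = 0.02,
           "Y->C" = 0.03, "Y->D" = 0.06)
  f2b <- f2_blocks_from_graph(g4, len, n_blocks = 10)
  fit <- fit_graph(g4, f2b, seed = 1)
  expect_lt(fit$ll, 1e-4)
  expect_lt(fit$wr, 1e-2)
  ## identifiable quantities (pairwise distances) recovered to 1e-4
  F2fit <- expected_f2_matrix(g4, fit$lengths, fit$alpha)
  F2true <- expected_f2_matrix(g4, len)
  expect_equal(F2fit, F2true, tolerance = 1e-4)
})

test_that("admixture proportions are recovered when identifiable", {
  ## with two leaves descending from the admixture node (and reference
  ## lineages on both parent sides) the proportion is point-identified;
  ## with a single admixed leaf below a free terminal edge it is only
  ## interval-identified, a known property of f-statistic graph models
  g <- admixture_graph(data.frame(
    from = c("R", "R", "S", "S", "T", "T", "U", "U", "V", "V", "M", "M"),
    to = c("O", "S", "A", "T", "U", "V", "B", "M", "C", "M", "X1", "X2")))
  len <- c("R->O" = 0.05, "R->S" = 0.01, "S->A" = 0.03, "S->T" = 0.02,
           "T->U" = 0.04, "T->V" = 0.05, "U->B" = 0.03, "V->C" = 0.02,
           "M->X1" = 0.015, "M->X2" = 0.01)
  f2b <- f2_blocks_from_graph(g, len, alpha = c(M = 0.4), n_blocks = 10)
  fit <- fit_graph(g, f2b, numstart = 30, seed = 2)
  expect_lt(fit$ll, 1e-3)
  expect_equal(unname(fit$alpha["M"]), 0.4, tolerance = 0.02)
})

test_that("the fit score is invariant to re-rooting along a drift path", {
  len_a <- c("R->A" = 0.05, "R->X" = 0.01, "X->B" = 0.04, "X->Y" = 0.02,
             "Y->C" = 0.03, "Y->D" = 0.06)
  g_a <- admixture_graph(data.frame(
    from = c("R", "R", "X", "X", "Y", "Y"),
    to = c("A", "X", "B", "Y", "C", "D")))
  ## same unrooted topology rooted on the Y-C edge instead
  g_b <- admixture_graph(data.frame(
    from = c("R2", "R2", "Y", "X", "X", "Y"),
    to = c("C", "Y", "X", "A", "B", "D")))
  f2b <- f2_blocks_from_graph(g_a, len_a, n_blocks = 12, jitter = 2e-4,
                              mode = "noise")
  fit_a <- fit_graph(g_a, f2b, seed = 3)
  fit_b <- fit_graph(g_b, f2b, seed = 3)
  expect_equal(fit_a$ll, fit_b$ll, tolerance = 1e-6)
  expect_equal(fit_a$wr, fit_b$wr, tolerance = 1e-4)
})

test_that("fitting the true tree to simulated data accepts the model", {
  model <- fast_tree_model(chrom_mb = 4)
  wrs <- vapply(1:6, function(s) {
    sim <- simulate_model(model, seed = 400 + s)
    blocks <- assign_blocks(sim$genotypes, 2.5e5)
    f2b <- f2_blocks(sim$genotypes, blocks)
    fit_graph(sim$graph, f2b, seed = 1)$wr
  }, numeric(1))
  ## the correct topology should essentially never be rejected
  expect_gte(sum(wrs < 3), 5)
  expect_lt(median(wrs), 3)
})

test_that("zero fit score implies zero worst residual", {
  g <- two_leaf_graph()
  f2b <- f2_blocks_from_graph(g, c("R->A" = 0.02, "R->B" = 0.01),
                              n_blocks = 6)
  fit <- fit_graph(g, f2b, seed = 1)
  expect_lt(fit$ll, 1e-6)
  expect_lt(fit$wr, 1e-3)
})

test_that("incorrect-graph sampling respects range, pool size and seed", {
  fits <- data.frame(topology = 1:500, ll = seq(1, 500))
  expect_warning(out <- sample_incorrect_graphs(fits, c(1000, 2000)),
                 "no topologies")
  expect_length(out, 0)
  expect_warning(out2 <- sample_incorrect_graphs(fits, c(70, 80), k = 100),
                 "only")
  expect_equal(sort(out2), 70:80)
  s1 <- sample_incorrect_graphs(fits, c(70, 300), k = 50, seed = 4)
  expect_length(s1, 50)
  expect_identical(s1, sample_incorrect_graphs(fits, c(70, 300), k = 50,
                                               seed = 4))
  expect_true(all(s1 >= 70 & s1 <= 300))
})

test_that("graph text formats round trip, including the qpGraph dialect", {
  g <- admixture_graph(data.frame(
    from = c("R", "R", "P1", "P2", "M", "P1", "P2"),
    to = c("P1", "P2", "M", "M", "Mleaf", "L1", "L2")))
  f <- file.path(tempdir(), "graph.txt")
  write_graph_text(g, f)
  g2 <- read_graph_text(f)
  expect_setequal(graph_leaves(g2), graph_leaves(g))
  expect_equal(sort(g2$admix_nodes), sort(g$admix_nodes))
  ## qpGraph-style dialect
  f2 <- file.path(tempdir(), "graph_qp.txt")
  writeLines(c("root R",
               "edge e1 R P1", "edge e2 R P2",
               "edge e3 P1 L1", "edge e4 P2 L2",
               "admix M P1 P2", "edge e5 M Mleaf"), f2)
  g3 <- read_graph_text(f2)
  expect_setequal(graph_leaves(g3), c("L1", "L2", "Mleaf"))
  expect_equal(g3$admix_nodes, "M")
})

test_that("graph validity is enforced", {
  expect_error(admixture_graph(data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle|root")
  expect_error(admixture_graph(data.frame(from = c("R", "R", "X"),
                                          to = c("X", "X", "X"))),
               "root|parents")
})
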