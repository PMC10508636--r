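# In-code fixtures: small deterministic genotype matrices and graphs.

## matrix with explicit dosages; rows sites, cols individuals
make_gm <- function(calls, pops, chrom = NULL, pos = NULL,
                    anc = NULL, der = NULL) {
  calls <- as.matrix(calls)
  ns <- nrow(calls)
  ids <- paste0(pops, "_", stats::ave(seq_along(pops), pops, FUN = seq_along))
  geno_matrix(calls,
              data.frame(chrom = chrom %||% rep("1", ns),
                         pos = pos %||% (seq_len(ns) * 1000L),
                         anc = anc %||% rep("A", ns),
                         der = der %||% rep("G", ns),
                         stringsAsFactors = FALSE),
              data.frame(id = ids, pop = pops, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random complete-data genotype matrix: sites x individuals, per-population
## allele frequencies drawn independently per site
random_gm <- function(n_sites, pops_n, seed = 1, n_chrom = 2) {
  set.seed(seed)
  pops <- rep(names(pops_n), unname(pops_n))
  ni <- length(pops)
  p <- matrix(stats::runif(n_sites * length(pops_n), 0.05, 0.95),
              n_sites, length(pops_n), dimnames = list(NULL, names(pops_n)))
  calls <- matrix(0L, n_sites, ni)
  for (j in seq_len(ni)) calls[, j] <- stats::rbinom(n_sites, 2, p[, pops[j]])
  chrom <- as.character(rep(seq_len(n_chrom), length.out = n_sites))
  chrom <- sort(chrom)
  make_gm(calls, pops, chrom = chrom,
          pos = unlist(lapply(table(chrom), seq_len)) * 50000L)
}

## per-site population frequencies for oracle computations
oracle_freqs <- function(gm, pop) {
  cols <- which(gm$ind$pop == pop)
  sub <- gm$calls[, cols, drop = FALSE]
  rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
}

## direct per-site f4 oracle (uncorrected cross product), averaged per block
oracle_f4_blocks <- function(gm, blocks, A, B, C, D) {
  v <- (oracle_freqs(gm, A) - oracle_freqs(gm, B)) *
       (oracle_freqs(gm, C) - oracle_freqs(gm, D))
  as.numeric(tapply(v, blocks$block, mean))
}

## rows of diploid dosages realizing given derived-copy counts
dosage_rows <- function(copies, n_dip) {
  t(vapply(copies, function(d) {
    x <- integer(n_dip); i <- 1
    while (d >= 2) { x[i] <- 2L; d <- d - 2; i <- i + 1 }
    if (d >= 1) x[i] <- 1L
    x
  }, integer(n_dip)))
}

## quick small-Ne demographic model of a 4-taxon tree for fitting tests
fast_tree_model <- function(chrom_mb = 5, ne = 12000) {
  pops <- data.frame(name = c("A", "B", "C", "O", "AB", "ABC", "ROOT"),
                     ne = ne)
  events <- list(
    list(type = "split", time = 600, derived = c("A", "B"), ancestral = "AB"),
    list(type = "split", time = 1400, derived = c("AB", "C"), ancestral = "ABC"),
    list(type = "split", time = 2600, derived = c("ABC", "O"), ancestral = "ROOT"))
  samples <- data.frame(pop = c("A", "B", "C", "O"), n = 5, time = 0)
  graph <- admixture_graph(data.frame(
    from = c("ROOT", "ROOT", "ABC", "ABC", "AB", "AB"),
    to = c("O", "ABC", "C", "AB", "A", "B"), stringsAsFactors = FALSE))
  demographic_model(pops, events, samples,
                    genome_spec(1, chrom_mb * 1e6), graph,
                    scenario = "fast-tree")
}

## synthetic f2 block data generated from a parameterized graph.
## mode "balanced": per-block values alternate around the exact expectation
## so the weighted estimate equals the graph value exactly while the
## jackknife covariance stays positive (a noise-free fixture with defined
## standard errors); mode "noise": iid Gaussian block noise.
f2_blocks_from_graph <- function(graph, lengths, alpha = NULL,
                                 n_blocks = 8, jitter = 1e-4,
                                 mode = c("balanced", "noise")) {
  mode <- match.arg(mode)
  stopifnot(mode != "balanced" || n_blocks %% 2 == 0)
  F2 <- expected_f2_matrix(graph, lengths, alpha)
  pops <- rownames(F2)
  pr <- utils::combn(length(pops), 2)
  est <- matrix(0, ncol(pr), n_blocks)
  set.seed(99)
  alt <- rep(c(1, -1), length.out = n_blocks)
  for (k in seq_len(ncol(pr))) {
    base <- F2[pr[1, k], pr[2, k]]
    est[k, ] <- base + switch(mode,
      balanced = stats::runif(1, 0.5, 1.5) * jitter * alt,
      noise = stats::rnorm(n_blocks, 0, jitter))
  }
  structure(list(est = est, cnt = matrix(1000, ncol(pr), n_blocks),
                 pairs = data.frame(a = pops[pr[1, ]], b = pops[pr[2, ]],
                                    stringsAsFactors = FALSE),
                 pops = pops, block_sites = rep(1000, n_blocks),
                 settings = list(correction = TRUE, min_ac2 = FALSE)),
            class = "f2_blocks_set")
}
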