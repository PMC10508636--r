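## Experiment orchestration: config-driven drivers for the three studies
## (case-study model, random admixture graphs, exhaustive topology scan).
## Every step is an exported package function; these runners wire them
## together, seed them reproducibly, and write plain-text artifacts.

#' Experiment configuration
#'
#' @param scenario One of `"case-study"`, `"random-graphs"`, `"simple-tree"`,
#'   `"exhaustive-scan"`.
#' @param seed Master integer seed.
#' @param genome A [genome_spec()].
#' @param iterations Number of simulation iterations / topologies.
#' @param numstart Graph-fit restarts (default 100).
#' @param wr_threshold Model-rejection threshold in SE (default 3).
#' @param out_dir Output directory (NULL: return results only).
#' @param ... Scenario-specific settings stored verbatim.
#' @export
experiment_config <- function(scenario, seed = 1, genome = genome_spec(),
                              iterations = 10, numstart = 100,
                              wr_threshold = 3, out_dir = NULL, ...) {
  structure(c(list(scenario = scenario, seed = seed, genome = genome,
                   iterations = iterations, numstart = numstart,
                   wr_threshold = wr_threshold, out_dir = out_dir),
              list(...)),
            class = "experiment_config")
}

write_artifact <- function(df, cfg, name) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, file.path(cfg$out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

## pick one individual id per population, seeded
pick_individuals <- function(gm, pops, seed) {
  vapply(seq_along(pops), function(i) {
    ids <- gm$ind$id[gm$ind$pop == pops[i]]
    ids[local_sample(seq_along(ids), 1, seed + i)]
  }, "")
}

#' Case-study ascertainment masks
#'
#' Builds the eight SNP-set definitions of the case-study experiment on a
#' simulated genotype matrix: unascertained, random subsample matching the
#' one-panel size, one-panel heterozygosity ascertainment (one individual
#' from the second African group), four-panel heterozygosity (one individual
#' per modern group), archaic polymorphism (the three archaic individuals),
#' and African / global / non-African MAF > 5%.
#'
#' @param gm Simulated case-study `geno_matrix`.
#' @param seed Seed for individual picks and thinning.
#' @return Named list of `site_mask` objects.
#' @export
case_study_masks <- function(gm, seed = 1) {
  amh <- c("afr1", "afr2", "nonafr1", "nonafr2")
  ho1_id <- pick_individuals(gm, "afr2", seed)
  ho4_ids <- pick_individuals(gm, amh, seed + 100)
  archaic_ids <- c(gm$ind$id[gm$ind$pop == "den"][1],
                   gm$ind$id[gm$ind$pop == "nea1"][1],
                   gm$ind$id[gm$ind$pop == "nea2"][1])
  ho1 <- het_in_individual(gm, ho1_id)
  masks <- list(
    unascertained = site_mask(rep(TRUE, n_sites(gm)), "unascertained"),
    subsampled = random_thin(gm, sum(ho1$keep), seed = seed + 200),
    ho1 = ho1,
    ho4 = union_panels(lapply(ho4_ids, function(id) het_in_individual(gm, id))),
    archaic = polymorphic_in_group(gm, archaic_ids),
    afr_maf = maf_in_metapopulation(gm, c("afr1", "afr2")),
    global_maf = maf_in_metapopulation(gm, amh),
    nonafr_maf = maf_in_metapopulation(gm, c("nonafr1", "nonafr2")))
  masks
}

#' Run the case-study experiment
#'
#' For each simulation iteration and each ascertainment scheme, fits the
#' full true admixture graph and the three single-archaic reductions, and
#' reports worst residuals and fit scores.
#'
#' @param config An [experiment_config()]; recognized extras:
#'   `neanderthal_flow` (default 0.02), `schemes` (subset of the
#'   [case_study_masks()] names; empty vector: unascertained baseline only),
#'   `reductions` (default the three archaic groups), `params_file`.
#' @return Data frame (iteration, scheme, graph, wr, ll, n_sites).
#' @export
run_case_study <- function(config) {
  flow <- config$neanderthal_flow %||% 0.02
  reductions <- config$reductions %||% c("nea1", "nea2", "den")
  model <- preset_case_study(flow, params_file = config$params_file,
                             genome = config$genome)
  schemes <- config$schemes %||% c("subsampled", "unascertained", "ho1",
                                   "ho4", "archaic", "afr_maf", "global_maf",
                                   "nonafr_maf")
  schemes <- union("unascertained", schemes)
  full_graph <- model$graph
  red_graphs <- lapply(reductions, function(a)
    prune_graph(full_graph, c("chimp", a, "afr1", "afr2", "nonafr1",
                              "nonafr2")))
  names(red_graphs) <- reductions
  out <- list()
  for (it in seq_len(config$iterations)) {
    sim <- simulate_model(model, seed = config$seed + it)
    gm <- sim$genotypes
    blocks <- assign_blocks(gm, config$block_size %||% 4e6)
    masks <- case_study_masks(gm, seed = config$seed * 1000 + it)
    cache <- f2_site_cache(gm, blocks)
    for (sc in schemes) {
      m <- masks[[sc]]
      f2b <- f2_blocks_masked(cache, m)
      fits <- c(list(full = fit_graph(full_graph, f2b,
                                      numstart = config$numstart,
                                      seed = config$seed + it)),
                lapply(red_graphs, function(g)
                  fit_graph(g, f2b, numstart = config$numstart,
                            seed = config$seed + it)))
      for (gname in names(fits))
        out[[length(out) + 1]] <- data.frame(
          iteration = it, scheme = sc, graph = gname,
          wr = fits[[gname]]$wr, ll = fits[[gname]]$ll,
          n_sites = sum(m$keep), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  write_artifact(res, config, "case_study_fits")
  res
}

#' Planned ascertained-dataset manifest of the random-graph study
#'
#' Enumerates, without simulating, every ascertained dataset the randomized
#' study design produces: one-panel heterozygosity ascertainment is repeated
#' for every sampled group of every simulation — the tip populations, the
#' outgroup, the true root and the non-outgroup root — while the four-panel,
#' three-individual-polymorphism and MAF schemes each use `n_random_sets`
#' random group sets per simulation (excluding the outgroup and the root
#' samples).
#'
#' @param n_per_class Simulations per graph complexity class (default 20).
#' @param classes List of c(n_pops, n_admix) complexity classes (default the
#'   four classes with 9 or 10 populations including the outgroup and 4 or 5
#'   admixture events).
#' @param n_random_sets Random group sets per simulation for the non-ho1
#'   schemes (default 10).
#' @return Data frame with one row per planned ascertained dataset
#'   (columns: class, sim, scheme, target).
#' @export
random_graph_design <- function(n_per_class = 20,
                                classes = list(c(9, 4), c(9, 5), c(10, 4),
                                               c(10, 5)),
                                n_random_sets = 10) {
  rows <- list()
  sim_id <- 0
  for (cl in classes) for (r in seq_len(n_per_class)) {
    sim_id <- sim_id + 1
    n_tips <- cl[1] - 1
    groups <- c(paste0("pop", seq_len(n_tips)), "outgroup", "root", "nonog")
    for (g in groups)
      rows[[length(rows) + 1]] <- data.frame(class = paste(cl, collapse = "-"),
                                             sim = sim_id, scheme = "ho1",
                                             target = g)
    for (sc in c("ho4", "poly3", "maf4")) for (k in seq_len(n_random_sets))
      rows[[length(rows) + 1]] <- data.frame(class = paste(cl, collapse = "-"),
                                             sim = sim_id, scheme = sc,
                                             target = sprintf("set%02d", k))
  }
  do.call(rbind, rows)
}

#' Run the random-graph study
#'
#' Simulates random admixture-graph histories (resampling until the
#' minimum-FST retention rule holds), applies one-panel heterozygosity
#' ascertainment on every sampled group (tips, outgroup, true root,
#' non-outgroup root), fits the true graph on each SNP set, and records the
#' Hudson FST between each ascertainment population and the root sample.
#'
#' @param config An [experiment_config()]; recognized extras: `classes`
#'   (list of c(n_pops, n_admix); default list(c(9,4))), `outgroup_ne`
#'   (default 1e5), `n_per_pop` (default 10), `fst_threshold` (0.15),
#'   `max_resample` (10).
#' @return List with `fits` (per topology x ascertainment) and `sims`
#'   (retention log).
#' @export
run_random_graph_study <- function(config) {
  classes <- config$classes %||% list(c(9, 4))
  fst_thr <- config$fst_threshold %||% 0.15
  out <- list(); simlog <- list()
  topo_id <- 0
  for (cl in classes) {
    for (r in seq_len(config$iterations)) {
      topo_id <- topo_id + 1
      ## resample until the FST retention rule holds
      attempt <- 0; sim <- NULL
      repeat {
        attempt <- attempt + 1
        sd <- config$seed + 7919 * topo_id + 101 * attempt
        model <- preset_random_graph(cl[1], cl[2], seed = sd,
                                     outgroup_ne = config$outgroup_ne %||% 1e5,
                                     genome = config$genome,
                                     n_per_pop = config$n_per_pop %||% 10)
        sim <- simulate_model(model, seed = sd)
        if (retain_by_fst(sim, fst_thr)) break
        if (attempt >= (config$max_resample %||% 10))
          stop("could not satisfy the FST retention rule")
      }
      simlog[[topo_id]] <- data.frame(topology = topo_id,
                                      n_pops = cl[1], n_admix = cl[2],
                                      attempts = attempt, seed = sim$seed)
      gm <- sim$genotypes
      blocks <- assign_blocks(gm, config$block_size %||% 4e6)
      truth <- sim$graph
      groups <- populations(gm)
      cache <- f2_site_cache(gm, blocks)
      pf <- pop_freqs(gm)
      f2b_all <- f2_blocks_masked(cache)
      obs <- observed_fstats(f2b_all, truth$leaves)
      fst_root <- vapply(setdiff(groups, "root"), function(p)
        hudson_from_freqs(pf, p, "root"), numeric(1))
      rm(pf)
      fit0 <- fit_graph(truth, f2b_all, numstart = config$numstart,
                        seed = sim$seed, obs = obs)
      out[[length(out) + 1]] <- data.frame(
        topology = topo_id, scheme = "unascertained", target = NA,
        wr = fit0$wr, ll = fit0$ll, fst_to_root = NA, n_sites = n_sites(gm))
      fit_masked <- function(msk, scheme, target, fst) {
        if (sum(msk$keep) < 20 * blocks$n_blocks) return(NULL)
        f2b <- f2_blocks_masked(cache, msk)
        fit <- fit_graph(truth, f2b, numstart = config$numstart,
                         seed = sim$seed,
                         obs = observed_fstats(f2b, truth$leaves))
        data.frame(topology = topo_id, scheme = scheme, target = target,
                   wr = fit$wr, ll = fit$ll, fst_to_root = fst,
                   n_sites = sum(msk$keep))
      }
      schemes <- config$schemes %||% "ho1"
      tips <- setdiff(groups, c("outgroup", "root", "nonog"))
      if ("ho1" %in% schemes) for (tg in groups) {
        id <- pick_individuals(gm, tg, seed = sim$seed)
        r <- fit_masked(het_in_individual(gm, id), "ho1", tg,
                        if (tg == "root") 0 else unname(fst_root[tg]))
        if (!is.null(r)) out[[length(out) + 1]] <- r
      }
      nsets <- config$n_random_sets %||% 10
      for (sc in intersect(schemes, c("ho4", "poly3", "maf4"))) {
        for (k in seq_len(nsets)) {
          sd2 <- sim$seed + 131 * k + match(sc, c("ho4", "poly3", "maf4"))
          npick <- if (sc == "poly3") 3 else 4
          set <- tips[local_sample(seq_along(tips), npick, sd2)]
          msk <- switch(sc,
            ho4 = union_panels(lapply(pick_individuals(gm, set, sd2),
                                      function(id) het_in_individual(gm, id))),
            poly3 = polymorphic_in_group(gm, pick_individuals(gm, set, sd2)),
            maf4 = maf_in_metapopulation(gm, set))
          r <- fit_masked(msk, sc, paste(set, collapse = "+"), NA)
          if (!is.null(r)) out[[length(out) + 1]] <- r
        }
      }
    }
  }
  res <- list(fits = do.call(rbind, out), sims = do.call(rbind, simlog))
  write_artifact(res$fits, config, "random_graph_fits")
  write_artifact(res$sims, config, "random_graph_sims")
  res
}

#' Run an exhaustive topology scan
#'
#' Fits a catalog of admixture-graph topologies for a five-population subset
#' on the unascertained data, on each requested ascertained set, and on
#' thinned replicates, producing the fit tables behind the flipped-verdict
#' and classifier metrics.
#'
#' @param config An [experiment_config()]; recognized extras: `gm` (a
#'   `geno_matrix`), `pops` (five populations), `masks` (named list of
#'   `site_mask`), `n_admix` (default 2), `max_topologies` (fit only the
#'   first k catalog entries; NULL = all), `n_thin` (thinned replicates,
#'   default 0), `thin_target` (sites per replicate).
#' @return List with `catalog_size` and `fits` (topology x SNP-set table).
#' @export
run_exhaustive_scan <- function(config) {
  gm <- config$gm; pops <- config$pops
  stopifnot(inherits(gm, "geno_matrix"), length(pops) == 5)
  cat_ <- enumerate_topologies(5, config$n_admix %||% 2, labels = sort(pops))
  idx <- seq_len(min(config$max_topologies %||% cat_$n, cat_$n))
  blocks <- assign_blocks(gm, config$block_size %||% 4e6)
  snp_sets <- c(list(all_sites = site_mask(rep(TRUE, n_sites(gm)), "all")),
                config$masks %||% list())
  if ((config$n_thin %||% 0) > 0) {
    tgt <- config$thin_target %||% stop("thin_target required with n_thin")
    for (r in seq_len(config$n_thin))
      snp_sets[[sprintf("thin_%03d", r)]] <-
        random_thin(gm, tgt, seed = config$seed + 5000 + r)
  }
  cache <- if (!anyNA(gm$calls)) f2_site_cache(gm, blocks, sort(pops)) else NULL
  out <- list()
  for (sn in names(snp_sets)) {
    f2b <- if (is.null(cache)) f2_blocks(gm, blocks, pops = pops,
                                         mask = snp_sets[[sn]])
           else f2_blocks_masked(cache, snp_sets[[sn]])
    obs <- observed_fstats(f2b, sort(pops))
    for (i in idx) {
      g <- catalog_graph(cat_, i)
      fit <- fit_graph(g, f2b, numstart = config$numstart,
                       seed = config$seed, obs = obs)
      out[[length(out) + 1]] <- data.frame(
        snp_set = sn, topology = i, wr = fit$wr, ll = fit$ll)
    }
  }
  res <- list(catalog_size = cat_$n, fits = do.call(rbind, out))
  write_artifact(res$fits, config, "exhaustive_fits")
  res
}
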