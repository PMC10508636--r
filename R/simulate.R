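## Synthetic-data generation: demographic models are simulated with msprime
## (hybrid discrete-time Wright-Fisher + coalescent, binary mutation model)
## through a bundled python driver; results come back as polarized
## `geno_matrix` objects together with the true admixture graph.

#' Genome specification for simulations
#'
#' Chromosomes are simulated as independent windows (default 250 kb) with the
#' flat within-window recombination rate; this keeps allele-frequency moments
#' identical to a contiguous chromosome while making deep-coalescent
#' simulations tractable (`device = "chromosome"` simulates contiguous
#' chromosomes instead).
#'
#' @param n_chrom Number of chromosomes (default 3).
#' @param chrom_length Chromosome length in bp (default 100 Mb).
#' @param recomb Recombination rate per bp per generation (default 2e-8).
#' @param mut Mutation rate per bp per generation (default 1.25e-8).
#' @param window Independence window in bp (default 250 kb).
#' @param device `"windows"` (default) or `"chromosome"`.
#' @export
genome_spec <- function(n_chrom = 3, chrom_length = 1e8, recomb = 2e-8,
                        mut = 1.25e-8, window = 2.5e5,
                        device = c("windows", "chromosome")) {
  device <- match.arg(device)
  list(n_chrom = as.integer(n_chrom), length = chrom_length, recomb = recomb,
       mut = mut, window = window, device = device)
}

#' Demographic model
#'
#' A population-genetic scenario: populations with constant diploid effective
#' sizes (one population per graph edge), dated population splits and pulse
#' admixture events, dated diploid sample sets, and a genome specification.
#'
#' @param populations Data frame with columns `name`, `ne`.
#' @param events List of events; each is `list(type = "split", time, derived,
#'   ancestral)` or `list(type = "pulse", time, recipient, donor, prop)`
#'   (forward-time: `prop` of `recipient`'s ancestry comes from `donor`).
#' @param samples Data frame with columns `pop`, `n`, `time` (generations).
#' @param genome A [genome_spec()].
#' @param graph Optional true `admix_graph` for downstream evaluation.
#' @param scenario Optional scenario descriptor string.
#' @export
demographic_model <- function(populations, events, samples,
                              genome = genome_spec(), graph = NULL,
                              scenario = "custom") {
  stopifnot(all(c("name", "ne") %in% names(populations)),
            all(c("pop", "n") %in% names(samples)))
  if (is.null(samples$time)) samples$time <- 0
  if (nrow(samples) == 0 || all(samples$n == 0)) stop("no samples specified")
  for (ev in events) {
    if (!ev$type %in% c("split", "pulse")) stop("unknown event type")
    if (ev$time <= 0) stop("event times must be positive")
    if (ev$type == "pulse" && (ev$prop <= 0 || ev$prop >= 1))
      stop("pulse proportions must be in (0, 1)")
  }
  structure(list(populations = populations, events = events,
                 samples = samples, genome = genome, graph = graph,
                 scenario = scenario),
            class = "demog_model")
}

#' @export
print.demog_model <- function(x, ...) {
  cat(sprintf("<demog_model> %s: %d populations, %d events, %d sample sets\n",
              x$scenario, nrow(x$populations), length(x$events),
              nrow(x$samples)))
  invisible(x)
}

python_binary <- function() {
  p <- getOption("ascbias.python", Sys.which("python"))
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("python interpreter not found")
  p
}

#' Simulate a demographic model
#'
#' Runs the bundled msprime driver: chromosomes are simulated with the
#' discrete-time Wright-Fisher model for the most recent 25 generations and
#' the standard coalescent beyond, mutations are placed under a binary model
#' at the flat rate of the genome spec, and genotypes are polarized by the
#' simulator's known ancestral state. Deterministic given the seed.
#'
#' @param model A `demog_model`.
#' @param seed Integer seed (drives the whole simulation).
#' @param dtwf Generations of discrete-time Wright-Fisher at the recent end
#'   (default 25).
#' @return A `sim_result`: list with `genotypes` (a `geno_matrix`), `graph`
#'   (true `admix_graph` or NULL), `seed`, `scenario`.
#' @export
simulate_model <- function(model, seed, dtwf = 25) {
  stopifnot(inherits(model, "demog_model"))
  spec <- list(seed = as.integer(seed), dtwf = dtwf,
               genome = model$genome,
               populations = lapply(seq_len(nrow(model$populations)),
                 function(i) list(name = model$populations$name[i],
                                  ne = model$populations$ne[i])),
               events = model$events,
               samples = lapply(seq_len(nrow(model$samples)),
                 function(i) list(pop = model$samples$pop[i],
                                  n = model$samples$n[i],
                                  time = model$samples$time[i])))
  td <- tempfile("ascbias_sim_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  jf <- file.path(td, "model.json")
  jsonlite::write_json(spec, jf, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "msprime_sim.py", package = "ascbias")
  if (!nzchar(script)) stop("bundled msprime driver not found")
  out <- system2(python_binary(), c(script, jf, td), stdout = TRUE,
                 stderr = TRUE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("simulation driver failed:\n", paste(out, collapse = "\n"))
  sites <- as.data.frame(arrow::read_feather(file.path(td, "sites.feather")))
  calls <- as.matrix(as.data.frame(arrow::read_feather(file.path(td, "calls.feather"))))
  ind <- as.data.frame(arrow::read_feather(file.path(td, "ind.feather")))
  gm <- geno_matrix(calls,
                    data.frame(chrom = as.character(sites$chrom),
                               pos = sites$pos, anc = sites$anc,
                               der = sites$der, stringsAsFactors = FALSE),
                    ind)
  structure(list(genotypes = gm, graph = model$graph, seed = seed,
                 scenario = model$scenario, model = model),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s (seed %d): ", x$scenario, x$seed))
  print(x$genotypes)
  invisible(x)
}

#' Minimum-FST retention rule for random simulations
#'
#' Keeps a simulation iff the minimum pairwise Hudson FST over the sampled
#' populations (excluding internal root samples) is below the threshold,
#' i.e. at least one population pair is as close as anatomically modern
#' human groups are.
#'
#' @param sim A `sim_result`.
#' @param threshold FST threshold (default 0.15).
#' @param exclude Populations ignored by the rule (default the internal root
#'   samples).
#' @return TRUE if the simulation is retained.
#' @export
retain_by_fst <- function(sim, threshold = 0.15,
                          exclude = c("root", "nonog")) {
  gm <- sim$genotypes
  pops <- setdiff(populations(gm), exclude)
  if (length(pops) < 2) stop("need at least two sampled populations")
  fmin <- Inf
  for (i in seq_along(pops)) for (j in seq_along(pops)) if (i < j) {
    f <- fst_hudson(gm, pops[i], pops[j])$est
    if (!is.na(f) && f < fmin) fmin <- f
    if (fmin < threshold) return(TRUE)
  }
  fmin < threshold
}

## --------------------------------------------------------------------------
## preset: bottlenecked four-taxon tree (O,(C,(A,B)))

#' Four-taxon tree with a post-split bottleneck
#'
#' Tree (O,(C,(A,B))) of depth 4,000 generations with uniform effective size
#' 100,000, except population A whose size is divided by `bottleneck_factor`
#' from immediately after the A-B divergence (1,999 generations ago) to the
#' present. Samples: 25/25/25/10 diploids for A/B/C/O at present (10 for A at
#' the 10,000-fold bottleneck, where diversity is nearly exhausted).
#'
#' @param bottleneck_factor One of 1, 10, 100, 1000, 10000.
#' @param genome A [genome_spec()].
#' @param ne Baseline effective size (default 100,000 diploids).
#' @return A `demog_model` carrying the true tree as `graph`.
#' @export
preset_simple_tree <- function(bottleneck_factor = 100,
                               genome = genome_spec(), ne = 1e5) {
  stopifnot(bottleneck_factor >= 1)
  pops <- data.frame(
    name = c("A", "B", "C", "O", "AB", "ABC", "ROOT"),
    ne = c(ne / bottleneck_factor, ne, ne, ne, ne, ne, ne))
  events <- list(
    list(type = "split", time = 1999, derived = c("A", "B"), ancestral = "AB"),
    list(type = "split", time = 3000, derived = c("AB", "C"), ancestral = "ABC"),
    list(type = "split", time = 4000, derived = c("ABC", "O"), ancestral = "ROOT"))
  nA <- if (bottleneck_factor >= 1e4) 10 else 25
  samples <- data.frame(pop = c("A", "B", "C", "O"),
                        n = c(nA, 25, 25, 10), time = 0)
  graph <- admixture_graph(data.frame(
    from = c("ROOT", "ROOT", "ABC", "ABC", "AB", "AB"),
    to = c("O", "ABC", "C", "AB", "A", "B"), stringsAsFactors = FALSE))
  demographic_model(pops, events, samples, genome, graph,
                    scenario = sprintf("simple-tree-bn%g", bottleneck_factor))
}

## --------------------------------------------------------------------------
## preset: archaic + modern human case study

#' Case-study demographic model (chimpanzee, three archaic, four modern)
#'
#' One chimpanzee individual at present, one early Neanderthal sampled 3,790
#' generations ago, one late Neanderthal and one Denisovan sampled 1,700
#' generations ago, and 10 diploids each from two African and two non-African
#' groups at present, with an out-of-Africa bottleneck; Neanderthal gene flow
#' into the non-African ancestor (through an unsampled Neanderthal-side
#' lineage) is simulated at proportion `neanderthal_flow` (0 disables the
#' pulse). Sizes and split dates come from a parameter file; the shipped
#' default is a clearly-labeled synthetic stand-in calibrated to reproduce
#' the qualitative FST structure between modern, archaic and outgroup
#' populations.
#'
#' @param neanderthal_flow Admixture proportion (0 or ~0.02).
#' @param params_file TSV of parameters (default: bundled stand-in).
#' @param genome A [genome_spec()].
#' @return A `demog_model`; its `graph` is the full true admixture graph.
#' @export
preset_case_study <- function(neanderthal_flow = 0.02, params_file = NULL,
                              genome = genome_spec()) {
  params_file <- params_file %||%
    system.file("extdata", "case_study_params_synthetic.tsv",
                package = "ascbias")
  pt <- utils::read.table(params_file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chimp", "nea1", "nea2", "den", "afr1", "afr2", "nonafr1",
            "nonafr2", "neaghost", "nea", "arch1", "arch", "amh", "afr",
            "ooa", "hom", "root")
  miss <- setdiff(need, pt$param[pt$kind == "ne"])
  if (length(miss)) stop("parameter file missing Ne rows: ",
                         paste(miss, collapse = ", "))
  ne <- stats::setNames(pt$value[pt$kind == "ne"], pt$param[pt$kind == "ne"])
  tm <- stats::setNames(pt$value[pt$kind == "time"], pt$param[pt$kind == "time"])
  needt <- c("t_nonafr", "t_ooa", "t_afr", "t_nea_split", "t_nea1",
             "t_arch_split", "t_hom", "t_root", "t_flow")
  misst <- setdiff(needt, names(tm))
  if (length(misst)) stop("parameter file missing time rows: ",
                          paste(misst, collapse = ", "))
  pops <- data.frame(name = need, ne = as.numeric(ne[need]))
  events <- list(
    list(type = "split", time = tm[["t_nonafr"]],
         derived = c("nonafr1", "nonafr2"), ancestral = "ooa"),
    list(type = "split", time = tm[["t_ooa"]],
         derived = c("afr2", "ooa"), ancestral = "afr"),
    list(type = "split", time = tm[["t_afr"]],
         derived = c("afr1", "afr"), ancestral = "amh"),
    list(type = "split", time = tm[["t_nea_split"]],
         derived = c("nea2", "neaghost"), ancestral = "nea"),
    list(type = "split", time = tm[["t_nea1"]],
         derived = c("nea1", "nea"), ancestral = "arch1"),
    list(type = "split", time = tm[["t_arch_split"]],
         derived = c("arch1", "den"), ancestral = "arch"),
    list(type = "split", time = tm[["t_hom"]],
         derived = c("amh", "arch"), ancestral = "hom"),
    list(type = "split", time = tm[["t_root"]],
         derived = c("hom", "chimp"), ancestral = "root"))
  if (neanderthal_flow > 0)
    events <- c(events, list(list(type = "pulse", time = tm[["t_flow"]],
                                  recipient = "ooa", donor = "neaghost",
                                  prop = neanderthal_flow)))
  samples <- data.frame(
    pop = c("chimp", "nea1", "nea2", "den", "afr1", "afr2", "nonafr1",
            "nonafr2"),
    n = c(1, 1, 1, 1, 10, 10, 10, 10),
    time = c(0, 3790, 1700, 1700, 0, 0, 0, 0))
  graph <- case_study_graph(neanderthal_flow > 0)
  demographic_model(pops, events, samples, genome, graph,
                    scenario = sprintf("case-study-flow%g", neanderthal_flow))
}

case_study_graph <- function(with_flow) {
  ed <- rbind(
    c("root", "chimp"), c("root", "hom"),
    c("hom", "amh"), c("hom", "arch"),
    c("arch", "den"), c("arch", "arch1"),
    c("arch1", "nea1"), c("arch1", "nea"),
    c("nea", "nea2"), c("nea", "neaghost"),
    c("amh", "afr1"), c("amh", "afr"),
    c("afr", "afr2"), c("afr", "ooa"))
  if (with_flow) {
    ## drift accrues on both parent lineages between their origins and the
    ## pulse time, so the admixture node hangs below explicit drift nodes
    ed <- rbind(ed,
                c("ooa", "ooapre"), c("neaghost", "ghostpre"),
                c("ooapre", "mix"), c("ghostpre", "mix"),
                c("mix", "ooa2"),
                c("ooa2", "nonafr1"), c("ooa2", "nonafr2"))
  } else {
    ed <- rbind(ed, c("ooa", "nonafr1"), c("ooa", "nonafr2"))
  }
  g <- admixture_graph(data.frame(from = ed[, 1], to = ed[, 2],
                                  stringsAsFactors = FALSE))
  prune_graph(g, c("chimp", "nea1", "nea2", "den", "afr1", "afr2",
                   "nonafr1", "nonafr2"))
}

#' Restrict an admixture graph to a subset of leaves
#'
#' Drops the other leaves, removes dangling branches, contracts single-child
#' pass-through nodes, and resolves admixture nodes left with one parent.
#'
#' @param graph An `admix_graph`.
#' @param keep Leaves to retain.
#' @return An `admix_graph` on the retained leaves.
#' @export
prune_graph <- function(graph, keep) {
  stopifnot(all(keep %in% graph$leaves))
  ed <- graph$edges[, c("from", "to")]
  repeat {
    nodes <- unique(c(ed$from, ed$to))
    outdeg <- table(factor(ed$from, levels = nodes))
    indeg <- table(factor(ed$to, levels = nodes))
    drop_leaf <- nodes[outdeg == 0 & !(nodes %in% keep)]
    if (length(drop_leaf)) {
      ed <- ed[!(ed$to %in% drop_leaf), , drop = FALSE]
      next
    }
    ## contract pass-through nodes (1 parent, 1 child), except the drift
    ## carrier directly above an admixture node (edges into admixture
    ## nodes are zero-length mixing edges, so the carrier must survive
    ## unless it is itself fed by another pass-through node)
    admx <- nodes[indeg == 2]
    mid <- nodes[indeg == 1 & outdeg == 1]
    keep_mid <- vapply(mid, function(m) {
      ch <- ed$to[ed$from == m]
      p <- ed$from[ed$to == m]
      ch %in% admx && !(p %in% mid)
    }, TRUE)
    mid <- mid[!keep_mid]
    if (length(mid)) {
      m <- mid[1]
      p <- ed$from[ed$to == m]; ch <- ed$to[ed$from == m]
      ed <- ed[ed$to != m & ed$from != m, , drop = FALSE]
      if (!(p == ch)) ed <- rbind(ed, data.frame(from = p, to = ch))
      next
    }
    ## root with single child: drop the root edge
    root <- nodes[indeg == 0]
    if (length(root) == 1 && outdeg[root] == 1) {
      ed <- ed[ed$from != root, , drop = FALSE]
      next
    }
    ## duplicated parallel edges (degenerate admixture): keep one
    key <- paste(ed$from, ed$to)
    if (anyDuplicated(key)) {
      ed <- ed[!duplicated(key), , drop = FALSE]
      next
    }
    break
  }
  admixture_graph(ed)
}

## --------------------------------------------------------------------------
## preset: random admixture graphs

#' Random admixture-graph demographic model
#'
#' Emulates the randomized graph generator of the reference toolchain: a
#' random bifurcating topology over the non-outgroup populations, an
#' outgroup diverging 40,000 generations ago with effective size
#' `outgroup_ne`, other edge sizes uniform in [2,000, 40,000] diploids,
#' demographic events separated by random gaps of 1,500-8,000 generations,
#' tips sampled at their terminal dates, and `n_admix` pulse admixture
#' events with proportions uniform in [0.10, 0.40] between contemporaneous
#' branches. The root of the simulation and the root of the non-outgroup
#' populations are sampled as well (population labels `"root"` and
#' `"nonog_root"`); they are not part of the fitted true graph.
#'
#' @param n_pops Total population count including the outgroup (9 or 10).
#' @param n_admix Number of admixture pulses (4 or 5).
#' @param seed Integer seed (drives topology and parameters).
#' @param outgroup_ne Outgroup effective size (100,000, or 1,000 for the
#'   drifted-outgroup variant).
#' @param genome A [genome_spec()].
#' @param n_per_pop Diploids sampled per population (default 10).
#' @return A `demog_model` carrying the true `admix_graph`.
#' @export
preset_random_graph <- function(n_pops = 9, n_admix = 4, seed,
                                outgroup_ne = 1e5, genome = genome_spec(),
                                n_per_pop = 10) {
  n_tips <- n_pops - 1
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  tips <- paste0("pop", seq_len(n_tips))
  ## random recursive bifurcation -> edge list with internal nodes i1..,
  ## root of non-outgroup populations = "nonog"
  counter <- new.env(); counter$i <- 0L
  split_set <- function(set, parent) {
    if (length(set) == 1) return(data.frame(from = parent, to = set))
    k <- sample.int(length(set) - 1, 1)
    sh <- sample(set)
    left <- sh[seq_len(k)]; right <- sh[-seq_len(k)]
    mk <- function(s) {
      if (length(s) == 1) s else {
        counter$i <- counter$i + 1L
        paste0("i", counter$i)
      }
    }
    ln <- mk(left); rn <- mk(right)
    rbind(data.frame(from = parent, to = ln),
          if (length(left) > 1) split_set(left, ln),
          data.frame(from = parent, to = rn),
          if (length(right) > 1) split_set(right, rn))
  }
  ed <- split_set(tips, "nonog")

  ## node times: outgroup diverges at 40,000 generations; events below are
  ## separated by random 1,500-8,000 generation gaps (clamped to stay
  ## positive in deep caterpillar topologies; tips may reach the present)
  t_og <- 40000
  times <- c(root = t_og, outgroup = 0)
  times["nonog"] <- t_og - stats::runif(1, 1500, 8000)
  assign_time <- function(node) {
    for (ch in ed$to[ed$from == node]) {
      t <- times[[node]] - stats::runif(1, 1500, 8000)
      if (ch %in% tips) {
        times[ch] <<- max(0, t)
      } else {
        times[ch] <<- if (t > 200) t else times[[node]] * stats::runif(1, 0.3, 0.6)
        assign_time(ch)
      }
    }
  }
  assign_time("nonog")
  ## full edge list incl. outgroup
  ed <- rbind(data.frame(from = "root", to = "outgroup"),
              data.frame(from = "root", to = "nonog"), ed)

  ## per-edge effective sizes (population = edge above the child node)
  ne <- stats::setNames(round(stats::runif(nrow(ed), 2000, 40000)), ed$to)
  ne["outgroup"] <- outgroup_ne
  ne_root <- round(stats::runif(1, 2000, 40000))

  ## pulse admixture events between contemporaneous edges
  edge_alive <- function(t) {
    ok <- vapply(seq_len(nrow(ed)), function(i) {
      hi <- times[[ed$from[i]]]
      lo <- times[[ed$to[i]]]
      t < hi && t > lo
    }, TRUE)
    which(ok)
  }
  pulses <- list()
  guard <- 0
  while (length(pulses) < n_admix && guard < 1000) {
    guard <- guard + 1
    t <- stats::runif(1, 200, times[["nonog"]] - 200)
    alive <- edge_alive(t)
    alive <- alive[ed$to[alive] != "outgroup"]   # keep the outgroup clean
    if (length(alive) < 2) next
    pick <- sample(alive, 2)
    pulses[[length(pulses) + 1]] <- list(
      time = t, recipient = ed$to[pick[1]], donor = ed$to[pick[2]],
      prop = stats::runif(1, 0.10, 0.40))
  }
  if (length(pulses) < n_admix) stop("could not place all admixture pulses")
  ## oldest first, so truth-graph insertions nest correctly on shared edges
  pulses <- pulses[order(-vapply(pulses, `[[`, 0, "time"))]

  pops <- data.frame(name = c(ed$to, "root"),
                     ne = c(as.numeric(ne[ed$to]), ne_root))
  events <- list()
  for (nd in unique(ed$from)) {
    der <- ed$to[ed$from == nd]
    anc <- if (nd == "root") "root" else nd
    events[[length(events) + 1]] <-
      list(type = "split", time = unname(times[[nd]]), derived = der,
           ancestral = anc)
  }
  for (p in pulses)
    events[[length(events) + 1]] <-
      list(type = "pulse", time = unname(p$time), recipient = p$recipient,
           donor = p$donor, prop = unname(p$prop))

  samples <- rbind(
    data.frame(pop = tips, n = n_per_pop,
               time = vapply(tips, function(x) unname(times[[x]]), 0)),
    data.frame(pop = "outgroup", n = n_per_pop, time = 0),
    data.frame(pop = "root", n = n_per_pop, time = times[["root"]]),
    data.frame(pop = "nonog", n = n_per_pop, time = times[["nonog"]]))
  ## root/non-outgroup-root samples get distinct population labels in the
  ## genotype matrix via sample pop name; msprime uses population names, so
  ## sample directly from those populations (labels kept as-is)

  graph <- random_graph_truth(ed, pulses)
  m <- demographic_model(pops, events, samples, genome, graph,
                         scenario = sprintf("random-graph-%dp-%da", n_pops,
                                            n_admix))
  m$times <- times
  m
}

## Build the true admixture graph (tips + outgroup as leaves) from the tree
## edge list and the pulse list. Pulses arrive oldest first; each insertion
## splits the segment adjacent to the recorded child node, so younger events
## on the same branch nest below older ones.
random_graph_truth <- function(ed, pulses) {
  E <- ed
  seg_of <- function(node) which(E$to == node)
  k <- 0
  for (p in pulses) {
    k <- k + 1
    vi <- paste0("mix", k); ui <- paste0("srcn", k)
    rp <- paste0("rpre", k)
    ri <- seg_of(p$recipient); di <- seg_of(p$donor)
    rfrom <- E$from[ri]
    dfrom <- E$from[di]
    E <- E[-c(ri, di), , drop = FALSE]
    ## rpre carries the recipient-side drift above the pulse; both parent
    ## edges of the admixture node itself are zero-length mixing edges
    E <- rbind(E,
               data.frame(from = rfrom, to = rp),
               data.frame(from = rp, to = vi),
               data.frame(from = vi, to = p$recipient),
               data.frame(from = dfrom, to = ui),
               data.frame(from = ui, to = p$donor),
               data.frame(from = ui, to = vi))
  }
  admixture_graph(E)
}
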