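## Admixture graphs: leaf-labeled DAGs of drift edges (lengths in f2 units)
## and two-parent admixture nodes (mixing proportions). Expected f-statistics
## follow the standard model: every f4 is a sum over drift edges of
## length(e) * (wA(e) - wB(e)) * (wC(e) - wD(e)), where wX(e) is the
## probability that a lineage sampled from X traverses e.

#' Construct an admixture graph
#'
#' @param edges Data frame (or 2/3-column matrix) with columns `from`, `to`
#'   and optionally `type`; when `type` is absent, edges into nodes with two
#'   parents are classified as admixture edges and all others as drift edges.
#' @param leaves Optional character vector naming the leaves (defaults to all
#'   nodes without children).
#' @return An object of class `admix_graph`.
#' @export
admixture_graph <- function(edges, leaves = NULL) {
  if (is.matrix(edges)) edges <- data.frame(from = edges[, 1], to = edges[, 2],
                                            stringsAsFactors = FALSE)
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  nodes <- unique(c(edges$from, edges$to))
  indeg <- table(factor(edges$to, levels = nodes))
  outdeg <- table(factor(edges$from, levels = nodes))
  root <- nodes[indeg == 0]
  if (length(root) != 1) stop("graph must have exactly one root")
  if (any(indeg > 2)) stop("nodes may have at most two parents")
  admix <- nodes[indeg == 2]
  lv <- nodes[outdeg == 0]
  if (!is.null(leaves)) {
    if (!setequal(lv, leaves)) stop("declared leaves do not match childless nodes")
    lv <- leaves
  }
  if (is.null(edges$type))
    edges$type <- ifelse(edges$to %in% admix, "admix", "drift")
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")])
  if (!igraph::is_dag(g)) stop("graph contains a cycle")
  ## cached traversal structure for the fitting hot path:
  ## children-first node order and parent-edge indices per node
  ord <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "in"))]
  pedges <- lapply(nodes, function(nd) which(edges$to == nd))
  names(pedges) <- nodes
  structure(list(edges = edges, nodes = nodes, root = root,
                 leaves = sort(lv), admix_nodes = admix,
                 ord = ord, pedges = pedges),
            class = "admix_graph")
}

#' @export
print.admix_graph <- function(x, ...) {
  cat(sprintf("<admix_graph> %d leaves (%s), %d admixture events, %d edges\n",
              length(x$leaves), paste(x$leaves, collapse = ","),
              length(x$admix_nodes), nrow(x$edges)))
  invisible(x)
}

#' Leaves of an admixture graph
#' @param graph An `admix_graph`.
#' @export
graph_leaves <- function(graph) graph$leaves

edge_ids <- function(graph) paste(graph$edges$from, graph$edges$to, sep = "->")

drift_edge_ids <- function(graph) edge_ids(graph)[graph$edges$type == "drift"]

## For each admixture node, its two parents sorted; alpha is the proportion
## contributed by the first (alphabetically smaller) parent.
admix_parents <- function(graph) {
  out <- lapply(graph$admix_nodes, function(v)
    sort(graph$edges$from[graph$edges$to == v]))
  names(out) <- graph$admix_nodes
  out
}

## edge weight matrix: rows = edges, cols = leaves; entry = probability that
## a lineage from the leaf traverses the edge
edge_weights <- function(graph, alpha) {
  ap <- admix_parents(graph)
  mult <- rep(1, nrow(graph$edges))
  for (v in graph$admix_nodes) {
    i1 <- which(graph$edges$to == v & graph$edges$from == ap[[v]][1])
    i2 <- which(graph$edges$to == v & graph$edges$from == ap[[v]][2])
    mult[i1] <- alpha[[v]]
    mult[i2] <- 1 - alpha[[v]]
  }
  nl <- length(graph$leaves)
  W <- matrix(0, nrow(graph$edges), nl,
              dimnames = list(edge_ids(graph), graph$leaves))
  w <- matrix(0, length(graph$nodes), nl,
              dimnames = list(graph$nodes, graph$leaves))
  w[cbind(graph$leaves, graph$leaves)] <- 1
  efrom <- graph$edges$from
  for (nd in graph$ord) {      # children before parents
    for (i in graph$pedges[[nd]]) {
      W[i, ] <- w[nd, ] * mult[i]
      w[efrom[i], ] <- w[efrom[i], ] + W[i, ]
    }
  }
  W
}

#' Expected pairwise f2 matrix of a parameterized graph
#'
#' @param graph An `admix_graph`.
#' @param lengths Named numeric vector of drift-edge lengths (names
#'   `"from->to"`); admixture edges carry no drift.
#' @param alpha Named numeric vector of admixture proportions, one per
#'   admixture node (the proportion contributed by the alphabetically first
#'   parent).
#' @return Symmetric matrix of expected f2 values between leaves.
#' @export
expected_f2_matrix <- function(graph, lengths, alpha = NULL) {
  did <- drift_edge_ids(graph)
  if (!all(did %in% names(lengths)))
    stop("missing drift edge length(s): ",
         paste(setdiff(did, names(lengths)), collapse = ", "))
  if (length(graph$admix_nodes) &&
      !all(graph$admix_nodes %in% names(alpha)))
    stop("missing admixture proportion(s)")
  W <- edge_weights(graph, alpha)
  len <- stats::setNames(rep(0, nrow(graph$edges)), edge_ids(graph))
  len[did] <- lengths[did]
  lv <- graph$leaves
  out <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    d <- W[, i] - W[, j]
    out[i, j] <- out[j, i] <- sum(len * d * d)
  }
  out
}

expected_f4_from_f2 <- function(F2, A, B, C, D) {
  0.5 * (F2[A, D] + F2[B, C] - F2[A, C] - F2[B, D])
}

## all distinct f-statistics over a population set: f2 pairs, f3 triples,
## f4 quadruple pairings (up to the antisymmetry/exchange symmetries)
all_fstat_tuples <- function(pops) {
  out <- list()
  n <- length(pops)
  for (ij in utils::combn(n, 2, simplify = FALSE))
    out[[length(out) + 1]] <- list(type = "f2",
                                   tuple = c(pops[ij[1]], pops[ij[2]],
                                             pops[ij[1]], pops[ij[2]]))
  if (n >= 3) for (tri in utils::combn(n, 3, simplify = FALSE)) for (t in 1:3) {
    tgt <- tri[t]; rest <- setdiff(tri, tgt)
    out[[length(out) + 1]] <- list(type = "f3",
                                   tuple = c(pops[tgt], pops[rest[1]],
                                             pops[tgt], pops[rest[2]]))
  }
  if (n >= 4) for (q in utils::combn(n, 4, simplify = FALSE)) {
    p <- pops[q]
    for (pair in list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3)))
      out[[length(out) + 1]] <- list(type = "f4", tuple = p[pair])
  }
  out
}

#' Observed f-statistics table for residual scanning
#'
#' Computes estimate and jackknife SE for every distinct f2, f3 and f4
#' statistic over a population set; used when scanning for the worst residual
#' of a fitted graph. Precompute once when fitting many topologies to the
#' same data.
#'
#' @param f2b An `f2_blocks_set`.
#' @param pops Populations (default: all in `f2b`).
#' @return Data frame with columns `type`, `p1..p4`, `est`, `se`.
#' @export
observed_fstats <- function(f2b, pops = NULL) {
  pops <- pops %||% f2b$pops
  tuples <- all_fstat_tuples(pops)
  w <- f_weights(f2b)
  res <- lapply(tuples, function(tp) {
    v <- f4_block_values(f2b, tp$tuple[1], tp$tuple[2], tp$tuple[3], tp$tuple[4])
    jk <- jackknife(v, w)
    data.frame(type = tp$type, p1 = tp$tuple[1], p2 = tp$tuple[2],
               p3 = tp$tuple[3], p4 = tp$tuple[4],
               est = jk$est, se = jk$se, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## f3-basis (reference population) spanning all f-statistics:
## f3(ref; i, j) for all i <= j from the non-reference populations
basis_tuples <- function(pops, ref = pops[1]) {
  others <- setdiff(pops, ref)
  out <- list()
  for (i in seq_along(others)) for (j in i:length(others))
    out[[length(out) + 1]] <- c(ref, others[i], ref, others[j])
  out
}

#' Fit an admixture graph to f2 block data
#'
#' Minimizes the quadratic form
#' \eqn{q(\theta) = (f_{obs} - f_{exp}(\theta))' Q^{-1} (f_{obs} - f_{exp}(\theta))}
#' over a full-rank basis of f-statistics (all f3 statistics anchored at a
#' reference population), with Q the block-jackknife covariance of the basis
#' regularized by a relative ridge (`diag` times the mean diagonal). Expected
#' values are linear in drift-edge lengths given the admixture proportions,
#' so the fit alternates a non-negative least-squares solve for the lengths
#' with bound-constrained optimization over the proportions, restarted from
#' `numstart` random draws. Reported metrics: `ll` (the minimized quadratic
#' score) and `wr` (worst residual: the largest |observed - fitted| / SE over
#' all f2, f3 and f4 statistics of the leaf set).
#'
#' @param graph An `admix_graph` whose leaves are populations of `f2b`.
#' @param f2b An `f2_blocks_set`.
#' @param numstart Number of random restarts for the admixture proportions
#'   (default 100; ignored for admixture-free graphs).
#' @param diag Relative ridge added to the covariance diagonal (default 1e-4).
#' @param seed Integer seed for the restarts.
#' @param obs Optional precomputed [observed_fstats()] table for the leaf set.
#' @param warm Optional named vector of admixture proportions used as an
#'   additional warm start (used by the leave-one-out refits).
#' @return An object of class `graph_fit`: `ll`, `wr`, `worst` (the worst
#'   statistic's row), fitted `lengths` and `alpha`, and the restart record.
#' @export
fit_graph <- function(graph, f2b, numstart = 100, diag = 1e-4, seed = 1,
                      obs = NULL, warm = NULL) {
  pops <- graph$leaves
  if (!all(pops %in% f2b$pops))
    stop("graph leaves missing from f2 data: ",
         paste(setdiff(pops, f2b$pops), collapse = ", "))
  w <- f_weights(f2b)
  tuples <- basis_tuples(pops)
  B <- t(vapply(tuples, function(tp)
    f4_block_values(f2b, tp[1], tp[2], tp[3], tp[4]), numeric(ncol(f2b$est))))
  fobs <- as.numeric(B %*% w) / sum(w)
  Q <- jackknife_cov(B, w)
  Q <- Q + diag * mean(base::diag(Q)) * base::diag(nrow(Q))
  Ct <- t(chol(Q))                      # Q = Ct %*% t(Ct)
  b <- forwardsolve(Ct, fobs)
  did <- drift_edge_ids(graph)
  k <- length(graph$admix_nodes)

  dr <- graph$edges$type == "drift"
  tp1 <- vapply(tuples, `[`, "", 1); tp2 <- vapply(tuples, `[`, "", 2)
  tp3 <- vapply(tuples, `[`, "", 3); tp4 <- vapply(tuples, `[`, "", 4)
  design <- function(alpha) {
    W <- edge_weights(graph, alpha)[dr, , drop = FALSE]
    t((W[, tp1] - W[, tp2]) * (W[, tp3] - W[, tp4]))  # stats x drift edges
  }
  ## structurally collinear design columns (e.g. the two root edges, whose
  ## lengths are only jointly identifiable) are detected once at a probe
  ## point and merged before every solve; any residual rank deficiency is
  ## absorbed by the rank-revealing QR fallback
  probe <- if (k > 0)
    stats::setNames(0.3 + 0.37 * seq_len(k) / (k + 1), graph$admix_nodes)
  else NULL
  Ap <- design(probe)
  pkey <- apply(round(Ap, 10), 2, paste, collapse = ",")
  grp <- match(pkey, unique(pkey))
  lead <- !duplicated(grp)

  ## Inner solve for the drift-edge lengths given the proportions. During
  ## the search over proportions an unconstrained least-squares relaxation
  ## is used (fast, exact when no non-negativity bound is active); the
  ## reported optimum is always re-solved with non-negative least squares.
  solve_lengths <- function(alpha, exact = TRUE) {
    A <- forwardsolve(Ct, design(alpha))
    Ar <- A[, lead, drop = FALSE]
    if (!exact) {
      co <- tryCatch(qr.coef(qr(Ar), b), error = function(e) rep(0, ncol(Ar)))
      co[is.na(co)] <- 0
      return(list(obj = sum((b - Ar %*% co)^2), lengths = NULL))
    }
    x <- tryCatch(pracma::lsqnonneg(Ar, b)$x, error = function(e) {
      co <- qr.coef(qr(Ar), b)
      co[is.na(co)] <- 0
      pmax(co, 0)
    })
    full <- numeric(length(grp))
    full[lead] <- x
    list(obj = sum((b - Ar %*% x)^2), lengths = stats::setNames(full, did))
  }

  if (k == 0) {
    best <- solve_lengths(NULL)
    best$alpha <- stats::setNames(numeric(0), character(0))
    restarts <- best$obj
  } else if (k == 1) {
    ## one proportion: deterministic grid scan plus golden-section
    ## refinement of the exact (non-negative least squares) objective
    obj1 <- function(a)
      solve_lengths(stats::setNames(a, graph$admix_nodes))$obj
    grid <- seq(0.005, 0.995, length.out = 45)
    gv <- vapply(grid, obj1, numeric(1))
    i <- which.min(gv)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    op <- stats::optimize(obj1, c(lo, hi), tol = 1e-7)
    al <- stats::setNames(op$minimum, graph$admix_nodes)
    sl <- solve_lengths(al)
    best <- list(obj = sl$obj, lengths = sl$lengths, alpha = al)
    restarts <- op$objective
  } else {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    starts <- matrix(stats::runif(numstart * k, 0.05, 0.95), numstart, k)
    if (!is.null(warm))
      starts <- rbind(pmin(pmax(warm[graph$admix_nodes], 1e-3), 1 - 1e-3),
                      starts)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    obj_a <- function(a)
      solve_lengths(stats::setNames(a, graph$admix_nodes), exact = FALSE)$obj
    best <- NULL; restarts <- numeric(nrow(starts))
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[s, ], obj_a, method = "L-BFGS-B",
                     lower = rep(1e-4, k), upper = rep(1 - 1e-4, k),
                     control = list(factr = 1e9, maxit = 60)),
        error = function(e) list(par = starts[s, ], value = obj_a(starts[s, ]),
                                 convergence = 99))
      al <- stats::setNames(o$par, graph$admix_nodes)
      sl <- solve_lengths(al)              # non-negative polish
      restarts[s] <- sl$obj
      if (is.null(best) || sl$obj < best$obj - 1e-12)
        best <- list(obj = sl$obj, lengths = sl$lengths, alpha = al)
    }
  }

  F2fit <- expected_f2_matrix(graph, best$lengths, best$alpha)
  if (is.null(obs)) obs <- observed_fstats(f2b, pops)
  fitted <- mapply(function(a, bb, cc, d) expected_f4_from_f2(F2fit, a, bb, cc, d),
                   obs$p1, obs$p2, obs$p3, obs$p4)
  resid <- abs(obs$est - fitted) / obs$se
  iw <- which.max(resid)
  structure(list(ll = best$obj, wr = resid[iw],
                 worst = cbind(obs[iw, , drop = FALSE], fitted = fitted[iw]),
                 lengths = best$lengths, alpha = best$alpha,
                 residuals = resid, restarts = restarts,
                 graph = graph),
            class = "graph_fit")
}

#' @export
print.graph_fit <- function(x, ...) {
  cat(sprintf("<graph_fit> LL %.3f  WR %.2f SE  worst %s(%s)\n",
              x$ll, x$wr, x$worst$type,
              paste(unlist(x$worst[, c("p1", "p2", "p3", "p4")]), collapse = ",")))
  invisible(x)
}

#' Block-jackknife uncertainty for fitted admixture proportions
#'
#' Refits the graph with each block deleted in turn (warm-started at the
#' full-data optimum plus a few random restarts) and applies the weighted
#' jackknife to the per-block proportion estimates.
#'
#' @param graph An `admix_graph` with at least one admixture node.
#' @param f2b The `f2_blocks_set` used for the fit.
#' @param fit The full-data `graph_fit`.
#' @param numstart Restarts per leave-one-out refit (default 5, in addition
#'   to the warm start).
#' @param diag Ridge, as in [fit_graph()].
#' @return Data frame with one row per admixture node: `alpha`, `se`,
#'   `lo95`, `hi95`.
#' @export
jackknife_alpha <- function(graph, f2b, fit, numstart = 5, diag = 1e-4) {
  k <- length(graph$admix_nodes)
  if (k == 0) stop("graph has no admixture nodes")
  m <- ncol(f2b$est)
  loo <- matrix(NA_real_, k, m, dimnames = list(graph$admix_nodes, NULL))
  for (j in seq_len(m)) {
    fj <- f2b
    fj$est <- f2b$est[, -j, drop = FALSE]
    fj$cnt <- f2b$cnt[, -j, drop = FALSE]
    fj$block_sites <- f2b$block_sites[-j]
    rj <- fit_graph(graph, fj, numstart = numstart, diag = diag,
                    seed = j, warm = fit$alpha)
    loo[, j] <- rj$alpha[graph$admix_nodes]
  }
  w <- f2b$block_sites
  out <- lapply(graph$admix_nodes, function(v) {
    W <- sum(w); h <- W / w
    theta <- fit$alpha[[v]]
    tau <- h * theta - (h - 1) * loo[v, ]
    theta_j <- m * theta - sum((1 - w / W) * loo[v, ])
    se <- sqrt(mean((tau - theta_j)^2 / (h - 1)))
    data.frame(node = v, alpha = theta, se = se,
               lo95 = theta - 1.96 * se, hi95 = theta + 1.96 * se)
  })
  do.call(rbind, out)
}

#' Sample poorly-fitting topologies by score range
#'
#' Draws `k` topologies uniformly from those whose fit score on unascertained
#' data lies in `ll_range`; used to measure power to reject incorrect graphs.
#' If fewer than `k` qualify, all are returned with a warning.
#'
#' @param fits Data frame with columns `topology` (an id) and `ll`.
#' @param ll_range Score interval (default c(70, 300)).
#' @param k Number of topologies to sample (default 100).
#' @param seed Integer seed.
#' @return Vector of topology ids.
#' @export
sample_incorrect_graphs <- function(fits, ll_range = c(70, 300), k = 100,
                                    seed = 1) {
  pool <- fits$topology[fits$ll >= ll_range[1] & fits$ll <= ll_range[2]]
  if (length(pool) == 0) {
    warning("no topologies in the requested score range")
    return(pool)
  }
  if (length(pool) <= k) {
    if (length(pool) < k) warning("only ", length(pool), " topologies available")
    return(pool)
  }
  pool[local_sample(seq_along(pool), k, seed)]
}

#' Read an admixture graph from text
#'
#' Accepts either the package's edge-list dialect (three whitespace-separated
#' columns: from, to, type) or the qpGraph-style layout with `root`, `label`,
#' `edge <name> <from> <to>` and `admix <child> <parent1> <parent2>` records.
#'
#' @param path Text file.
#' @return An `admix_graph`.
#' @export
read_graph_text <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  tok <- strsplit(ln, "[ \t]+")
  first <- vapply(tok, `[`, "", 1)
  if (any(first %in% c("edge", "admix", "root", "label", "vertex"))) {
    ed <- list()
    for (t in tok) {
      if (t[1] == "edge") ed[[length(ed) + 1]] <- c(t[3], t[4], "drift")
      if (t[1] == "admix") {
        ed[[length(ed) + 1]] <- c(t[3], t[2], "admix")
        ed[[length(ed) + 1]] <- c(t[4], t[2], "admix")
      }
    }
    m <- do.call(rbind, ed)
  } else {
    m <- do.call(rbind, tok)
  }
  admixture_graph(data.frame(from = m[, 1], to = m[, 2],
                             type = if (ncol(m) >= 3) m[, 3] else NULL,
                             stringsAsFactors = FALSE))
}

#' Write an admixture graph in the edge-list dialect
#'
#' @param graph An `admix_graph`.
#' @param path Output file.
#' @export
write_graph_text <- function(graph, path) {
  utils::write.table(graph$edges[, c("from", "to", "type")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
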