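## f-statistics from per-block f2 estimates, with weighted block-jackknife
## errors. All f3/f4 statistics are linear combinations of f2:
##   f4(A,B;C,D) = 1/2 [f2(A,D) + f2(B,C) - f2(A,C) - f2(B,D)]
##   f3(T;A,B)   = f4(T,A;T,B),   f2(A,B) = f4(A,B;A,B)

#' Per-population derived-allele frequencies
#'
#' @param gm A `geno_matrix`.
#' @param pops Populations (default all).
#' @param mask Optional `site_mask` restricting sites.
#' @return List with matrices `der` (derived counts), `n` (non-missing
#'   chromosome counts), `p` (frequencies), one column per population, plus
#'   the index of retained sites.
#' @export
pop_freqs <- function(gm, pops = NULL, mask = NULL) {
  pops <- pops %||% populations(gm)
  keep <- if (is.null(mask)) rep(TRUE, n_sites(gm))
          else if (inherits(mask, "site_mask")) mask$keep else as.logical(mask)
  idx <- which(keep)
  Z <- vapply(pops, function(p) as.numeric(gm$ind$pop == p),
              numeric(nrow(gm$ind)))
  ## stream over site chunks to bound peak memory on large matrices
  der <- matrix(0, length(idx), length(pops))
  n <- matrix(0, length(idx), length(pops))
  chunk <- 200000L
  for (lo in seq(1L, length(idx), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(idx))
    cc <- gm$calls[idx[lo:hi], , drop = FALSE]
    nn <- !is.na(cc)
    cc[!nn] <- 0L
    der[lo:hi, ] <- cc %*% Z
    n[lo:hi, ] <- 2 * (nn %*% Z)
  }
  p <- ifelse(n > 0, der / n, NA_real_)
  colnames(der) <- colnames(n) <- colnames(p) <- pops
  list(der = der, n = n, p = p, sites = idx)
}

#' Per-block f2 estimates for all population pairs
#'
#' For each genome block and unordered population pair computes the mean over
#' usable sites of the unbiased estimator
#' \deqn{(\hat p_A - \hat p_B)^2 - \frac{\hat p_A (1-\hat p_A)}{n_A - 1}
#'       - \frac{\hat p_B (1-\hat p_B)}{n_B - 1}}
#' with \eqn{\hat p} the sample derived frequency and n the non-missing
#' chromosome count at the site. A site is skipped for a pair when either
#' population has fewer than two chromosomes called there (or, with
#' `min_ac2 = TRUE`, fewer than two copies of either allele class observed in
#' total). These per-block estimates and their usable-site counts are the
#' basis for every f-statistic and graph fit.
#'
#' @param gm A `geno_matrix`.
#' @param blocks A `block_partition` from [assign_blocks()].
#' @param pops Populations to include (default all).
#' @param mask Optional `site_mask`.
#' @param correction Apply the finite-sample bias correction (default TRUE;
#'   the naive uncorrected estimator is available for cross-checks).
#' @param min_ac2 Require at least 2 allele copies per population at a site
#'   (default FALSE, the convention for complete simulated data).
#' @return An object of class `f2_blocks_set`.
#' @export
f2_blocks <- function(gm, blocks, pops = NULL, mask = NULL,
                      correction = TRUE, min_ac2 = FALSE) {
  stopifnot(inherits(blocks, "block_partition"))
  pops <- pops %||% populations(gm)
  pf <- pop_freqs(gm, pops, mask)
  b <- blocks$block[pf$sites]
  nb <- blocks$n_blocks
  pr <- utils::combn(length(pops), 2)
  npair <- ncol(pr)
  est <- matrix(0, npair, nb)
  cnt <- matrix(0, npair, nb)
  for (k in seq_len(npair)) {
    i <- pr[1, k]; j <- pr[2, k]
    ## sites need >=2 chromosomes per population for the bias correction;
    ## min_ac2 enforces the same floor also in uncorrected mode
    ok <- if (correction || min_ac2) pf$n[, i] >= 2 & pf$n[, j] >= 2
          else pf$n[, i] >= 1 & pf$n[, j] >= 1
    v <- (pf$p[, i] - pf$p[, j])^2
    if (correction)
      v <- v - pf$p[, i] * (1 - pf$p[, i]) / (pf$n[, i] - 1) -
               pf$p[, j] * (1 - pf$p[, j]) / (pf$n[, j] - 1)
    v[!ok] <- 0
    sums <- rowsum_by(v, b, nb)
    ns <- rowsum_by(as.numeric(ok), b, nb)
    est[k, ] <- ifelse(ns > 0, sums / ns, 0)
    cnt[k, ] <- ns
  }
  keep_b <- colSums(cnt) > 0
  structure(list(est = est[, keep_b, drop = FALSE],
                 cnt = cnt[, keep_b, drop = FALSE],
                 pairs = data.frame(a = pops[pr[1, ]], b = pops[pr[2, ]],
                                    stringsAsFactors = FALSE),
                 pops = pops,
                 block_sites = rowsum_by(rep(1, length(b)), b, nb)[keep_b],
                 settings = list(correction = correction, min_ac2 = min_ac2)),
            class = "f2_blocks_set")
}

#' Site-wise f2 cache for repeated masked evaluations
#'
#' Precomputes the per-site unbiased f2 summands for every population pair
#' once, so that per-block f2 sets for many ascertainment masks of the same
#' matrix can be assembled by subsetting (complete data only). Used by the
#' experiment runners, where dozens of SNP sets are evaluated per
#' simulation.
#'
#' @param gm A complete-data `geno_matrix`.
#' @param blocks A `block_partition`.
#' @param pops Populations (default all).
#' @return An object of class `f2_site_cache`.
#' @export
f2_site_cache <- function(gm, blocks, pops = NULL) {
  pops <- pops %||% populations(gm)
  if (anyNA(gm$calls)) stop("the site cache requires complete data")
  pf <- pop_freqs(gm, pops)
  pr <- utils::combn(length(pops), 2)
  V <- matrix(0, n_sites(gm), ncol(pr))
  for (k in seq_len(ncol(pr))) {
    i <- pr[1, k]; j <- pr[2, k]
    V[, k] <- (pf$p[, i] - pf$p[, j])^2 -
      pf$p[, i] * (1 - pf$p[, i]) / (pf$n[, i] - 1) -
      pf$p[, j] * (1 - pf$p[, j]) / (pf$n[, j] - 1)
  }
  structure(list(V = V, pairs = data.frame(a = pops[pr[1, ]],
                                           b = pops[pr[2, ]],
                                           stringsAsFactors = FALSE),
                 pops = pops, blocks = blocks),
            class = "f2_site_cache")
}

#' Per-block f2 set from a site cache and a mask
#'
#' @param cache An [f2_site_cache()].
#' @param mask Optional `site_mask` (NULL: all sites).
#' @return An `f2_blocks_set`, identical to [f2_blocks()] on the same mask.
#' @export
f2_blocks_masked <- function(cache, mask = NULL) {
  keep <- if (is.null(mask)) rep(TRUE, nrow(cache$V))
          else if (inherits(mask, "site_mask")) mask$keep else as.logical(mask)
  b <- cache$blocks$block[keep]
  nb <- cache$blocks$n_blocks
  sums <- rowsum(cache$V[keep, , drop = FALSE], b)
  ns <- rowsum_by(rep(1, length(b)), b, nb)
  full <- matrix(0, nb, ncol(cache$V))
  full[as.integer(rownames(sums)), ] <- sums
  est <- t(full) / rep(pmax(ns, 1), each = ncol(cache$V))
  keep_b <- ns > 0
  structure(list(est = est[, keep_b, drop = FALSE],
                 cnt = matrix(ns[keep_b], ncol(cache$V), sum(keep_b),
                              byrow = TRUE),
                 pairs = cache$pairs, pops = cache$pops,
                 block_sites = ns[keep_b],
                 settings = list(correction = TRUE, min_ac2 = FALSE)),
            class = "f2_blocks_set")
}

rowsum_by <- function(v, g, ng) {
  out <- numeric(ng)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.f2_blocks_set <- function(x, ...) {
  cat(sprintf("<f2_blocks_set> %d populations, %d pairs, %d blocks\n",
              length(x$pops), nrow(x$pairs), ncol(x$est)))
  invisible(x)
}

## per-block values of f2(a, b); zero vector when a == b
pair_blocks <- function(f2b, a, b) {
  if (a == b) return(rep(0, ncol(f2b$est)))
  i <- which((f2b$pairs$a == a & f2b$pairs$b == b) |
             (f2b$pairs$a == b & f2b$pairs$b == a))
  if (length(i) != 1) stop("pair not present: ", a, ", ", b)
  f2b$est[i, ]
}

f4_block_values <- function(f2b, A, B, C, D) {
  0.5 * (pair_blocks(f2b, A, D) + pair_blocks(f2b, B, C) -
         pair_blocks(f2b, A, C) - pair_blocks(f2b, B, D))
}

#' Weighted delete-one-block jackknife
#'
#' Computes the weighted overall estimate, leave-one-block-out estimates, and
#' the weighted jackknife standard error (Busing et al. formula with
#' h_j = W / w_j), the standard error convention of the f-statistic
#' toolchain. Requires at least two blocks.
#'
#' @param values Per-block statistic values.
#' @param weights Per-block weights (usable site counts).
#' @return List with `est`, `se`, `z`, `loo` (leave-one-out values),
#'   `n_blocks`.
#' @export
jackknife <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  ok <- weights > 0
  values <- values[ok]; weights <- weights[ok]
  m <- length(values)
  if (m < 2) stop("jackknife needs at least 2 non-empty blocks")
  W <- sum(weights)
  tot <- sum(values * weights)
  theta <- tot / W
  loo <- (tot - values * weights) / (W - weights)
  h <- W / weights
  tau <- h * theta - (h - 1) * loo
  theta_j <- m * theta - sum((1 - weights / W) * loo)
  varj <- mean((tau - theta_j)^2 / (h - 1))
  se <- sqrt(varj)
  list(est = theta, se = se, z = if (se > 0) theta / se else NA_real_,
       loo = loo, n_blocks = m)
}

#' Jackknife covariance across several statistics
#'
#' Covariance of a set of statistics computed from the same blocks, using the
#' same weighted pseudovalue construction as [jackknife()]; the diagonal
#' equals each statistic's jackknife variance.
#'
#' @param valmat Matrix of per-block values (statistics x blocks).
#' @param weights Per-block weights.
#' @return Covariance matrix (statistics x statistics).
#' @export
jackknife_cov <- function(valmat, weights) {
  valmat <- as.matrix(valmat)
  ok <- weights > 0
  valmat <- valmat[, ok, drop = FALSE]; weights <- weights[ok]
  m <- ncol(valmat)
  if (m < 2) stop("jackknife needs at least 2 non-empty blocks")
  W <- sum(weights)
  tot <- valmat %*% weights
  theta <- as.numeric(tot) / W
  loo <- (matrix(tot, nrow(valmat), m) - sweep(valmat, 2, weights, `*`)) /
    matrix(W - weights, nrow(valmat), m, byrow = TRUE)
  h <- W / weights
  tau <- matrix(theta, nrow(valmat), m) * matrix(h, nrow(valmat), m, byrow = TRUE) -
    sweep(loo, 2, h - 1, `*`)
  theta_j <- m * theta - as.numeric(loo %*% (1 - weights / W))
  d <- tau - matrix(theta_j, nrow(valmat), m)
  d <- sweep(d, 2, sqrt(h - 1), `/`)
  (d %*% t(d)) / m
}

## Hudson FST point estimate from precomputed frequencies (complete data)
hudson_from_freqs <- function(pf, a, b) {
  pA <- pf$p[, a]; pB <- pf$p[, b]
  nA <- pf$n[, a]; nB <- pf$n[, b]
  ok <- nA >= 2 & nB >= 2
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  sum(num[ok]) / sum(den[ok])
}

fstat_result <- function(type, pops, values, weights) {
  jk <- jackknife(values, weights)
  structure(list(type = type, pops = pops, est = jk$est, se = jk$se,
                 z = jk$z, n_blocks = jk$n_blocks, blocks = values,
                 weights = weights),
            class = "fstat")
}

#' @export
print.fstat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.2f  (%d blocks)\n",
              x$type, paste(x$pops, collapse = ", "), x$est, x$se, x$z,
              x$n_blocks))
  invisible(x)
}

f_weights <- function(f2b) f2b$block_sites

#' f4, f3 and f2 statistics with block-jackknife errors
#'
#' `f4(A,B;C,D)` measures the covariance of allele-frequency differences
#' (pA - pB)(pC - pD) and is computed per block as a linear combination of
#' f2 estimates; `f3(T;A,B) = f4(T,A;T,B)` and `f2(A,B) = f4(A,B;A,B)`.
#'
#' @param f2b An `f2_blocks_set`.
#' @param A,B,C,D,target Population labels present in `f2b`.
#' @return An `fstat` object (estimate, jackknife SE, Z, per-block values).
#' @export
f4 <- function(f2b, A, B, C, D) {
  fstat_result("f4", c(A, B, C, D), f4_block_values(f2b, A, B, C, D),
               f_weights(f2b))
}

#' @rdname f4
#' @export
f3 <- function(f2b, target, A, B) {
  fstat_result("f3", c(target, A, B),
               f4_block_values(f2b, target, A, target, B), f_weights(f2b))
}

#' @rdname f4
#' @export
f2_stat <- function(f2b, A, B) {
  fstat_result("f2", c(A, B), pair_blocks(f2b, A, B), f_weights(f2b))
}

#' Hudson FST between two populations
#'
#' Ratio-of-averages Hudson estimator: the mean over sites of the unbiased f2
#' numerator divided by the mean of \eqn{\hat p_A (1-\hat p_B) + \hat p_B
#' (1-\hat p_A)}. With a block partition, the jackknife SE of the ratio is
#' returned; without one, only the point estimate.
#'
#' @param gm A `geno_matrix`.
#' @param A,B Population labels.
#' @param mask Optional `site_mask`.
#' @param blocks Optional `block_partition` for jackknife errors.
#' @return An `fstat`-like list with `est` (and `se`, `z` when blocks given).
#' @export
fst_hudson <- function(gm, A, B, mask = NULL, blocks = NULL) {
  pf <- pop_freqs(gm, c(A, B), mask)
  ok <- pf$n[, 1] >= 2 & pf$n[, 2] >= 2
  pA <- pf$p[ok, 1]; pB <- pf$p[ok, 2]
  nA <- pf$n[ok, 1]; nB <- pf$n[ok, 2]
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  if (sum(den) == 0) stop("FST undefined: zero denominator")
  if (is.null(blocks)) {
    return(structure(list(type = "fst", pops = c(A, B),
                          est = sum(num) / sum(den), se = NA_real_,
                          z = NA_real_, n_blocks = NA_integer_),
                     class = "fstat"))
  }
  b <- blocks$block[pf$sites][ok]
  nb <- blocks$n_blocks
  nums <- rowsum_by(num, b, nb)
  dens <- rowsum_by(den, b, nb)
  cnts <- rowsum_by(rep(1, length(b)), b, nb)
  keep <- cnts > 0 & dens != 0
  nums <- nums[keep]; dens <- dens[keep]; cnts <- cnts[keep]
  m <- length(nums)
  if (m < 2) stop("jackknife needs at least 2 non-empty blocks")
  est <- sum(nums) / sum(dens)
  loo <- (sum(nums) - nums) / (sum(dens) - dens)
  W <- sum(cnts); h <- W / cnts
  tau <- h * est - (h - 1) * loo
  theta_j <- m * est - sum((1 - cnts / W) * loo)
  se <- sqrt(mean((tau - theta_j)^2 / (h - 1)))
  structure(list(type = "fst", pops = c(A, B), est = est, se = se,
                 z = if (se > 0) est / se else NA_real_, n_blocks = m),
            class = "fstat")
}

#' Derived allele frequency spectrum by hypergeometric projection
#'
#' Projects each site's derived-allele count down to a fixed number of
#' chromosomes and averages the resulting hypergeometric bin probabilities
#' over sites, yielding the expected proportion of sites per derived-allele
#' count 0..n. Optionally conditions on a mask (e.g. sites polymorphic in a
#' sample drawn at the root).
#'
#' @param gm A `geno_matrix`.
#' @param pop Population label.
#' @param n_chrom Projection size in chromosomes (default 20).
#' @param mask Optional `site_mask`.
#' @param conditioning Optional second mask; only sites kept by both are used.
#' @return An object of class `daf_spectrum`: list with `prop` (length
#'   n_chrom + 1, sums to 1), `n_chrom`, `pop`, `n_sites`.
#' @export
daf_spectrum <- function(gm, pop, n_chrom = 20, mask = NULL,
                         conditioning = NULL) {
  m <- if (is.null(mask)) rep(TRUE, n_sites(gm))
       else if (inherits(mask, "site_mask")) mask$keep else as.logical(mask)
  if (!is.null(conditioning)) {
    cm <- if (inherits(conditioning, "site_mask")) conditioning$keep
          else as.logical(conditioning)
    m <- m & cm
  }
  pf <- pop_freqs(gm, pop, site_mask(m))
  d <- pf$der[, 1]; n <- pf$n[, 1]
  ok <- n >= n_chrom
  if (!any(ok)) stop("no site has ", n_chrom, " chromosomes in ", pop)
  d <- d[ok]; n <- n[ok]
  acc <- numeric(n_chrom + 1)
  ## group identical (d, n) pairs: projection depends only on those
  key <- paste(d, n)
  tab <- table(key)
  for (k in names(tab)) {
    dn <- as.numeric(strsplit(k, " ")[[1]])
    probs <- stats::dhyper(0:n_chrom, dn[1], dn[2] - dn[1], n_chrom)
    acc <- acc + probs * tab[[k]]
  }
  structure(list(prop = acc / sum(acc), n_chrom = n_chrom, pop = pop,
                 n_sites = length(d)),
            class = "daf_spectrum")
}

#' @export
print.daf_spectrum <- function(x, ...) {
  cat(sprintf("<daf_spectrum> %s, %d chromosomes, %d sites\n",
              x$pop, x$n_chrom, x$n_sites))
  print(round(x$prop, 4))
  invisible(x)
}
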