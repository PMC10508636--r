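## Ascertainment schemes: every producer returns a site_mask with provenance.
## Pooling for MAF/DAF weights each non-missing chromosome equally
## (allele-count pooling over the union of groups), matching the
## "union of groups" phrasing used for meta-population thresholds.

pooled_freq <- function(gm, cols) {
  sub <- gm$calls[, cols, drop = FALSE]
  der <- rowSums(sub, na.rm = TRUE)
  n <- 2L * rowSums(!is.na(sub))
  list(der = der, n = n, freq = ifelse(n > 0, der / n, NA_real_))
}

#' Heterozygosity ascertainment in a single individual
#'
#' Keeps sites at which the given individual is heterozygous (dosage exactly
#' 1); missing calls are dropped. This is the scheme behind a single Human
#' Origins style SNP panel.
#'
#' @param gm A `geno_matrix`.
#' @param individual Individual id.
#' @return A `site_mask`.
#' @export
het_in_individual <- function(gm, individual) {
  j <- ind_index(gm, individual)
  d <- gm$calls[, j]
  site_mask(!is.na(d) & d == 1L, "het-in-individual",
            list(individual = individual))
}

#' Union of ascertainment panels (logical OR)
#'
#' Merges SNP sets, e.g. four single-individual heterozygosity panels into a
#' Human Origins style multi-panel array.
#'
#' @param masks List of `site_mask` objects over the same matrix.
#' @return A `site_mask`.
#' @export
union_panels <- function(masks) {
  stopifnot(length(masks) >= 1)
  len <- unique(vapply(masks, function(m) length(m$keep), 1L))
  if (length(len) != 1) stop("masks are over different matrices")
  keep <- Reduce(`|`, lapply(masks, function(m) m$keep))
  site_mask(keep, "union-of-panels",
            list(components = lapply(masks, function(m) m$scheme)))
}

#' Polymorphism ascertainment in a pooled group of individuals
#'
#' Keeps sites at which both alleles are observed among the pooled non-missing
#' calls of the listed individuals (e.g. sites polymorphic in a group of
#' high-coverage archaic genomes).
#'
#' @param gm A `geno_matrix`.
#' @param individuals Individual ids forming the ascertainment group.
#' @return A `site_mask`.
#' @export
polymorphic_in_group <- function(gm, individuals) {
  if (length(individuals) == 0) stop("empty individual list")
  j <- ind_index(gm, individuals)
  pf <- pooled_freq(gm, j)
  keep <- pf$n > 0 & pf$der > 0 & pf$der < pf$n
  site_mask(keep, "polymorphic-in-group", list(individuals = individuals))
}

#' Minor allele frequency ascertainment in a meta-population
#'
#' Pools allele counts over all non-missing calls of all individuals of the
#' listed populations and keeps sites with `min(p, 1-p) > threshold`
#' (strictly greater, matching the ">5% MAF" convention). Sites with an empty
#' pool are treated as MAF 0 and dropped.
#'
#' @param gm A `geno_matrix`.
#' @param pops Population ids pooled into the meta-population.
#' @param threshold MAF threshold (default 0.05).
#' @return A `site_mask`.
#' @export
maf_in_metapopulation <- function(gm, pops, threshold = 0.05) {
  cols <- pop_columns(gm, pops)
  pf <- pooled_freq(gm, cols)
  maf <- pmin(pf$freq, 1 - pf$freq)
  keep <- !is.na(maf) & maf > threshold
  site_mask(keep, "maf-in-metapopulation",
            list(pops = pops, threshold = threshold))
}

#' Mutation-class ascertainment
#'
#' `atgc_only()` keeps A/T and G/C SNPs (strand-symmetric, unaffected by
#' biased gene conversion and by deamination damage); `transversions_only()`
#' keeps every non-transition.
#'
#' @param gm A `geno_matrix` with allele columns populated.
#' @return A `site_mask`.
#' @export
atgc_only <- function(gm) {
  cl <- mutation_class(gm)
  site_mask(!is.na(cl) & cl == "AT/GC", "atgc-only", list())
}

#' @rdname atgc_only
#' @export
transversions_only <- function(gm) {
  cl <- mutation_class(gm)
  site_mask(!is.na(cl) & cl != "transition", "transversions-only", list())
}

#' Random thinning to a fixed site count
#'
#' Uniform sample without replacement of exactly `n_target` sites,
#' reproducible given the seed. Used both as an ascertainment and to build
#' thinned-replicate null distributions.
#'
#' @param gm A `geno_matrix`.
#' @param n_target Number of sites to keep.
#' @param seed Integer seed (mandatory).
#' @param from Optional logical vector / `site_mask` restricting the pool.
#' @return A `site_mask`.
#' @export
random_thin <- function(gm, n_target, seed, from = NULL) {
  pool <- if (is.null(from)) rep(TRUE, n_sites(gm))
          else if (inherits(from, "site_mask")) from$keep else as.logical(from)
  avail <- which(pool)
  if (n_target > length(avail))
    stop(sprintf("n_target (%d) exceeds available sites (%d)",
                 n_target, length(avail)))
  keep <- rep(FALSE, n_sites(gm))
  keep[local_sample(avail, n_target, seed)] <- TRUE
  site_mask(keep, "random-thin", list(n_target = n_target), seed = seed)
}

## sample() in a private RNG scope so schemes do not disturb the caller's RNG
local_sample <- function(x, size, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  x[sample.int(length(x), size)]
}

#' Derived-allele-frequency tail removal
#'
#' Removes sites whose pooled derived allele frequency in the union of the
#' listed populations exceeds the threshold; sites with DAF equal to the
#' threshold are kept (a `<=` rule).
#'
#' @param gm A `geno_matrix`.
#' @param pops Populations pooled for the DAF.
#' @param threshold DAF ceiling (default 0.95).
#' @return A `site_mask`.
#' @export
daf_tail_removal <- function(gm, pops, threshold = 0.95) {
  cols <- pop_columns(gm, pops)
  pf <- pooled_freq(gm, cols)
  keep <- !is.na(pf$freq) & pf$freq <= threshold
  site_mask(keep, "daf-tail-removal", list(pops = pops, threshold = threshold))
}

#' Fixed site-list ascertainment
#'
#' Keeps sites matching a user-supplied TSV list (columns: chromosome,
#' position, allele1, allele2), e.g. a 1240K-like capture panel. Matching is
#' strict on (chromosome, position, unordered allele pair); positions present
#' in the list with a mismatching allele pair are dropped with a warning.
#'
#' @param gm A `geno_matrix`.
#' @param path TSV file with columns chrom, pos, a1, a2 (no header required).
#' @return A `site_mask`.
#' @export
fixed_site_list <- function(gm, path) {
  if (!file.exists(path)) stop("missing site list: ", path)
  if (length(readLines(path, n = 1)) == 0)
    return(site_mask(rep(FALSE, n_sites(gm)), "fixed-site-list",
                     list(path = path)))
  lst <- tryCatch(utils::read.table(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stop("malformed site list: ", conditionMessage(e)))
  if (nrow(lst) > 0 && ncol(lst) < 4) stop("site list needs 4 columns (chrom pos a1 a2)")
  if (nrow(lst) == 0)
    return(site_mask(rep(FALSE, n_sites(gm)), "fixed-site-list", list(path = path)))
  poskey <- paste(gm$sites$chrom, gm$sites$pos)
  lkey <- paste(as.character(lst[[1]]), as.integer(lst[[2]]))
  hit <- poskey %in% lkey
  pairkey <- function(a, b) paste(pmin(toupper(a), toupper(b)),
                                  pmax(toupper(a), toupper(b)))
  fullkey <- paste(poskey, pairkey(gm$sites$anc, gm$sites$der))
  lfull <- paste(lkey, pairkey(as.character(lst[[3]]), as.character(lst[[4]])))
  keep <- fullkey %in% lfull
  if (any(hit & !keep))
    warning(sum(hit & !keep), " site(s) matched by position but dropped for allele mismatch")
  site_mask(keep, "fixed-site-list", list(path = path))
}
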