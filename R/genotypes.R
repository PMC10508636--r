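#' Polarized genotype matrix
#'
#' Container for diploid genotype data polarized into ancestral and derived
#' alleles. Rows of `calls` are biallelic sites ordered by (chromosome,
#' position); columns are individuals; entries are derived-allele dosages in
#' \{0, 1, 2\} or `NA` for missing calls.
#'
#' @param calls Integer matrix of derived-allele dosages (sites x individuals),
#'   values 0/1/2 or `NA`.
#' @param sites Data frame with columns `chrom`, `pos`, `anc`, `der`
#'   (1-based positions; single-base ancestral/derived alleles).
#' @param individuals Data frame with columns `id` and `pop`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, sites, individuals) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(sites), ncol(calls) == nrow(individuals))
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  stopifnot(all(c("id", "pop") %in% names(individuals)))
  if (anyDuplicated(individuals$id)) stop("duplicated individual ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$anc)) sites$anc <- NA_character_
  if (is.null(sites$der)) sites$der <- NA_character_
  o <- order(sites$chrom, sites$pos)
  if (any(o != seq_along(o))) {
    sites <- sites[o, , drop = FALSE]
    calls <- calls[o, , drop = FALSE]
  }
  rownames(sites) <- NULL
  dimnames(calls) <- list(NULL, individuals$id)
  structure(list(calls = calls, sites = sites,
                 ind = data.frame(id = as.character(individuals$id),
                                  pop = as.character(individuals$pop),
                                  stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d sites x %d individuals (%d populations)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$ind$pop))))
  invisible(x)
}

#' Number of sites / individuals / populations
#' @param gm A `geno_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$calls)

#' @rdname n_sites
#' @export
populations <- function(gm) unique(gm$ind$pop)

ind_index <- function(gm, ids) {
  i <- match(ids, gm$ind$id)
  if (anyNA(i)) stop("unknown individual id(s): ", paste(ids[is.na(i)], collapse = ", "))
  i
}

pop_columns <- function(gm, pops) {
  if (!all(pops %in% gm$ind$pop))
    stop("unknown population id(s): ",
         paste(setdiff(pops, gm$ind$pop), collapse = ", "))
  which(gm$ind$pop %in% pops)
}

#' Mutation class of each site
#'
#' Classifies biallelic SNPs into `"AT/GC"` (allele pair \{A,T\} or \{G,C\},
#' the strand-symmetric class unaffected by biased gene conversion),
#' `"transition"` (\{A,G\} or \{C,T\}), and `"transversion-other"` (the
#' remaining transversions). The three classes partition all biallelic SNPs.
#'
#' @param gm A `geno_matrix` with allele columns populated.
#' @return Character vector, one class per site.
#' @export
mutation_class <- function(gm) {
  a <- toupper(gm$sites$anc); d <- toupper(gm$sites$der)
  pair <- paste(pmin(a, d), pmax(a, d))
  out <- rep("transversion-other", length(pair))
  out[pair %in% c("A T", "C G")] <- "AT/GC"
  out[pair %in% c("A G", "C T")] <- "transition"
  out[is.na(a) | is.na(d)] <- NA_character_
  out
}

#' Subset a genotype matrix to masked sites
#'
#' @param gm A `geno_matrix`.
#' @param mask A `site_mask` (or logical vector over sites).
#' @return The `geno_matrix` restricted to the retained sites.
#' @export
apply_mask <- function(gm, mask) {
  keep <- if (inherits(mask, "site_mask")) mask$keep else as.logical(mask)
  stopifnot(length(keep) == n_sites(gm))
  gm$calls <- gm$calls[keep, , drop = FALSE]
  gm$sites <- gm$sites[keep, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm
}

## --------------------------------------------------------------------------
## site masks

#' Site mask with provenance
#'
#' A boolean keep-flag per site plus a record of the ascertainment scheme that
#' produced it. Masks compose by logical AND ([mask_and()]) or OR
#' ([union_panels()]).
#'
#' @param keep Logical vector, one flag per site.
#' @param scheme Short scheme descriptor (e.g. `"het-in-individual"`).
#' @param params Named list of scheme parameters.
#' @param seed Optional integer seed used by the scheme.
#' @export
site_mask <- function(keep, scheme = "manual", params = list(), seed = NULL) {
  structure(list(keep = as.logical(keep), scheme = scheme,
                 params = params, seed = seed),
            class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  cat(sprintf("<site_mask> %s: %d / %d sites kept\n",
              x$scheme, sum(x$keep), length(x$keep)))
  invisible(x)
}

#' @export
length.site_mask <- function(x) length(x$keep)

#' Intersect site masks (logical AND)
#'
#' @param ... `site_mask` objects over the same matrix.
#' @return A combined `site_mask`.
#' @export
mask_and <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1)
  keep <- Reduce(`&`, lapply(ms, function(m) m$keep))
  site_mask(keep, scheme = paste(vapply(ms, function(m) m$scheme, ""),
                                 collapse = " & "),
            params = list(components = lapply(ms, function(m) m$params)))
}

#' Serialize mask provenance to JSON
#' @param mask A `site_mask`.
#' @export
mask_provenance <- function(mask) {
  jsonlite::toJSON(list(scheme = mask$scheme, params = mask$params,
                        seed = mask$seed, n_kept = sum(mask$keep),
                        n_total = length(mask$keep)),
                   auto_unbox = TRUE, null = "null")
}

## --------------------------------------------------------------------------
## EIGENSTRAT I/O (unpacked ASCII)

#' Read genotypes in EIGENSTRAT format
#'
#' Reads the unpacked ASCII geno/snp/ind triplet. Genotype codes are the
#' EIGENSTRAT convention: number of *reference* alleles with 9 for missing.
#' Dosages are converted to derived-allele counts using the snp-file allele
#' columns: by convention here the snp file's second allele column (allele 2,
#' the "reference" counted by the geno file) is taken as ancestral unless
#' `ancestral = "allele1"`.
#'
#' @param prefix Path prefix; files `<prefix>.geno`, `<prefix>.snp`,
#'   `<prefix>.ind` must exist. Alternatively pass explicit paths.
#' @param geno,snp,ind Explicit file paths (override `prefix`).
#' @param ancestral Which snp-file allele column is the ancestral state,
#'   `"allele2"` (default, the allele whose count the geno file stores) or
#'   `"allele1"`.
#' @return A `geno_matrix`.
#' @export
read_eigenstrat <- function(prefix = NULL, geno = NULL, snp = NULL, ind = NULL,
                            ancestral = c("allele2", "allele1")) {
  ancestral <- match.arg(ancestral)
  if (!is.null(prefix)) {
    geno <- geno %||% paste0(prefix, ".geno")
    snp  <- snp  %||% paste0(prefix, ".snp")
    ind  <- ind  %||% paste0(prefix, ".ind")
  }
  for (f in c(geno, snp, ind)) if (!file.exists(f)) stop("missing file: ", f)
  indt <- utils::read.table(ind, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(indt) < 3) stop("ind file needs 3 columns (id, sex, population)")
  names(indt)[c(1, 3)] <- c("id", "pop")
  snpt <- utils::read.table(snp, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(snpt) < 6) stop("snp file needs 6 columns (id, chrom, gpos, pos, allele1, allele2)")
  names(snpt) <- c("snp_id", "chrom", "gpos", "pos", "a1", "a2")[seq_len(ncol(snpt))]
  glines <- readLines(geno)
  if (length(glines) != nrow(snpt))
    stop(sprintf("geno rows (%d) != snp rows (%d)", length(glines), nrow(snpt)))
  nind <- nrow(indt)
  if (any(nchar(glines) != nind))
    stop("geno line width does not match number of individuals")
  gflat <- utf8ToInt(paste(glines, collapse = "")) - utf8ToInt("0")
  if (!all(gflat %in% c(0L, 1L, 2L, 9L)))
    stop("unknown genotype code (expected 0/1/2/9)")
  calls <- matrix(gflat, nrow = length(glines), ncol = nind, byrow = TRUE)
  calls[calls == 9L] <- NA_integer_
  ## geno counts allele2-like "reference"; flip so counts are derived
  if (ancestral == "allele2") {
    anc <- snpt$a2; der <- snpt$a1
  } else {
    anc <- snpt$a1; der <- snpt$a2
    calls <- 2L - calls
  }
  geno_matrix(calls,
              data.frame(chrom = as.character(snpt$chrom), pos = snpt$pos,
                         anc = anc, der = der, stringsAsFactors = FALSE),
              data.frame(id = indt$id, pop = indt$pop, stringsAsFactors = FALSE))
}

#' Write genotypes in EIGENSTRAT format
#'
#' Inverse of [read_eigenstrat()] with `ancestral = "allele2"`: the geno file
#' stores derived-allele dosages directly (so a round trip is bit-identical),
#' allele 1 of the snp file is the derived allele and allele 2 the ancestral.
#'
#' @param gm A `geno_matrix`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_eigenstrat <- function(gm, prefix) {
  calls <- gm$calls
  calls[is.na(calls)] <- 9L
  glines <- apply(calls, 1, paste, collapse = "")
  writeLines(glines, paste0(prefix, ".geno"))
  s <- gm$sites
  snp <- data.frame(id = sprintf("snp_%d", seq_len(nrow(s))),
                    chrom = s$chrom, gpos = 0, pos = s$pos,
                    a1 = ifelse(is.na(s$der), "X", s$der),
                    a2 = ifelse(is.na(s$anc), "X", s$anc))
  utils::write.table(snp, paste0(prefix, ".snp"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ind <- data.frame(id = gm$ind$id, sex = "U", pop = gm$ind$pop)
  utils::write.table(ind, paste0(prefix, ".ind"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Thin wrapper around `vcfR`: extracts biallelic SNPs, converts GT fields to
#' REF-alt dosages, and polarizes with REF as the provisional ancestral
#' allele (re-polarize against an outgroup individual with [polarize()]).
#'
#' @param path VCF file (may be gzipped).
#' @param pop_map Named character vector mapping sample id to population;
#'   defaults to each sample being its own population.
#' @return A `geno_matrix`.
#' @export
read_vcf_genotypes <- function(path, pop_map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  bi <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  if (!all(bi)) v <- v[bi, ]
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  ids <- colnames(gt)
  pops <- if (is.null(pop_map)) ids else unname(pop_map[ids])
  geno_matrix(dose,
              data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         anc = fix[, "REF"], der = fix[, "ALT"],
                         stringsAsFactors = FALSE),
              data.frame(id = ids, pop = pops, stringsAsFactors = FALSE))
}

## --------------------------------------------------------------------------
## polarization, blocks, missingness

#' Polarize by an outgroup individual
#'
#' Re-labels ancestral/derived states so that the outgroup individual's allele
#' is ancestral. Sites where the outgroup is missing or heterozygous are
#' dropped. Applying the operation twice with the same outgroup equals
#' applying it once.
#'
#' @param gm A `geno_matrix`.
#' @param outgroup Individual id used as the ancestral-state source.
#' @return A polarized `geno_matrix` (possibly with fewer sites).
#' @export
polarize <- function(gm, outgroup) {
  j <- ind_index(gm, outgroup)
  og <- gm$calls[, j]
  keep <- !is.na(og) & og != 1L
  flip <- keep & og == 2L           # outgroup homozygous derived -> swap labels
  calls <- gm$calls
  calls[flip, ] <- 2L - calls[flip, , drop = FALSE]
  sites <- gm$sites
  tmp <- sites$anc[flip]
  sites$anc[flip] <- sites$der[flip]
  sites$der[flip] <- tmp
  gm$calls <- calls[keep, , drop = FALSE]
  gm$sites <- sites[keep, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm
}

#' Assign sites to jackknife genome blocks
#'
#' Blocks are contiguous `block_size`-bp intervals that never span
#' chromosomes: a site at position p maps to local block `floor((p-1)/size)`
#' within its chromosome, and non-empty blocks are numbered consecutively
#' across chromosomes.
#'
#' @param gm A `geno_matrix` (sites sorted by chromosome, position).
#' @param block_size Block length in bp (default 4 Mb).
#' @return A `block_partition`: list with `block` (integer block index per
#'   site), `n_blocks`, and `sites_per_block`.
#' @export
assign_blocks <- function(gm, block_size = 4e6) {
  s <- gm$sites
  if (is.unsorted(order(s$chrom, s$pos)) ||
      any(tapply(s$pos, s$chrom, is.unsorted)))
    stop("sites must be sorted by position within chromosome")
  local <- floor((s$pos - 1) / block_size)
  key <- paste(s$chrom, local, sep = ":")
  block <- match(key, unique(key))
  structure(list(block = block, n_blocks = max(block),
                 block_size = block_size,
                 sites_per_block = tabulate(block)),
            class = "block_partition")
}

#' Missing-data site filter
#'
#' Group-level completeness: a site is kept iff every listed population has at
#' least one non-missing individual call there ("no missing data at the group
#' level"). The stricter per-individual variant (`level = "individual"`)
#' requires every individual of the listed populations to be called.
#'
#' @param gm A `geno_matrix`.
#' @param pops Populations that must be complete; an empty vector keeps all
#'   sites.
#' @param level `"group"` (default) or `"individual"`.
#' @return A `site_mask`.
#' @export
filter_missing <- function(gm, pops, level = c("group", "individual")) {
  level <- match.arg(level)
  if (length(pops) == 0)
    return(site_mask(rep(TRUE, n_sites(gm)), "missingness",
                     list(pops = character(0), level = level)))
  keep <- rep(TRUE, n_sites(gm))
  for (p in pops) {
    cols <- pop_columns(gm, p)
    miss <- is.na(gm$calls[, cols, drop = FALSE])
    keep <- keep & if (level == "group") rowSums(!miss) > 0 else rowSums(miss) == 0
  }
  site_mask(keep, "missingness", list(pops = pops, level = level))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
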