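## Bias and power quantification for ascertainment schemes: flipped-verdict
## fractions over graph collections, residual SE / R-squared of Z-score
## trends, percentile classifiers against thinned-replicate nulls, and power
## against known-incorrect graphs.

#' Flipped-verdict fractions between two fit tables
#'
#' Given worst-residual values for the same topologies fitted on all sites
#' and on an ascertained set: the bias fraction is the share of topologies
#' rejected under ascertainment (WR > threshold) but accepted on all sites
#' (WR < threshold); the power fraction is the reverse. Swapping the two
#' inputs exchanges the fractions.
#'
#' @param wr_all,wr_asc Numeric vectors of worst residuals, aligned by
#'   topology (or data frames with columns `topology` and `wr`).
#' @param threshold Verdict threshold in SE units (default 3).
#' @return Named vector `c(bias = ..., power = ...)`.
#' @export
flipped_fractions <- function(wr_all, wr_asc, threshold = 3) {
  if (is.data.frame(wr_all)) {
    stopifnot(is.data.frame(wr_asc))
    m <- match(wr_all$topology, wr_asc$topology)
    if (anyNA(m)) stop("fit tables do not align")
    wr_asc <- wr_asc$wr[m]; wr_all <- wr_all$wr
  }
  stopifnot(length(wr_all) == length(wr_asc))
  if (length(wr_all) == 0) stop("empty fit tables")
  c(bias = mean(wr_asc > threshold & wr_all < threshold),
    power = mean(wr_asc < threshold & wr_all > threshold))
}

#' Residual SE and correlation of a linear trend
#'
#' Ordinary least squares of the ascertained values on the all-sites values
#' (optionally with the intercept fixed at zero). The residual standard
#' error, expressed in the same units as the inputs (typically f4 Z-scores),
#' reflects both ascertainment bias and site-sampling variance.
#'
#' @param x Values on all sites.
#' @param y Values under ascertainment.
#' @param zero_intercept Fix the intercept at 0 (default FALSE).
#' @param z_cap If non-NULL, restrict to points with `|x| < z_cap` (the
#'   trend-summary convention uses 15).
#' @return List with `residual_se`, `r2`, `slope`, `intercept`, `n`.
#' @export
trend_dispersion <- function(x, y, zero_intercept = FALSE, z_cap = NULL) {
  stopifnot(length(x) == length(y))
  if (!is.null(z_cap)) {
    keep <- abs(x) < z_cap
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("degenerate x (zero variance)")
  fit <- if (zero_intercept) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  p <- length(stats::coef(fit))
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  list(residual_se = sqrt(rss / (length(x) - p)),
       r2 = r2,
       slope = unname(stats::coef(fit)[if (zero_intercept) "x" else "x"]),
       intercept = if (zero_intercept) 0 else unname(stats::coef(fit)[1]),
       n = length(x))
}

#' Percentile classifier against a thinned-replicate null
#'
#' A metric value is classified as biased when it falls strictly beyond the
#' configured percentile of its null distribution across randomly thinned
#' SNP sets (the 2.5% tail of 200 replicates by default; a 10th-percentile /
#' 10-replicate variant is used for simulated data).
#'
#' @param value Metric value under the ascertainment being classified.
#' @param null Numeric vector of the metric across thinned replicates.
#' @param side `"upper"` (biased when too large, e.g. residual SE) or
#'   `"lower"` (biased when too small, e.g. R-squared).
#' @param percentile Tail probability (default 0.025).
#' @return List with `biased` (logical), `threshold`, `percentile`, `side`.
#' @export
classify_bias <- function(value, null, side = c("upper", "lower"),
                          percentile = 0.025) {
  side <- match.arg(side)
  if (length(null) < 2) stop("null distribution too small")
  if (length(null) * min(percentile, 1 - percentile) < 0.5 &&
      length(null) < 1 / percentile)
    warning("null has few replicates for the requested percentile")
  thr <- stats::quantile(null, if (side == "upper") 1 - percentile else percentile,
                         names = FALSE)
  biased <- if (side == "upper") value > thr else value < thr
  list(biased = biased, threshold = thr, percentile = percentile, side = side)
}

#' Thinned-replicate null distribution of a metric
#'
#' Draws `n_rep` random site subsets of exactly `n_target` sites (matching
#' the ascertained panel's size) with recorded seeds and evaluates the
#' metric on each.
#'
#' @param gm A `geno_matrix`.
#' @param n_target Number of sites per replicate.
#' @param metric_fun Function taking a `site_mask` and returning a scalar.
#' @param n_rep Number of replicates (default 200; 10 in the simulated-data
#'   variant).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param from Optional mask restricting the sampling pool.
#' @return List with `values` and `seeds`.
#' @export
thinned_null <- function(gm, n_target, metric_fun, n_rep = 200, seed = 1,
                         from = NULL) {
  seeds <- seed + seq_len(n_rep)
  values <- vapply(seeds, function(s)
    metric_fun(random_thin(gm, n_target, seed = s, from = from)), numeric(1))
  list(values = values, seeds = seeds)
}

#' Power against known-incorrect graphs
#'
#' Summarizes fits of a set of poorly-fitting topologies on all sites versus
#' an ascertained set: the median worst-residual difference (ascertained
#' minus all-sites; positive means ascertainment pushes wrong models further
#' from acceptance) and the proportion of incorrect graphs that flip from
#' rejected on all sites to accepted under ascertainment.
#'
#' @param wr_all,wr_asc Worst residuals of the incorrect graphs, aligned.
#' @param threshold Verdict threshold (default 3).
#' @return Named vector `c(median_delta = ..., flip = ...)`.
#' @export
power_vs_incorrect <- function(wr_all, wr_asc, threshold = 3) {
  stopifnot(length(wr_all) == length(wr_asc))
  if (length(wr_all) == 0) stop("empty fit set")
  c(median_delta = stats::median(wr_asc - wr_all),
    flip = mean(wr_all > threshold & wr_asc < threshold))
}
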