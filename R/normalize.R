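#' Median-of-ratios size factors
#'
#' The classical RNA-seq library-size estimator: each sample's factor is the
#' median, over reference analytes (those with no zero count), of the ratio
#' of its count to the analyte's geometric mean across samples. Factors are
#' rescaled to geometric mean 1 so normalized values stay on the counts
#' scale.
#'
#' @param counts a [feature_table()] of raw counts.
#' @return tibble with `sample_id` and `size_factor`.
#' @examples
#' m <- matrix(c(1, 2, 4, 2, 4, 8), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' size_factors_median_ratio(feature_table(m, "rna_counts"))
#' @export
size_factors_median_ratio <- function(counts) {
  stopifnot(inherits(counts, "feature_table"))
  x <- unclass(counts)
  ref <- rowSums(x <= 0) == 0
  if (!any(ref)) {
    abort("no analyte with all-positive counts; add a pseudocount before estimating size factors")
  }
  logx <- log(x[ref, , drop = FALSE])
  loggeo <- rowMeans(logx)
  # median of ratios taken on the log scale (even reference counts use the
  # log-scale midpoint), then rescaled to geometric mean 1
  raw <- apply(logx - loggeo, 2, median)
  raw <- raw - mean(raw)
  tibble(sample_id = colnames(x), size_factor = unname(exp(raw)))
}

#' Apply size factors (with optional log2 transform)
#'
#' @param counts a [feature_table()].
#' @param factors tibble from [size_factors_median_ratio()] (or any tibble
#'   with `sample_id`, `size_factor`).
#' @param log2 if `TRUE`, return `log2(value / factor + pseudocount)`.
#' @param pseudocount pseudocount for the log transform (default 1).
#' @return a normalized [feature_table()].
#' @export
normalize_counts <- function(counts, factors, log2 = FALSE, pseudocount = 1) {
  stopifnot(inherits(counts, "feature_table"))
  miss <- setdiff(colnames(counts), factors$sample_id)
  if (length(miss)) abort(paste0("missing size factor for sample(s): ", paste(miss, collapse = ", ")))
  f <- setNames(factors$size_factor, factors$sample_id)[colnames(counts)]
  if (any(f <= 0)) abort("size factors must be > 0")
  out <- sweep(unclass(counts), 2, f, `/`)
  if (log2) out <- log2(out + pseudocount)
  ft_replace(counts, out, normalized = TRUE)
}

#' Per-sample relative abundance
#'
#' Rescales each sample (column) to sum to 1. Tables already tagged as
#' microbiome relative abundances with column sums of 1 pass through
#' unchanged.
#'
#' @param table a [feature_table()] of non-negative values.
#' @return a [feature_table()] whose columns each sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- unclass(table)
  tot <- colSums(x)
  if (any(tot <= 0)) {
    abort(paste0("zero-sum sample(s): ",
                 paste(colnames(x)[tot <= 0], collapse = ", ")))
  }
  if (all(abs(tot - 1) < 1e-12)) return(ft_replace(table, x, normalized = TRUE))
  ft_replace(table, sweep(x, 2, tot, `/`), normalized = TRUE)
}

#' Counts per million
#'
#' @param counts a [feature_table()] of non-negative counts.
#' @return a [feature_table()] with each column scaled to a library of 1e6.
#' @export
cpm <- function(counts) {
  stopifnot(inherits(counts, "feature_table"))
  x <- unclass(counts)
  tot <- colSums(x)
  if (any(tot <= 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(colnames(x)[tot <= 0], collapse = ", ")))
  }
  ft_replace(counts, sweep(x, 2, tot, `/`) * 1e6, normalized = TRUE)
}

#' Intensity normalization (log2 + per-sample median centering)
#'
#' Default stand-in normalization for proteomic / metabolomic intensity
#' tables: log2 transform with a pseudocount, then subtract each sample's
#' median so sample medians align at 0. The choice is recorded in the
#' returned table's `normalization` attribute.
#'
#' @param table a [feature_table()] of intensities.
#' @param pseudocount added before the log2 (default 1).
#' @return a normalized [feature_table()].
#' @export
normalize_intensity <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "feature_table"))
  x <- log2(unclass(table) + pseudocount)
  x <- sweep(x, 2, apply(x, 2, median), `-`)
  out <- ft_replace(table, x, normalized = TRUE)
  attr(out, "normalization") <- "log2_median_center"
  out
}
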