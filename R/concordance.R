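#' Promoter windows around transcription start sites
#'
#' Builds the TSS +/- `halfwidth` bp window for every gene as a 0-based
#' half-open interval `[tss - halfwidth, tss + halfwidth + 1)` — 1001
#' positions at the default halfwidth of 500 — clamped at position 0. The
#' window is symmetric around the TSS and therefore strand-independent.
#'
#' @param annotation TSS tibble (`gene_id`, `chrom`, `tss`, optionally
#'   `strand`; see [read_tss_bed()]).
#' @param halfwidth window half-width in bp (default 500).
#' @return tibble with `gene_id`, `chrom`, `start`, `end`.
#' @examples
#' tss_windows(tibble::tibble(gene_id = "g", chrom = "chr1", tss = 1000))
#' @export
tss_windows <- function(annotation, halfwidth = 500) {
  if (halfwidth < 0) abort("`halfwidth` must be >= 0")
  tibble(gene_id = annotation$gene_id, chrom = annotation$chrom,
         start = pmax(0L, as.integer(annotation$tss) - as.integer(halfwidth)),
         end = as.integer(annotation$tss) + as.integer(halfwidth) + 1L)
}

#' Sum accessibility fragments over promoter windows
#'
#' Accepts fragment records as a BED-like tibble (`chrom`, `start`, `end`,
#' `count`, and a `sample` column naming the group each fragment belongs
#' to) and sums, per gene and group, the counts of all fragments
#' overlapping the gene's window (overlap = any shared position under
#' 0-based half-open coordinates). A precomputed gene-by-group
#' [feature_table()] of window counts passes through unchanged.
#'
#' @param fragments BED-like fragment tibble, or a `fragment_counts`
#'   [feature_table()].
#' @param windows promoter windows from [tss_windows()].
#' @return a [feature_table()] (modality `fragment_counts`) of summed
#'   window counts, genes x groups. Genes whose window lies on a
#'   chromosome absent from the fragments get zero counts and are listed in
#'   the `missing_chrom` attribute.
#' @export
window_accessibility <- function(fragments, windows) {
  if (inherits(fragments, "feature_table")) {
    stopifnot(ft_modality(fragments) == "fragment_counts")
    return(fragments)
  }
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(fragments))
  if (length(miss)) abort(paste0("fragments missing column(s): ", paste(miss, collapse = ", ")))
  if (!"count" %in% names(fragments)) fragments$count <- 1
  if (!"sample" %in% names(fragments)) fragments$sample <- "all"
  if (any(windows$end <= windows$start)) abort("degenerate window(s)")
  groups <- sort(unique(fragments$sample))
  m <- matrix(0, nrow(windows), length(groups),
              dimnames = list(windows$gene_id, groups))
  frag_by_chrom <- split(fragments, fragments$chrom)
  missing_chrom <- character(0)
  for (i in seq_len(nrow(windows))) {
    fr <- frag_by_chrom[[windows$chrom[i]]]
    if (is.null(fr)) {
      missing_chrom <- c(missing_chrom, windows$gene_id[i])
      next
    }
    ov <- fr$start < windows$end[i] & fr$end > windows$start[i]
    if (any(ov)) {
      sums <- tapply(fr$count[ov], fr$sample[ov], sum)
      m[i, names(sums)] <- sums
    }
  }
  out <- feature_table(m, modality = "fragment_counts")
  attr(out, "missing_chrom") <- missing_chrom
  if (length(missing_chrom)) {
    warn(sprintf("%d gene window(s) on chromosomes with no fragments", length(missing_chrom)))
  }
  out
}

#' Log2 accessibility difference between two conditions
#'
#' @param cpm_a,cpm_b named numeric vectors of CPM-normalized window counts
#'   over the same gene universe (baseline and comparison).
#' @param pseudocount added to both sides before the ratio (default 1).
#' @return tibble with `gene_id` and `acc_delta`
#'   (`log2((cpm_b + pc) / (cpm_a + pc))`).
#' @export
accessibility_delta <- function(cpm_a, cpm_b, pseudocount = 1) {
  if (!setequal(names(cpm_a), names(cpm_b))) {
    abort("the two conditions must share the same gene universe")
  }
  genes <- names(cpm_a)
  tibble(gene_id = genes,
         acc_delta = log2((unname(cpm_b[genes]) + pseudocount) /
                          (unname(cpm_a[genes]) + pseudocount)))
}

#' Concordance of promoter accessibility changes with expression changes
#'
#' Stratifies genes by differential-expression direction and tests, with a
#' one-sided rank-sum test, whether the accessibility log2 differences of
#' upregulated DEGs exceed those of downregulated DEGs (open chromatin
#' tracking increased expression). Also reports the Spearman correlation
#' between accessibility delta and expression log2FC over all matched
#' genes.
#'
#' @param deltas tibble from [accessibility_delta()].
#' @param degs tibble with `analyte_id` (or `gene_id`), `log2fc`, and a
#'   `deg` flag or pre-filtered rows; direction is the sign of `log2fc`.
#' @return list (class `concordance_result`): `p_value` (one-sided,
#'   up > down), `correlation` (Spearman rho), `n_up`, `n_down`,
#'   `matched` (per-gene tibble).
#' @export
concordance_test <- function(deltas, degs) {
  if ("gene_id" %in% names(degs) && !"analyte_id" %in% names(degs)) {
    degs <- rename(degs, analyte_id = "gene_id")
  }
  if ("deg" %in% names(degs)) degs <- filter(degs, .data$deg)
  matched <- inner_join(deltas, select(degs, "analyte_id", "log2fc"),
                        by = c(gene_id = "analyte_id"))
  up <- matched$acc_delta[matched$log2fc > 0]
  down <- matched$acc_delta[matched$log2fc < 0]
  if (length(up) < 2) abort("up-DEG stratum has < 2 genes")
  if (length(down) < 2) abort("down-DEG stratum has < 2 genes")
  exact <- length(up) <= 8 && length(down) <= 8 && !anyDuplicated(c(up, down))
  p <- suppressWarnings(
    wilcox.test(up, down, alternative = "greater", exact = exact, correct = TRUE)$p.value
  )
  rho <- suppressWarnings(cor(matched$acc_delta, matched$log2fc, method = "spearman"))
  structure(list(p_value = p, correlation = rho,
                 n_up = length(up), n_down = length(down), matched = matched),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> up(n=%d) vs down(n=%d): one-sided rank-sum p = %.3g, Spearman rho = %.3f\n",
              x$n_up, x$n_down, x$p_value, x$correlation))
  invisible(x)
}

#' @export
glance.concordance_result <- function(x, ...) {
  tibble(p_value = x$p_value, correlation = x$correlation,
         n_up = x$n_up, n_down = x$n_down)
}
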