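#' Analyte-by-sample abundance tables
#'
#' A `feature_table` is the package's core container: a numeric matrix of
#' abundances with analytes as rows and samples as columns, tagged with the
#' assay modality and a flag saying whether the values have already been
#' normalized. All statistics in the package consume this container; the
#' orientation (analytes x samples) is fixed and asserted at every boundary.
#'
#' @param x a numeric matrix with rownames (analyte ids) and colnames
#'   (sample ids), or a data frame whose first column holds analyte ids and
#'   whose remaining columns are one sample each.
#' @param modality assay modality, one of
#'   `"rna_counts"`, `"protein_intensity"`, `"metabolite_intensity"`,
#'   `"cytokine"`, `"microbiome_relabund"`, `"fragment_counts"`.
#' @param normalized logical; `TRUE` once values have passed through a
#'   normalization stage. Raw (`normalized = FALSE`) values must be
#'   non-negative.
#'
#' @return a `feature_table` object.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' ft <- feature_table(m, "rna_counts")
#' dim(ft)
#' @export
feature_table <- function(x, modality, normalized = FALSE) {
  modality <- match.arg(modality, ft_modalities())
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    vals <- as.matrix(x[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(x[-1], is.numeric, logical(1)))
      abort(paste0("non-numeric sample column(s): ",
                   paste(names(x)[-1][bad], collapse = ", ")))
    }
    rownames(vals) <- ids
    x <- vals
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or a data frame")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("`x` needs rownames (analyte ids) and colnames (sample ids)")
  }
  check_unique_ids(rownames(x), "analyte")
  check_unique_ids(colnames(x), "sample")
  if (any(!is.finite(x))) abort("values must all be finite")
  if (!normalized && any(x < 0)) abort("raw (non-normalized) values must be >= 0")
  structure(x, class = c("feature_table", "matrix", "array"),
            modality = modality, normalized = normalized)
}

ft_modalities <- function() {
  c("rna_counts", "protein_intensity", "metabolite_intensity",
    "cytokine", "microbiome_relabund", "fragment_counts")
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate ", what, " id(s): ", paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d analytes x %d samples  modality=%s  normalized=%s\n",
              nrow(x), ncol(x), attr(x, "modality"), attr(x, "normalized")))
  n <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @rdname feature_table
#' @param ft a `feature_table`.
#' @export
ft_modality <- function(ft) attr(ft, "modality")

#' @rdname feature_table
#' @export
ft_normalized <- function(ft) isTRUE(attr(ft, "normalized"))

#' @rdname feature_table
#' @export
analyte_ids <- function(ft) rownames(ft)

#' @rdname feature_table
#' @export
sample_ids <- function(ft) colnames(ft)

# rebuild a feature_table around a transformed matrix, keeping/overriding tags
ft_replace <- function(ft, values, normalized = ft_normalized(ft),
                       modality = ft_modality(ft)) {
  feature_table(values, modality = modality, normalized = normalized)
}

#' Long-format view of a feature table
#'
#' @param x a `feature_table`.
#' @param ... unused.
#' @return a tibble with one row per analyte x sample cell
#'   (`analyte_id`, `sample_id`, `value`).
#' @export
tidy.feature_table <- function(x, ...) {
  tibble(
    analyte_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' @export
as_tibble.feature_table <- function(x, ...) {
  bind_cols(tibble(analyte_id = rownames(x)),
            as_tibble(`attributes<-`(unclass(x), list(dim = dim(x), dimnames = dimnames(x)))))
}

#' One-row summary of a feature table
#'
#' @param x a `feature_table`.
#' @param ... unused.
#' @export
glance.feature_table <- function(x, ...) {
  tibble(n_analytes = nrow(x), n_samples = ncol(x),
         modality = ft_modality(x), normalized = ft_normalized(x),
         total = sum(x))
}
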