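#' Read an analyte-by-sample abundance table
#'
#' Expects delimited text with the analyte id in the first column and one
#' sample per remaining column. The delimiter is tab by default; a comma is
#' auto-detected from the header line. Parsing is locale-independent
#' (`.` decimal separator, no grouping marks).
#'
#' @param path file path.
#' @param modality assay modality tag (see [feature_table()]).
#' @param normalized whether values in the file are already normalized.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, modality, normalized = FALSE) {
  delim <- detect_delim(path)
  # base parser: locale-independent and correctly-rounding, so written
  # tables read back bitwise-identical
  df <- utils::read.delim(path, sep = delim, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("feature table needs an id column and >= 1 sample column")
  check_unique_ids(names(df)[-1], "sample")
  vals <- df[-1]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))
      abort(sprintf("non-numeric cell(s) in column '%s', row(s) %s",
                    names(vals)[j], paste(head(bad_rows, 5), collapse = ", ")))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(df[[1]])
  feature_table(m, modality = modality, normalized = normalized)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header, fixed = TRUE) && grepl(",", header, fixed = TRUE)) "," else "\t"
}

#' Write a feature table as TSV
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param header_lines optional character vector of provenance lines, written
#'   as `#`-prefixed comments before the table.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("analyte_id", colnames(ft)), collapse = "\t"), con)
  body <- apply(unclass(ft), 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(ft), body, sep = "\t"), con)
  invisible(path)
}

#' Read a merged MetaPhlAn-style relative abundance table
#'
#' Keeps only species-level rows (taxonomy strings whose deepest
#' pipe-delimited rank starts with `s__`), names each analyte by that
#' species token, and tags the result as `microbiome_relabund`.
#'
#' @param path file path to the merged table (first column taxonomy string).
#' @return a [feature_table()] of species rows.
#' @export
read_metaphlan_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  taxa <- as.character(df[[1]])
  deepest <- vapply(strsplit(taxa, "|", fixed = TRUE),
                    function(p) p[[length(p)]], character(1))
  keep <- startsWith(deepest, "s__")
  if (!any(keep)) abort("no species-level (s__) rows found")
  m <- as.matrix(df[keep, -1, drop = FALSE])
  rownames(m) <- deepest[keep]
  feature_table(m, modality = "microbiome_relabund", normalized = TRUE)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is tab-delimited: set name, description, then one member id per field.
#' The collection is a named list of character vectors with the descriptions
#' kept as an attribute.
#'
#' @param path file path.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1L)
  check_unique_ids(names_, "gene set")
  sets <- map(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- names_[lengths(sets) == 0]
  if (length(empty)) abort(paste0("empty gene set(s): ", paste(empty, collapse = ", ")))
  names(sets) <- names_
  structure(sets, class = "gene_set_collection",
            description = setNames(vapply(parts, `[[`, character(1), 2L), names_))
}

#' @rdname read_gmt
#' @param sets a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, member counts %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read a BED-like TSS annotation
#'
#' Four or more tab-separated columns: chromosome, position (0-based TSS),
#' gene id, strand. Extra columns are ignored.
#'
#' @param path file path.
#' @return tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 4) abort("TSS annotation needs >= 4 columns (chrom, pos, gene, strand)")
  out <- tibble(gene_id = as.character(df[[3]]), chrom = as.character(df[[1]]),
                tss = as.integer(df[[2]]), strand = as.character(df[[4]]))
  if (any(out$tss < 0)) abort("TSS positions must be >= 0")
  if (anyDuplicated(out$gene_id)) abort("duplicate gene ids in TSS annotation")
  out
}

#' Read sample metadata
#'
#' Delimited text with columns `sample_id`, `subject_id`, `timepoint_label`
#' and optionally `day_offset`.
#'
#' @param path file path.
#' @return a tibble of sample metadata.
#' @export
read_sample_info <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path), comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "subject_id", "timepoint_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("sample info missing column(s): ", paste(miss, collapse = ", ")))
  check_unique_ids(df$sample_id, "sample")
  df$timepoint_label <- canonical_timepoint(df$timepoint_label)
  as_tibble(df)
}

#' @rdname read_sample_info
#' @param samples a sample-metadata tibble.
#' @export
write_sample_info <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}
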