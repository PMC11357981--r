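#' Named phase contrasts
#'
#' A contrast compares a set of comparison timepoints against a set of
#' baseline timepoints. The default registry holds the five mission
#' profiles: the flight profile FP1 (pre-flight baseline vs R+1), recovery
#' profiles RP1 (vs R+45) and RP2 (vs R+82), and longitudinal profiles LP1
#' (vs R+45 and R+82 pooled) and LP2 (vs R+82). Only LP2's composition is
#' fixed by convention (pre-flight vs R+82); the others are registry
#' defaults and can be overridden per run.
#'
#' @param name contrast name.
#' @param baseline,comparison character vectors of timepoint labels;
#'   disjoint and non-empty.
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(name, baseline, comparison) {
  baseline <- canonical_timepoint(baseline)
  comparison <- canonical_timepoint(comparison)
  if (!length(baseline) || !length(comparison)) {
    abort("baseline and comparison must be non-empty")
  }
  if (length(intersect(baseline, comparison))) {
    abort("baseline and comparison must be disjoint")
  }
  structure(list(name = name, baseline = baseline, comparison = comparison),
            class = "contrast_spec")
}

#' @rdname contrast_spec
#' @export
contrast_registry <- function() {
  pre <- c("L-92", "L-44", "L-3")
  list(
    FP1 = contrast_spec("FP1", pre, "R+1"),
    RP1 = contrast_spec("RP1", pre, "R+45"),
    RP2 = contrast_spec("RP2", pre, "R+82"),
    LP1 = contrast_spec("LP1", pre, c("R+45", "R+82")),
    LP2 = contrast_spec("LP2", pre, "R+82")
  )
}

#' Pseudobulk aggregation across cell-type tables
#'
#' Element-wise sum of per-group (for example per-cell-type) count tables
#' over an identical analyte-by-sample universe, emulating a bulk
#' measurement.
#'
#' @param tables list of [feature_table()]s with identical dimnames.
#' @return a single summed [feature_table()].
#' @export
pseudobulk_aggregate <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(rownames(t), rownames(ref)) ||
        !identical(colnames(t), colnames(ref))) {
      abort("all tables must share the same analytes and samples")
    }
  }
  total <- Reduce(`+`, map(tables, unclass))
  feature_table(total, modality = ft_modality(ref), normalized = FALSE)
}

#' Rank-sum differential test for a phase contrast
#'
#' Per analyte: a two-sided Wilcoxon rank-sum test of comparison vs
#' baseline values (exact when the values are untied and both sides are
#' below 50, normal approximation with continuity correction otherwise), a
#' fold change
#' `log2FC = log2((mean_comparison + eps) / (mean_baseline + eps))`, and a
#' multiplicity-adjusted p-value.
#'
#' @param table a [feature_table()].
#' @param samples sample metadata tibble.
#' @param contrast a [contrast_spec()].
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param pseudocount eps in the fold-change (default 1 for count-scale
#'   tables, use 0 for log-scale intensities).
#' @param group optional label recorded in the `group` column (e.g. a cell
#'   type) — adjustment is per call, i.e. within group.
#' @return tibble (class `differential_result`): `analyte_id`, `group`,
#'   `log2fc`, `p_value`, `adj_p`, `deg` (called at the default thresholds;
#'   recall with [call_degs()] for other thresholds).
#' @export
differential_test <- function(table, samples, contrast, adjust = c("BH", "bonferroni"),
                              pseudocount = 1, group = NA_character_) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(table, "feature_table"), inherits(contrast, "contrast_spec"))
  samples$timepoint_label <- canonical_timepoint(samples$timepoint_label)
  base_ids <- samples$sample_id[samples$timepoint_label %in% contrast$baseline]
  comp_ids <- samples$sample_id[samples$timepoint_label %in% contrast$comparison]
  base_ids <- intersect(base_ids, colnames(table))
  comp_ids <- intersect(comp_ids, colnames(table))
  if (!length(base_ids) || !length(comp_ids)) {
    abort(sprintf("contrast %s: empty side (baseline %d, comparison %d samples)",
                  contrast$name, length(base_ids), length(comp_ids)))
  }
  x <- unclass(table)
  xb <- x[, base_ids, drop = FALSE]
  xc <- x[, comp_ids, drop = FALSE]
  lfc <- unname(log2((rowMeans(xc) + pseudocount) / (rowMeans(xb) + pseudocount)))
  p <- vapply(seq_len(nrow(x)), function(i) {
    ranksum_p(xc[i, ], xb[i, ])
  }, double(1))
  adj <- p.adjust(p, method = ifelse(adjust == "BH", "BH", "bonferroni"))
  out <- tibble(analyte_id = rownames(x), group = group,
                contrast = contrast$name, log2fc = lfc,
                p_value = p, adj_p = adj)
  out$deg <- deg_flag(out$adj_p, out$log2fc, 0.05, 0.5)
  structure(out, class = c("differential_result", class(out)),
            contrast = contrast, adjust = adjust,
            n_baseline = length(base_ids), n_comparison = length(comp_ids))
}

# two-sided rank-sum p; exact enumeration for untied samples below 50 per
# side, midrank normal approximation with continuity correction otherwise
ranksum_p <- function(a, b) {
  if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
  exact <- length(a) < 50 && length(b) < 50 && !anyDuplicated(c(a, b))
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact, correct = TRUE)$p.value
  )
}

deg_flag <- function(adj_p, lfc, alpha, tau) {
  !is.na(adj_p) & adj_p < alpha & abs(lfc) > tau
}

#' @export
glance.differential_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  tibble(contrast = ct$name, n_analytes = nrow(x), n_deg = sum(x$deg),
         n_baseline = attr(x, "n_baseline"), n_comparison = attr(x, "n_comparison"),
         adjust = attr(x, "adjust"))
}

#' Call differentially expressed analytes
#'
#' Strict thresholds as conventionally reported: adjusted p strictly below
#' `alpha` and |log2FC| strictly above `lfc_threshold`.
#'
#' @param records a [differential_test()] tibble.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_threshold |log2FC| threshold (default 0.5).
#' @return character vector of DEG analyte ids.
#' @export
call_degs <- function(records, alpha = 0.05, lfc_threshold = 0.5) {
  records$analyte_id[deg_flag(records$adj_p, records$log2fc, alpha, lfc_threshold)]
}

#' Fraction of target-profile DEGs shared with a reference profile
#'
#' `|target intersect reference| / |target|`. An empty target set yields
#' `NA` (undefined), not 0.
#'
#' @param reference_degs,target_degs character vectors of DEG ids.
#' @return a single fraction in `[0, 1]`, or `NA` for an empty target.
#' @export
shared_fraction <- function(reference_degs, target_degs) {
  if (!length(reference_degs)) abort("reference DEG set is empty")
  if (!length(target_degs)) return(NA_real_)
  length(intersect(target_degs, reference_degs)) / length(target_degs)
}

#' Classify fold-change directionality between two profiles
#'
#' For an analyte that is differential in both profiles: `"reversed"` when
#' the log2FC signs differ (return toward / past baseline), `"persistent"`
#' when they agree.
#'
#' @param lfc_reference,lfc_target log2 fold changes (finite, non-zero).
#' @return character vector of `"reversed"` / `"persistent"`.
#' @export
reversal_classification <- function(lfc_reference, lfc_target) {
  if (any(!is.finite(lfc_reference)) || any(!is.finite(lfc_target)) ||
      any(lfc_reference == 0) || any(lfc_target == 0)) {
    abort("log2FCs must be finite and non-zero (DEGs under a strict threshold)")
  }
  ifelse(sign(lfc_reference) == sign(lfc_target), "persistent", "reversed")
}

#' Compare DEG sets between profiles
#'
#' Convenience wrapper that, for each target profile, reports the fraction
#' of its DEGs shared with the reference profile and, among the shared
#' DEGs, the reversed and persistent fractions of fold-change
#' directionality.
#'
#' @param results named list of [differential_test()] tibbles, including
#'   the reference profile.
#' @param reference name of the reference profile (default `"FP1"`).
#' @param alpha,lfc_threshold DEG thresholds.
#' @return tibble with one row per non-reference profile: `reference`,
#'   `target`, `n_target_degs`, `shared_fraction`, `n_shared`,
#'   `reversed_fraction`, `persistent_ids` (list column).
#' @export
compare_profiles <- function(results, reference = "FP1",
                             alpha = 0.05, lfc_threshold = 0.5) {
  if (!reference %in% names(results)) abort(paste0("missing reference profile: ", reference))
  ref_tab <- results[[reference]]
  ref_degs <- call_degs(ref_tab, alpha, lfc_threshold)
  if (!length(ref_degs)) {
    warn(paste0("reference profile ", reference, " has no DEGs; fractions undefined"))
  }
  targets <- setdiff(names(results), reference)
  map(targets, function(tg) {
    tab <- results[[tg]]
    degs <- call_degs(tab, alpha, lfc_threshold)
    shared <- intersect(degs, ref_degs)
    if (length(shared)) {
      dir <- reversal_classification(
        ref_tab$log2fc[match(shared, ref_tab$analyte_id)],
        tab$log2fc[match(shared, tab$analyte_id)])
      rev_frac <- mean(dir == "reversed")
      persistent <- shared[dir == "persistent"]
    } else {
      rev_frac <- NA_real_; persistent <- character(0)
    }
    tibble(reference = reference, target = tg,
           n_target_degs = length(degs),
           shared_fraction = if (length(ref_degs)) shared_fraction(ref_degs, degs)
                             else NA_real_,
           n_shared = length(shared),
           reversed_fraction = rev_frac,
           persistent_ids = list(persistent))
  }) |> bind_rows()
}

#' Unique vs shared membership across per-group DEG sets
#'
#' Over the union of all groups' DEG sets, counts the analytes found in
#' exactly one group vs in two or more, with percentages reported to one
#' decimal place.
#'
#' @param deg_sets named list (>= 2 groups) of character vectors.
#' @return tibble with `category` (`unique` / `shared`), `n`, `pct`.
#' @examples
#' profile_uniqueness_summary(list(a = c("g1", "g2"), b = c("g2", "g3")))
#' @export
profile_uniqueness_summary <- function(deg_sets) {
  if (length(deg_sets) < 2) abort("need >= 2 groups")
  membership <- table(unlist(map(deg_sets, unique)))
  n_unique <- sum(membership == 1)
  n_shared <- sum(membership >= 2)
  total <- n_unique + n_shared
  if (total == 0) abort("all DEG sets are empty")
  tibble(category = c("unique", "shared"),
         n = c(n_unique, n_shared),
         pct = round(100 * c(n_unique, n_shared) / total, 1))
}
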