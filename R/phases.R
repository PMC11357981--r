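#' Mission phase taxonomy
#'
#' A phase scheme maps timepoint labels to the four mission phases
#' (`pre_flight`, `in_flight`, `post_flight`, `recovery`) and records, per
#' assay modality, which timepoints enter the coefficient-of-variation
#' analysis. The default scheme encodes the ten timepoints of a short
#' civilian orbital mission: three pre-flight draws (L-92, L-44, L-3), three
#' flight days (FD1-FD3), immediate return (R+1) and three recovery draws
#' (R+45, R+82, R+194).
#'
#' The default CV mask covers L-92, L-44, L-3, R+1, R+45 and R+82 for every
#' modality; microbiome relative abundances additionally include the
#' in-flight FD2 and FD3 collections. R+194 maps to the recovery phase but is
#' excluded from the default CV mask.
#'
#' Labels are matched after canonicalizing the Unicode minus sign to the
#' ASCII hyphen, so `"L−44"` and `"L-44"` are the same timepoint.
#'
#' @param mapping named character vector: timepoint label -> phase.
#' @param cv_mask named list: modality -> character vector of timepoint
#'   labels included in CV analyses. The entry `".default"` applies to
#'   modalities without their own entry.
#' @return a `phase_scheme` object.
#' @examples
#' sc <- phase_scheme()
#' sc$mapping[["R+45"]]
#' @export
phase_scheme <- function(mapping = NULL, cv_mask = NULL) {
  if (is.null(mapping)) {
    mapping <- c(
      "L-92" = "pre_flight", "L-44" = "pre_flight", "L-3" = "pre_flight",
      "FD1" = "in_flight", "FD2" = "in_flight", "FD3" = "in_flight",
      "R+1" = "post_flight",
      "R+45" = "recovery", "R+82" = "recovery", "R+194" = "recovery"
    )
  }
  names(mapping) <- canonical_timepoint(names(mapping))
  bad <- setdiff(unique(mapping), phase_levels())
  if (length(bad)) abort(paste0("unknown phase(s): ", paste(bad, collapse = ", ")))
  if (is.null(cv_mask)) {
    base <- c("L-92", "L-44", "L-3", "R+1", "R+45", "R+82")
    cv_mask <- list(
      ".default" = base,
      microbiome_relabund = c(base, "FD2", "FD3")
    )
  }
  cv_mask <- map(cv_mask, canonical_timepoint)
  unk <- setdiff(unique(unlist(cv_mask)), names(mapping))
  if (length(unk)) abort(paste0("cv_mask label(s) not in mapping: ", paste(unk, collapse = ", ")))
  structure(list(mapping = mapping, cv_mask = cv_mask), class = "phase_scheme")
}

phase_levels <- function() c("pre_flight", "in_flight", "post_flight", "recovery")

#' @export
print.phase_scheme <- function(x, ...) {
  cat("<phase_scheme>\n")
  for (ph in phase_levels()) {
    labs <- names(x$mapping)[x$mapping == ph]
    if (length(labs)) cat(sprintf("  %-11s %s\n", ph, paste(labs, collapse = ", ")))
  }
  invisible(x)
}

# canonicalize Unicode minus / en-dash variants to ASCII hyphen
canonical_timepoint <- function(x) {
  gsub("[−–—]", "-", as.character(x))
}

#' Assign mission phases to samples
#'
#' @param samples tibble with at least `sample_id` and `timepoint_label`.
#' @param scheme a [phase_scheme()]; the default encodes the ten-timepoint
#'   mission schedule.
#' @return `samples` with a `phase` column added (factor over the four
#'   phases). Errors if any label is not resolvable by the scheme.
#' @examples
#' s <- tibble::tibble(sample_id = "a", subject_id = "C001", timepoint_label = "R+45")
#' assign_phases(s)$phase
#' @export
assign_phases <- function(samples, scheme = phase_scheme()) {
  labs <- canonical_timepoint(samples$timepoint_label)
  unknown <- sort(unique(labs[!labs %in% names(scheme$mapping)]))
  if (length(unknown)) {
    abort(paste0("unresolvable timepoint label(s): ", paste(unknown, collapse = ", ")))
  }
  samples$timepoint_label <- labs
  samples$phase <- factor(unname(scheme$mapping[labs]), levels = phase_levels())
  as_tibble(samples)
}

# timepoints a modality contributes to CV analyses under a scheme
cv_mask_labels <- function(scheme, modality) {
  scheme$cv_mask[[modality]] %||% scheme$cv_mask[[".default"]] %||% names(scheme$mapping)
}
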