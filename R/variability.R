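#' Coefficient of variation (population form)
#'
#' CV = population standard deviation (denominator n) divided by the mean,
#' computed on normalized abundances.
#'
#' @param values numeric vector of normalized abundances.
#' @param zero_mean what to do when the mean is 0: `"error"` (default) or
#'   `"na"` to return a missing sentinel.
#' @return the raw CV (dimensionless).
#' @examples
#' coefficient_of_variation(c(2, 4, 6))  # sqrt(8/3) / 4
#' @export
coefficient_of_variation <- function(values, zero_mean = c("error", "na")) {
  zero_mean <- match.arg(zero_mean)
  values <- as.numeric(values)
  if (length(values) == 0) abort("empty vector: CV undefined")
  if (any(!is.finite(values))) abort("values must be finite")
  mu <- mean(values)
  if (mu == 0) {
    if (zero_mean == "error") abort("zero mean: CV undefined")
    return(NA_real_)
  }
  sqrt(mean((values - mu)^2)) / mu
}

# row-wise mean and population CV of a column subset; flags non-positive means
pooled_mean_cv <- function(x, cols) {
  xs <- x[, cols, drop = FALSE]
  mu <- rowMeans(xs)
  v <- rowMeans(xs * xs) - mu * mu
  v[v < 0] <- 0
  cv <- ifelse(mu == 0, NA_real_, sqrt(v) / mu)
  list(mean = mu, cv = cv, n = rep(ncol(xs), nrow(xs)))
}

# average within-subject first, then mean/CV across subject means
subject_mean_cv <- function(x, cols, subj) {
  groups <- split(cols, subj[cols])
  groups <- groups[lengths(groups) > 0]
  xm <- vapply(groups, function(ix) rowMeans(x[, ix, drop = FALSE]),
               numeric(nrow(x)))
  if (is.null(dim(xm))) xm <- matrix(xm, nrow = nrow(x))
  pooled_mean_cv(xm, seq_len(ncol(xm)))
}

phase_mean_cv <- function(x, cols, averaging, subj) {
  if (averaging == "per_subject_mean") subject_mean_cv(x, cols, subj)
  else pooled_mean_cv(x, cols)
}

#' Per-phase mean and raw CV for every analyte
#'
#' Splits the samples into mission-phase intervals (after applying the
#' scheme's per-modality CV mask) and computes, per analyte and phase, the
#' mean abundance and the raw CV. Two averaging conventions are offered:
#' `"pooled"` (CV over all subject-by-timepoint values in the phase; the
#' default) and `"per_subject_mean"` (average each subject's values within
#' the phase first, then CV across subject means — the microbiome
#' convention).
#'
#' @param table a normalized [feature_table()].
#' @param samples sample metadata tibble (`sample_id`, `subject_id`,
#'   `timepoint_label`).
#' @param scheme a [phase_scheme()].
#' @param averaging `"pooled"` or `"per_subject_mean"`.
#' @param apply_mask apply the scheme's per-modality CV timepoint mask
#'   (default `TRUE`).
#' @return tibble with `analyte_id`, `phase`, `n_values`, `mean_abundance`,
#'   `raw_cv`, `flagged` (records with < 2 values or non-positive mean are
#'   flagged and excluded from reference building downstream).
#' @export
interval_cv <- function(table, samples, scheme = phase_scheme(),
                        averaging = c("pooled", "per_subject_mean"),
                        apply_mask = TRUE) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(table, "feature_table"))
  if (!ft_normalized(table)) {
    warn("feature table is not flagged as normalized; CV assumes normalized values")
  }
  samples <- assign_phases(samples, scheme)
  miss <- setdiff(colnames(table), samples$sample_id)
  if (length(miss)) abort(paste0("samples without metadata: ", paste(miss, collapse = ", ")))
  if (apply_mask) {
    keep_labels <- cv_mask_labels(scheme, ft_modality(table))
    samples <- filter(samples, .data$timepoint_label %in% keep_labels)
  }
  samples <- filter(samples, .data$sample_id %in% colnames(table))
  x <- unclass(table)
  col_of <- setNames(seq_len(ncol(x)), colnames(x))
  subj <- character(ncol(x))
  subj[col_of[samples$sample_id]] <- samples$subject_id

  phases <- split(samples$sample_id, as.character(samples$phase), drop = TRUE)
  out <- imap(phases, function(ids, ph) {
    st <- phase_mean_cv(x, unname(col_of[ids]), averaging, subj)
    n_eff <- if (averaging == "per_subject_mean") {
      length(unique(samples$subject_id[samples$sample_id %in% ids]))
    } else length(ids)
    tibble(analyte_id = rownames(x), phase = ph,
           n_values = n_eff, mean_abundance = unname(st$mean),
           raw_cv = unname(st$cv),
           flagged = n_eff < 2 | !is.finite(unname(st$cv)) | unname(st$mean) <= 0)
  })
  arrange(bind_rows(out), .data$phase, .data$analyte_id)
}

# Equal-frequency rank binning of (mean, cv) records; returns per-record bin,
# per-bin stats, and per-record z. Shared by the reference builder and the
# permutation chain so both run the identical procedure.
bin_stats_by_rank <- function(means, cvs, n_bins, min_per_bin) {
  n <- length(means)
  k <- max(1L, min(as.integer(n_bins), n %/% as.integer(min_per_bin)))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ord <- order(means)
  bin_sorted <- rep.int(seq_len(k), sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  cvs_sorted <- cvs[ord]
  s1 <- unname(rowsum(cvs_sorted, bin_sorted, reorder = TRUE)[, 1])
  s2 <- unname(rowsum(cvs_sorted^2, bin_sorted, reorder = TRUE)[, 1])
  cv_mean <- s1 / sizes
  cv_sd <- sqrt(pmax(s2 / sizes - cv_mean^2, 0))
  z <- (cvs - cv_mean[bin]) / cv_sd[bin]
  degenerate <- cv_sd[bin] == 0
  z[degenerate] <- ifelse(cvs[degenerate] == cv_mean[bin][degenerate], 0, NA_real_)
  list(bin = bin, z = unname(z), k = k, sizes = sizes,
       cv_mean = cv_mean, cv_sd = cv_sd,
       lower = unname(vapply(split(means[ord], bin_sorted), min, double(1))),
       upper = unname(vapply(split(means[ord], bin_sorted), max, double(1))))
}

#' Build the mean-abundance quantile reference for CV standardization
#'
#' Pools CV records across all phases, splits them into approximately
#' `n_bins` equal-frequency bins on mean abundance (reducing the bin count
#' whenever a bin would hold fewer than `min_per_bin` records), and records
#' each bin's CV mean and CV standard deviation. The reference is
#' phase-agnostic: one mean/CV distribution per dataset.
#'
#' @param cv_records tibble from [interval_cv()] (flagged records are
#'   dropped).
#' @param n_bins requested number of quantile bins (default 100).
#' @param min_per_bin minimum records per bin (default 10); with `n`
#'   records the effective bin count is `min(n_bins, floor(n / min_per_bin))`,
#'   floored at 1.
#' @return a `quantile_reference`: tibble with one row per bin (`bin`,
#'   `lower`, `upper`, `n`, `cv_mean`, `cv_sd`, `degenerate`) carrying the
#'   internal bin boundaries used for later record assignment.
#' @export
build_quantile_reference <- function(cv_records, n_bins = 100, min_per_bin = 10) {
  rec <- filter(cv_records, !.data$flagged, is.finite(.data$raw_cv),
                is.finite(.data$mean_abundance))
  if (nrow(rec) == 0) abort("no usable CV records")
  if (nrow(rec) < min_per_bin) {
    warn("fewer records than `min_per_bin`: single degenerate-prone bin")
  }
  bs <- bin_stats_by_rank(rec$mean_abundance, rec$raw_cv, n_bins, min_per_bin)
  ref <- tibble(bin = seq_len(bs$k), lower = bs$lower, upper = bs$upper,
                n = bs$sizes, cv_mean = bs$cv_mean, cv_sd = bs$cv_sd,
                degenerate = bs$cv_sd == 0)
  # half-open assignment boundaries between adjacent bins (midpoints)
  breaks <- if (bs$k > 1) (bs$upper[-bs$k] + bs$lower[-1]) / 2 else numeric(0)
  structure(ref, class = c("quantile_reference", class(ref)), breaks = breaks,
            n_records = nrow(rec))
}

#' @export
glance.quantile_reference <- function(x, ...) {
  tibble(n_bins = nrow(x), n_records = attr(x, "n_records"),
         n_degenerate = sum(x$degenerate),
         mean_bin_size = mean(x$n))
}

#' Abundance-standardized CV (z-score against the quantile reference)
#'
#' Each record's mean abundance is matched to a reference bin (half-open
#' intervals, last bin closed; means outside the reference range clamp to
#' the end bins) and its CV is converted to
#' `z = (CV - CVmean_q) / CVsd_q`. In a zero-spread bin the z-score is 0
#' when the CV equals the bin mean and a missing sentinel otherwise (never
#' infinite).
#'
#' @param cv_records tibble from [interval_cv()].
#' @param reference a [build_quantile_reference()] object.
#' @return `cv_records` with `bin` and `cv_z` columns added.
#' @export
standardize_cv <- function(cv_records, reference) {
  stopifnot(inherits(reference, "quantile_reference"))
  breaks <- attr(reference, "breaks")
  bin <- findInterval(cv_records$mean_abundance, breaks) + 1L
  m <- reference$cv_mean[bin]
  s <- reference$cv_sd[bin]
  z <- (cv_records$raw_cv - m) / s
  deg <- !is.na(s) & s == 0
  if (any(deg, na.rm = TRUE)) {
    z[deg] <- ifelse(cv_records$raw_cv[deg] == m[deg], 0, NA_real_)
    if (anyNA(z[deg])) warn("zero-spread bin(s): z set to missing for off-mean CVs")
  }
  z[cv_records$flagged] <- NA_real_
  mutate(cv_records, bin = bin, cv_z = z)
}

#' One-call CV profile: interval CVs standardized against the pooled reference
#'
#' @inheritParams interval_cv
#' @param n_bins,min_per_bin passed to [build_quantile_reference()].
#' @return tibble of standardized CV records (see [standardize_cv()]).
#' @export
cv_profile <- function(table, samples, scheme = phase_scheme(),
                       averaging = c("pooled", "per_subject_mean"),
                       n_bins = 100, min_per_bin = 10) {
  averaging <- match.arg(averaging)
  rec <- interval_cv(table, samples, scheme, averaging)
  ref <- build_quantile_reference(rec, n_bins, min_per_bin)
  standardize_cv(rec, ref)
}
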