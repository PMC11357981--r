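#' Shuffled-label permutation test of between-phase variability shifts
#'
#' For each analyte the observed statistic is the difference in
#' abundance-standardized CV between two phases,
#' `delta_z = z(phase_b) - z(phase_a)` (post-flight minus pre-flight by
#' default). The null is built by shuffling the phase labels among the
#' pooled phase-a / phase-b samples and repeating the full procedure —
#' interval CVs, quantile-reference construction, standardization — on every
#' shuffle. Samples belonging to other masked phases keep their labels and
#' keep contributing to the reference, which is rebuilt inside each
#' permutation.
#'
#' The per-analyte outputs are the observed `delta_z`, the null mean and
#' standard deviation, a permutation z-score
#' `(observed - null mean) / null sd`, the rank of the observed value among
#' the null draws (count of null values >= observed), and the one-sided
#' add-one empirical p-value `(1 + rank) / (1 + n_perm)`.
#'
#' @inheritParams interval_cv
#' @param phase_a,phase_b the two phases being contrasted (defaults
#'   `pre_flight` and `post_flight`).
#' @param n_perm number of label shuffles (default 10000).
#' @param seed integer RNG seed; identical seeds give identical results.
#' @param stratify_by_subject shuffle labels within each subject's samples
#'   instead of globally (default `FALSE`).
#' @param exhaustive enumerate every distinct assignment of the phase-b
#'   label set among the pooled samples instead of sampling; the empirical
#'   p-value is then the exact tail fraction over all assignments (the
#'   observed assignment included). Only available without stratification.
#' @param n_bins,min_per_bin quantile-reference parameters.
#' @return a tibble (class `perm_delta_result`) with one row per analyte:
#'   `analyte_id`, `delta_z`, `null_n`, `null_mean`, `null_sd`, `perm_z`,
#'   `rank`, `p_value`.
#' @export
permutation_delta_test <- function(table, samples, scheme = phase_scheme(),
                                   phase_a = "pre_flight", phase_b = "post_flight",
                                   n_perm = 10000, seed = 1L,
                                   stratify_by_subject = FALSE,
                                   exhaustive = FALSE,
                                   averaging = c("pooled", "per_subject_mean"),
                                   n_bins = 100, min_per_bin = 10) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(table, "feature_table"))
  if (!exhaustive && n_perm < 1) abort("`n_perm` must be >= 1")
  if (exhaustive && stratify_by_subject) {
    abort("exhaustive enumeration is only implemented for global shuffling")
  }
  samples <- assign_phases(samples, scheme)
  keep_labels <- cv_mask_labels(scheme, ft_modality(table))
  samples <- filter(samples, .data$timepoint_label %in% keep_labels,
                    .data$sample_id %in% colnames(table))
  x <- unclass(table)
  col_of <- setNames(seq_len(ncol(x)), colnames(x))
  subj <- character(ncol(x)); subj[col_of[samples$sample_id]] <- samples$subject_id

  ph <- as.character(samples$phase)
  cols_a <- unname(col_of[samples$sample_id[ph == phase_a]])
  cols_b <- unname(col_of[samples$sample_id[ph == phase_b]])
  if (length(cols_a) < 1 || length(cols_b) < 1) {
    abort(sprintf("both phases need >= 1 sample (%s: %d, %s: %d)",
                  phase_a, length(cols_a), phase_b, length(cols_b)))
  }
  other_phases <- setdiff(unique(ph), c(phase_a, phase_b))
  fixed_stats <- map(other_phases, function(p)
    phase_mean_cv(x, unname(col_of[samples$sample_id[ph == p]]), averaging, subj))

  fixed_means <- unlist(map(fixed_stats, "mean"), use.names = FALSE)
  fixed_cvs <- unlist(map(fixed_stats, "cv"), use.names = FALSE)

  n_analytes <- nrow(x)
  delta_for <- function(ca, cb) {
    sa <- phase_mean_cv(x, ca, averaging, subj)
    sb <- phase_mean_cv(x, cb, averaging, subj)
    means <- c(sa$mean, sb$mean, fixed_means)
    cvs <- c(sa$cv, sb$cv, fixed_cvs)
    ok <- is.finite(means) & is.finite(cvs) & means > 0
    z <- rep(NA_real_, length(means))
    if (any(ok)) {
      bs <- bin_stats_by_rank(means[ok], cvs[ok], n_bins, min_per_bin)
      z[ok] <- bs$z
    }
    z[n_analytes + seq_len(n_analytes)] - z[seq_len(n_analytes)]
  }

  obs <- delta_for(cols_a, cols_b)

  pool <- c(cols_a, cols_b)
  na <- length(cols_a)
  if (exhaustive) {
    picks <- utils::combn(pool, length(cols_b), simplify = FALSE)
    null_mat <- vapply(picks, function(cb) delta_for(setdiff(pool, cb), cb),
                       numeric(n_analytes))
    n_draws <- length(picks)
  } else {
    by_subj <- split(seq_along(pool), subj[pool])
    null_mat <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        idx <- if (stratify_by_subject) {
          perm <- integer(length(pool))
          for (g in by_subj) perm[g] <- if (length(g) > 1) sample(g) else g
          pool[perm]
        } else sample(pool)
        delta_for(idx[seq_len(na)], idx[-seq_len(na)])
      }, numeric(n_analytes))
    })
    n_draws <- n_perm
  }
  if (is.null(dim(null_mat))) null_mat <- matrix(null_mat, nrow = n_analytes)

  null_n <- rowSums(is.finite(null_mat))
  null_mean <- rowMeans(null_mat, na.rm = TRUE)
  null_sd <- sqrt(pmax(rowMeans(null_mat^2, na.rm = TRUE) - null_mean^2, 0) *
                    ifelse(null_n > 1, null_n / (null_n - 1), NA_real_))
  rank_ge <- rowSums(sweep(null_mat, 1, obs, `>=`), na.rm = TRUE)
  p <- if (exhaustive) rank_ge / null_n else (1 + rank_ge) / (1 + null_n)
  perm_z <- ifelse(is.finite(null_sd) & null_sd > 0,
                   (obs - null_mean) / null_sd, NA_real_)
  bad <- !is.finite(obs)
  p[bad] <- NA_real_; rank_ge[bad] <- NA_integer_; perm_z[bad] <- NA_real_

  out <- tibble(analyte_id = rownames(x), delta_z = obs,
                null_n = null_n, null_mean = null_mean, null_sd = null_sd,
                perm_z = perm_z, rank = rank_ge, p_value = p)
  structure(out, class = c("perm_delta_result", class(out)),
            n_perm = n_draws, seed = seed, phase_a = phase_a, phase_b = phase_b,
            exhaustive = exhaustive, stratified = stratify_by_subject)
}

#' @export
glance.perm_delta_result <- function(x, ...) {
  tibble(n_analytes = nrow(x), n_perm = attr(x, "n_perm"),
         phase_a = attr(x, "phase_a"), phase_b = attr(x, "phase_b"),
         exhaustive = attr(x, "exhaustive"), stratified = attr(x, "stratified"),
         n_significant_05 = sum(x$p_value <= 0.05, na.rm = TRUE))
}

#' Order analytes for preranked enrichment
#'
#' Sorts analytes by a chosen score (descending; most increased variability
#' first), breaking ties lexicographically by analyte id. Analytes with a
#' missing score are dropped with a message.
#'
#' @param results a [permutation_delta_test()] result (or any tibble with
#'   `analyte_id` and the score column).
#' @param key score column name (default `"perm_z"`).
#' @return tibble with `analyte_id` and `score`, in rank order.
#' @export
rank_for_enrichment <- function(results, key = "perm_z") {
  if (nrow(results) == 0) abort("empty results")
  if (!key %in% names(results)) abort(paste0("no such score column: ", key))
  score <- results[[key]]
  dropped <- sum(!is.finite(score))
  if (dropped > 0) inform(sprintf("dropping %d analyte(s) with missing scores", dropped))
  out <- tibble(analyte_id = results$analyte_id, score = score) |>
    filter(is.finite(.data$score)) |>
    arrange(desc(.data$score), .data$analyte_id)
  out
}
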