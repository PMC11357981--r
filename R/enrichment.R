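#' Preranked enrichment score (weighted running-sum statistic)
#'
#' Walks the ranked list from top to bottom, incrementing the running sum by
#' `|score|^weight / sum(|score|^weight over hits)` at members of the set
#' and decrementing by `1 / (N - n_hits)` at non-members; the enrichment
#' score is the signed extremum of the running sum. With `weight = 0` this
#' is the classical two-sample Kolmogorov-Smirnov statistic on the hit/miss
#' rank distributions.
#'
#' @param ranked tibble with `analyte_id` and `score`, already in rank
#'   order (see [rank_for_enrichment()]); ids must be unique.
#' @param set character vector of member ids (must intersect the list).
#' @param weight score weighting exponent (default 1).
#' @return list with `es`, the `running_sum` profile, the hit positions and
#'   the `leading_edge` member ids.
#' @export
preranked_es <- function(ranked, set, weight = 1) {
  ids <- ranked$analyte_id
  check_unique_ids(ids, "ranked analyte")
  hit <- ids %in% set
  n <- length(ids)
  nh <- sum(hit)
  if (nh == 0) abort("gene set has no members in the ranked list")
  w <- abs(ranked$score)^weight
  if (weight > 0 && sum(w[hit]) == 0) abort("all member scores are zero; cannot weight")
  inc <- numeric(n)
  if (nh == n) {
    inc[hit] <- w[hit] / sum(w[hit])
  } else {
    inc[hit] <- w[hit] / sum(w[hit])
    inc[!hit] <- -1 / (n - nh)
  }
  rs <- cumsum(inc)
  i_max <- which.max(abs(rs))
  es <- rs[i_max]
  leading <- if (es >= 0) ids[seq_len(i_max)][hit[seq_len(i_max)]]
             else ids[i_max:n][hit[i_max:n]]
  list(es = es, running_sum = rs, hits = which(hit), leading_edge = leading)
}

#' Permutation null and normalized enrichment score for the preranked statistic
#'
#' The null draws `k` analyte ids uniformly without replacement from the
#' ranked list, `n_perm` times, recomputing the enrichment score each time
#' (gene-label permutation). `nes_and_p()` normalizes an observed score by
#' the mean |null score| of matching sign and reports the add-one tail
#' fraction among matching-sign null draws.
#'
#' @inheritParams preranked_es
#' @param k set size to draw.
#' @param n_perm number of null draws.
#' @param seed integer RNG seed.
#' @return `preranked_null()`: numeric vector of null enrichment scores.
#' @export
preranked_null <- function(ranked, k, n_perm, seed = 1L, weight = 1) {
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  ids <- ranked$analyte_id
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      preranked_es(ranked, sample(ids, k), weight)$es
    }, double(1))
  })
}

#' @rdname preranked_null
#' @param es observed enrichment score.
#' @param null vector of null enrichment scores.
#' @return `nes_and_p()`: tibble with `nes`, `p_value`, `n_matching_sign`.
#' @export
nes_and_p <- function(es, null) {
  same <- null * sign(es) >= 0 & null != 0
  if (es == 0) same <- rep(TRUE, length(null))
  n_match <- sum(same)
  if (n_match == 0) {
    return(tibble(nes = NA_real_, p_value = 1 / (length(null) + 1),
                  n_matching_sign = 0L))
  }
  nes <- es / mean(abs(null[same]))
  p <- (1 + sum(abs(null[same]) >= abs(es))) / (n_match + 1)
  tibble(nes = nes, p_value = p, n_matching_sign = n_match)
}

#' Preranked gene-set enrichment over a collection
#'
#' Runs the weighted running-sum statistic for every set in the collection,
#' builds a shared-size-matched permutation null per set, and reports ES,
#' NES, nominal p and Benjamini-Hochberg q.
#'
#' @inheritParams preranked_es
#' @param collection a [read_gmt()] collection (named list of id vectors).
#' @param n_perm null draws per set (default 2000).
#' @param seed integer RNG seed.
#' @param min_size sets with fewer overlapping members are skipped.
#' @return tibble (class `gsea_result`): `set`, `size`, `es`, `nes`,
#'   `p_value`, `q_value`, `direction`, `leading_edge` (list column).
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 2000, seed = 1L,
                           weight = 1, min_size = 2) {
  ids <- ranked$analyte_id
  sizes <- map_int(collection, ~ length(intersect(.x, ids)))
  keep <- sizes >= min_size
  if (!any(keep)) abort("no gene set overlaps the ranked list")
  nulls <- new.env()
  rows <- imap(collection[keep], function(members, nm) {
    fit <- preranked_es(ranked, members, weight)
    k <- sizes[[nm]]
    key <- as.character(k)
    if (is.null(nulls[[key]])) {
      nulls[[key]] <- preranked_null(ranked, k, n_perm,
                                     seed = child_seed_int(seed, k), weight = weight)
    }
    np <- nes_and_p(fit$es, nulls[[key]])
    tibble(set = nm, size = k, es = fit$es, nes = np$nes, p_value = np$p_value,
           direction = ifelse(fit$es >= 0, "up", "down"),
           leading_edge = list(fit$leading_edge))
  }) |> bind_rows()
  rows$q_value <- bh_adjust(rows$p_value)
  rows <- relocate(rows, "q_value", .after = "p_value")
  structure(arrange(rows, .data$p_value, .data$set),
            class = c("gsea_result", class(rows)),
            n_perm = n_perm, seed = seed, weight = weight)
}

child_seed_int <- function(seed, k) as.integer((as.double(seed) + 104729 * k) %% 2147483647)

#' @export
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_perm = attr(x, "n_perm"), weight = attr(x, "weight"),
         n_q_05 = sum(x$q_value < 0.05, na.rm = TRUE))
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests each gene set for overrepresentation in a hit list within a
#' universe: `p = P(X >= overlap)` for `X` hypergeometric, with enrichment
#' ratio observed / expected overlap. Sets are intersected with the
#' universe before testing; FDR is Benjamini-Hochberg across sets.
#'
#' @param hits character vector of hit ids (subset of `universe`).
#' @param collection named list of gene sets (or a single character vector).
#' @param universe character vector of all testable ids.
#' @return tibble (class `ora_result`): `set`, `universe_size`, `set_size`,
#'   `n_hits`, `overlap`, `enrichment_ratio`, `p_value`, `fdr`.
#' @export
ora_hypergeometric <- function(hits, collection, universe) {
  if (!length(universe)) abort("empty universe")
  if (!length(hits)) abort("empty hit list")
  hits <- unique(hits)
  universe <- unique(universe)
  out_u <- setdiff(hits, universe)
  if (length(out_u)) abort(paste0("hit(s) outside the universe: ",
                                  paste(head(out_u, 5), collapse = ", ")))
  if (!is.list(collection)) collection <- list(set = collection)
  rows <- imap(collection, function(members, nm) {
    k <- intersect(unique(members), universe)
    ov <- length(intersect(k, hits))
    p <- phyper(ov - 1, length(k), length(universe) - length(k),
                length(hits), lower.tail = FALSE)
    expected <- length(hits) * length(k) / length(universe)
    tibble(set = nm, universe_size = length(universe), set_size = length(k),
           n_hits = length(hits), overlap = ov,
           enrichment_ratio = ifelse(expected > 0, ov / expected, NA_real_),
           p_value = p)
  }) |> bind_rows()
  rows$fdr <- bh_adjust(rows$p_value)
  structure(rows, class = c("ora_result", class(rows)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with enforced monotonicity,
#' returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Reported-pathway filter
#'
#' Keeps the union of the `top_n` records with the lowest FDR and every
#' record with FDR below `fdr` — the conventional reporting rule for
#' overrepresentation tables.
#'
#' @param records tibble with an `fdr` column (and `set` for deterministic
#'   tie-breaking).
#' @param fdr FDR inclusion threshold (default 0.05).
#' @param top_n size of the always-reported head (default 40).
#' @return the filtered records, ordered by FDR.
#' @export
filter_pathways <- function(records, fdr = 0.05, top_n = 40) {
  if (!"fdr" %in% names(records)) abort("records need an `fdr` column")
  ord <- arrange(records, .data$fdr, .data$set)
  top <- head(ord, top_n)
  under <- filter(ord, .data$fdr < !!fdr)
  distinct(bind_rows(top, under))
}
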