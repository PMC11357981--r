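# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths: plain loops, enumeration and closed forms only.

oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x)) / m
}

# group-by mean/CV over a long data frame (analyte, value)
oracle_group_cv <- function(values, groups) {
  out <- list()
  for (g in unique(groups)) {
    v <- values[groups == g]
    out[[g]] <- c(mean = mean(v), cv = oracle_cv(v))
  }
  out
}

# equal-frequency binning + per-bin stats, the slow way
oracle_bin_stats <- function(means, cvs, n_bins, min_per_bin) {
  n <- length(means)
  k <- max(1, min(n_bins, n %/% min_per_bin))
  ord <- order(means)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  res <- data.frame(bin = seq_len(k), cv_mean = NA_real_, cv_sd = NA_real_, n = sizes)
  z <- numeric(n)
  for (i in seq_len(k)) {
    idx <- ord[starts[i]:stops[i]]
    cm <- mean(cvs[idx])
    cs <- sqrt(mean((cvs[idx] - cm)^2))
    res$cv_mean[i] <- cm
    res$cv_sd[i] <- cs
    z[idx] <- if (cs > 0) (cvs[idx] - cm) / cs else ifelse(cvs[idx] == cm, 0, NA_real_)
  }
  list(table = res, z = z)
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  p_low <- mean(stats <= r_obs)
  p_high <- mean(stats >= r_obs)
  min(1, 2 * min(p_low, p_high))
}

# one-sided (greater) exact rank-sum p by enumeration
oracle_ranksum_greater <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  mean(stats >= r_obs)
}

# running-sum enrichment score, step by step
oracle_es <- function(ids, scores, set, w) {
  hit <- ids %in% set
  nh <- sum(hit)
  n <- length(ids)
  denom_hit <- sum(abs(scores[hit])^w)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) abs(scores[i])^w / denom_hit else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# hypergeometric upper tail by direct summation of the pmf
oracle_hyper_tail <- function(overlap, set_size, universe, hits) {
  x <- overlap:min(set_size, hits)
  sum(choose(set_size, x) * choose(universe - set_size, hits - x)) /
    choose(universe, hits)
}

# BH step-up, spelled out
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  q
}

# per-base window sums: expand fragments onto positions, then sum
oracle_window_sums <- function(frags, windows) {
  sums <- setNames(numeric(nrow(windows)), windows$gene_id)
  for (i in seq_len(nrow(windows))) {
    pos <- windows$start[i]:(windows$end[i] - 1)
    for (j in seq_len(nrow(frags))) {
      if (frags$chrom[j] != windows$chrom[i]) next
      fp <- frags$start[j]:(frags$end[j] - 1)
      if (length(intersect(pos, fp)) > 0) sums[i] <- sums[i] + frags$count[j]
    }
  }
  sums
}

# median-of-ratios size factors, spelled out per sample (log-scale midpoint
# for even reference counts, then geometric mean 1)
oracle_size_factors <- function(m) {
  ref <- apply(m, 1, function(r) all(r > 0))
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  raw <- apply(m[ref, , drop = FALSE], 2,
               function(col) exp(median(log(col / geo))))
  unname(raw / exp(mean(log(raw))))
}

# small labelled cohort for quick tests
tiny_cohort <- function(n_analytes = 60, seed = 42, spikes = NULL, ...) {
  generate_cohort(cohort_config(modalities = c(rna_counts = n_analytes),
                                spikes = spikes, seed = seed, ...))
}

random_feature_table <- function(n = 8, m = 5, seed = 1, modality = "rna_counts") {
  withr::with_seed(seed, {
    x <- matrix(stats::rgamma(n * m, 2, 0.1), n, m,
                dimnames = list(sprintf("a%02d", 1:n), sprintf("s%02d", 1:m)))
    feature_table(x, modality)
  })
}
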