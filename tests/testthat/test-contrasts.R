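two_group_samples <- function(n_base = 3, n_comp = 3) {
  tibble::tibble(
    sample_id = c(paste0("b", seq_len(n_base)), paste0("c", seq_len(n_comp))),
    subject_id = paste0("C", c(seq_len(n_base), seq_len(n_comp))),
    timepoint_label = c(rep("L-3", n_base), rep("R+1", n_comp)))
}

two_group_table <- function(base, comp, ids = NULL) {
  nb <- ncol(base); nc <- ncol(comp)
  m <- cbind(base, comp)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, c(paste0("b", seq_len(nb)), paste0("c", seq_len(nc))))
  feature_table(m, "rna_counts", normalized = TRUE)
}

fp1 <- contrast_spec("FP1", "L-3", "R+1")

test_that("pseudobulk aggregation sums element-wise across groups", {
  a <- feature_table(matrix(c(1, 2), 1, dimnames = list("g", c("s1", "s2"))),
                     "rna_counts")
  b <- feature_table(matrix(c(3, 4), 1, dimnames = list("g", c("s1", "s2"))),
                     "rna_counts")
  expect_equal(unclass(pseudobulk_aggregate(list(a, b)))[1, ], c(s1 = 4, s2 = 6))
  expect_equal(unclass(pseudobulk_aggregate(list(a))), unclass(a))

  tabs <- lapply(1:4, function(s) random_feature_table(6, 3, seed = s))
  total <- unclass(pseudobulk_aggregate(tabs))
  manual <- unclass(tabs[[1]]) + unclass(tabs[[2]]) + unclass(tabs[[3]]) +
    unclass(tabs[[4]])
  expect_equal(total, manual, tolerance = 0)

  c2 <- feature_table(matrix(1, 1, 2, dimnames = list("other", c("s1", "s2"))),
                      "rna_counts")
  expect_error(pseudobulk_aggregate(list(a, c2)), "same analytes")
})

test_that("differential_test handles null and shifted groups as defined", {
  base <- matrix(rep(c(1, 2, 3), each = 1), 1)
  ft <- two_group_table(base, base)
  res <- differential_test(ft, two_group_samples(), fp1)
  expect_equal(res$log2fc, 0)
  expect_equal(res$p_value, 1)

  ft2 <- two_group_table(matrix(c(1, 1, 1), 1), matrix(c(2, 2, 2), 1))
  res2 <- differential_test(ft2, two_group_samples(), fp1, pseudocount = 0)
  expect_equal(res2$log2fc, 1)

  # a contrast whose baseline label matches no sample has an empty side
  expect_error(differential_test(ft, two_group_samples(),
                                 contrast_spec("X", "L-92", "R+1")),
               "empty side")
})

test_that("rank-sum p equals exact enumeration on small untied samples", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      nb <- sample(3:6, 1); nc <- sample(3:6, 1)
      base <- matrix(rlnorm(8 * nb), 8)
      comp <- matrix(rlnorm(8 * nc) * rep(c(1, 4), each = 4), 8)
    })
    ft <- two_group_table(base, comp)
    res <- differential_test(ft, two_group_samples(nb, nc), fp1)
    for (i in seq_len(8)) {
      expect_equal(res$p_value[i], oracle_ranksum_exact(comp[i, ], base[i, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("adjusted p is BH within the call and adj_p >= p", {
  withr::with_seed(3, {
    ft <- two_group_table(matrix(rlnorm(40 * 4), 40), matrix(rlnorm(40 * 4), 40))
  })
  res <- differential_test(ft, two_group_samples(4, 4), fp1)
  expect_equal(res$adj_p, oracle_bh(res$p_value), tolerance = 1e-12)
  expect_true(all(res$adj_p >= res$p_value - 1e-12))
})

test_that("DEG calling uses strict thresholds and is monotone", {
  rec <- tibble::tibble(analyte_id = c("a", "b", "c", "d"),
                        log2fc = c(0.6, 0.5, 2.0, -0.8),
                        adj_p = c(0.01, 0.01, 0.05, 0.001))
  expect_equal(call_degs(rec), c("a", "d"))          # b fails |lfc| > 0.5, c fails p < 0.05
  expect_true("a" %in% call_degs(rec, 0.05, 0.5))
  # tightening either threshold never adds DEGs
  loose <- call_degs(rec, 0.05, 0.5)
  expect_true(all(call_degs(rec, 0.01, 0.5) %in% loose))
  expect_true(all(call_degs(rec, 0.05, 0.7) %in% loose))
})

test_that("shared fraction is target-normalized and guards the empty target", {
  expect_equal(shared_fraction(c("a", "b"), c("a", "b")), 1)
  expect_equal(shared_fraction(c("a", "b", "c", "d"), c("a", "b", "e")), 2 / 3)
  expect_equal(shared_fraction(c("a", "b"), c("x", "y")), 0)
  expect_true(is.na(shared_fraction(c("a"), character(0))))
  expect_error(shared_fraction(character(0), "a"), "empty")
})

test_that("directionality classification separates reversal from persistence", {
  # the canonical persistent pair: positive log2FC in both flight and recovery
  expect_equal(reversal_classification(0.742, 0.808), "persistent")
  expect_equal(reversal_classification(1.2, -0.6), "reversed")
  expect_equal(reversal_classification(-0.9, -0.7), "persistent")
  expect_error(reversal_classification(0, 1), "non-zero")
})

test_that("uniqueness summary reproduces membership percentages", {
  sets <- list(
    cd4 = sprintf("u%03d", 1:100), cd8 = sprintf("u%03d", 101:160),
    cd14 = c(sprintf("u%03d", 161:211), sprintf("s%02d", 1:87)),
    cd16 = sprintf("s%02d", 1:87))
  out <- profile_uniqueness_summary(sets)
  expect_equal(out$n, c(211L, 87L))
  expect_equal(out$pct, c(70.8, 29.2))

  disjoint <- profile_uniqueness_summary(list(a = "x", b = "y"))
  expect_equal(disjoint$pct, c(100, 0))

  withr::with_seed(5, {
    rand <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  })
  names(rand) <- paste0("g", 1:4)
  out2 <- profile_uniqueness_summary(rand)
  counts <- table(unlist(lapply(rand, unique)))
  expect_equal(out2$n, c(sum(counts == 1), sum(counts >= 2)))
})

test_that("profiles with decaying overshoot effects reverse direction at recovery", {
  ids <- sprintf("gene_%04d", 1:120)
  spikes <- tibble::tibble(analyte_id = ids, modality = "rna_counts",
                           phase = "post_flight",
                           mean_effect = rep(c(8, 1 / 8), 60),
                           disp_effect = 1, halflife_days = 10, rebound = 1)
  co <- generate_cohort(cohort_config(modalities = c(rna_counts = 1200),
                                      spikes = spikes, seed = 8))
  diffs <- lapply(contrast_registry()[c("FP1", "RP1", "LP2")], function(ct)
    differential_test(co$tables$rna_counts, co$samples, ct))
  n_fp1 <- length(call_degs(diffs$FP1))
  n_lp2 <- length(call_degs(diffs$LP2))
  expect_gt(n_fp1, 0)
  expect_gt(n_fp1, n_lp2)
  cp <- compare_profiles(diffs)
  rev_rp1 <- cp$reversed_fraction[cp$target == "RP1"]
  expect_gt(rev_rp1, 0.9)
})

test_that("differential p-values are calibrated on null data", {
  co <- generate_cohort(cohort_config(modalities = c(rna_counts = 2000), seed = 29))
  res <- differential_test(co$tables$rna_counts, co$samples,
                           contrast_registry()$FP1)
  # the exact rank-sum p is discrete (12 vs 4 values), so calibration is
  # checked at the attainable support: P(p <= alpha) must track alpha from
  # below, never exceed it beyond binomial noise, and not be grossly
  # conservative
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    rate <- mean(res$p_value <= alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(res))
    expect_lte(rate, alpha + 3 * se)
    expect_gte(rate, alpha / 2)
  }
})
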