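test_that("coefficient_of_variation is population sd over mean", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  # sd = sqrt(8/3), mean = 4
  expect_equal(coefficient_of_variation(c(2, 4, 6)), sqrt(8 / 3) / 4,
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.408248, tolerance = 1e-6)
  expect_error(coefficient_of_variation(c(0, 0, 0)), "zero mean")
  expect_error(coefficient_of_variation(numeric(0)), "empty")
  expect_true(is.na(coefficient_of_variation(c(-1, 1), zero_mean = "na")))
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rlnorm(9))
    expect_equal(coefficient_of_variation(x), oracle_cv(x), tolerance = 1e-12)
  }
})

test_that("interval_cv pools the expected number of values per phase", {
  co <- tiny_cohort(n_analytes = 20, seed = 4)
  rec <- interval_cv(co$tables$rna_counts, co$samples)
  # default mask: 3 pre timepoints x 4 subjects, 1 post x 4, 2 recovery x 4
  expect_equal(unique(rec$n_values[rec$phase == "pre_flight"]), 12)
  expect_equal(unique(rec$n_values[rec$phase == "post_flight"]), 4)
  expect_equal(unique(rec$n_values[rec$phase == "recovery"]), 8)
  expect_false("in_flight" %in% rec$phase)
})

test_that("pooled interval_cv matches a brute-force group-by", {
  co <- tiny_cohort(n_analytes = 25, seed = 6)
  tab <- unclass(co$tables$rna_counts)
  sm <- assign_phases(co$samples)
  rec <- interval_cv(co$tables$rna_counts, co$samples)
  keep <- astrovar:::cv_mask_labels(phase_scheme(), "rna_counts")
  for (ph in unique(rec$phase)) {
    ids <- sm$sample_id[as.character(sm$phase) == ph & sm$timepoint_label %in% keep]
    for (an in sample(rownames(tab), 5)) {
      v <- tab[an, ids]
      row <- rec[rec$analyte_id == an & rec$phase == ph, ]
      expect_equal(row$raw_cv, oracle_cv(v), tolerance = 1e-12)
      expect_equal(row$mean_abundance, mean(v), tolerance = 1e-12)
    }
  }
})

test_that("per-subject averaging gives CV zero for identical subject means", {
  m <- matrix(c(1, 3, 1, 3), nrow = 1)
  # two subjects, two pre-flight timepoints each: values (1,3) per subject
  dimnames(m) <- list("a", c("C1_L-92", "C1_L-44", "C2_L-92", "C2_L-44"))
  sm <- tibble::tibble(sample_id = colnames(m),
                       subject_id = rep(c("C1", "C2"), each = 2),
                       timepoint_label = rep(c("L-92", "L-44"), 2))
  ft <- feature_table(m, "rna_counts", normalized = TRUE)
  rec <- interval_cv(ft, sm, averaging = "per_subject_mean")
  expect_equal(rec$raw_cv, 0)
  expect_equal(rec$mean_abundance, 2)
})

test_that("quantile reference bins are equal-frequency with brute-force stats", {
  withr::with_seed(10, {
    means <- rlnorm(1000, 4, 2)
    cvs <- abs(rnorm(1000, 0.4, 0.15))
  })
  rec <- tibble::tibble(analyte_id = sprintf("a%04d", 1:1000), phase = "pre_flight",
                        n_values = 12, mean_abundance = means, raw_cv = cvs,
                        flagged = FALSE)
  ref <- build_quantile_reference(rec, n_bins = 100, min_per_bin = 10)
  expect_equal(nrow(ref), 100)
  expect_true(all(ref$n == 10))
  oracle <- oracle_bin_stats(means, cvs, 100, 10)
  expect_equal(ref$cv_mean, oracle$table$cv_mean, tolerance = 1e-12)
  expect_equal(ref$cv_sd, oracle$table$cv_sd, tolerance = 1e-12)

  z <- standardize_cv(rec, ref)
  expect_equal(z$cv_z, oracle$z, tolerance = 1e-10)
})

test_that("bin count shrinks so no bin holds fewer than min_per_bin records", {
  withr::with_seed(2, {
    rec <- tibble::tibble(analyte_id = sprintf("a%02d", 1:50), phase = "x",
                          n_values = 5, mean_abundance = rlnorm(50),
                          raw_cv = runif(50), flagged = FALSE)
  })
  ref <- build_quantile_reference(rec, n_bins = 100, min_per_bin = 10)
  expect_equal(nrow(ref), 5)
  expect_true(all(ref$n == 10))
})

test_that("constant-CV references are flagged degenerate and z stays finite or missing", {
  rec <- tibble::tibble(analyte_id = sprintf("a%02d", 1:30), phase = "x",
                        n_values = 5, mean_abundance = seq(1, 30),
                        raw_cv = 0.25, flagged = FALSE)
  ref <- build_quantile_reference(rec, n_bins = 3, min_per_bin = 10)
  expect_true(all(ref$degenerate))
  expect_equal(ref$cv_mean, rep(0.25, 3))
  z <- standardize_cv(rec, ref)
  expect_equal(z$cv_z, rep(0, 30))   # CV equals the bin mean exactly

  off <- rec; off$raw_cv[1] <- 0.5
  ref2 <- build_quantile_reference(rec, n_bins = 1, min_per_bin = 30)
  expect_warning(z2 <- standardize_cv(off, ref2), "zero-spread")
  expect_true(is.na(z2$cv_z[1]))
  expect_false(any(is.infinite(z2$cv_z)))
})

test_that("standardize_cv implements (CV - CVmean_q) / CVsd_q", {
  rec <- tibble::tibble(analyte_id = "a", phase = "x", n_values = 5,
                        mean_abundance = 10, raw_cv = 0.5, flagged = FALSE)
  ref <- tibble::tibble(bin = 1L, lower = 0, upper = 20, n = 10L,
                        cv_mean = 0.3, cv_sd = 0.1, degenerate = FALSE)
  ref <- structure(ref, class = c("quantile_reference", class(ref)),
                   breaks = numeric(0), n_records = 10L)
  expect_equal(standardize_cv(rec, ref)$cv_z, 2.0)
  rec$raw_cv <- 0.3
  expect_equal(standardize_cv(rec, ref)$cv_z, 0)
})

test_that("standardized z is calibrated per bin on a null cohort", {
  co <- generate_cohort(cohort_config(modalities = c(rna_counts = 1500), seed = 17))
  z <- cv_profile(co$tables$rna_counts, co$samples, n_bins = 20)
  by_bin <- split(z$cv_z[!z$flagged], z$bin[!z$flagged])
  by_bin <- by_bin[lengths(by_bin) >= 50]
  expect_gt(length(by_bin), 5)
  for (b in by_bin) {
    expect_lt(abs(mean(b)), 0.25)
    expect_gt(sd(b), 0.7)
    expect_lt(sd(b), 1.3)
  }
})

test_that("standardization decouples z from mean abundance", {
  co <- generate_cohort(cohort_config(modalities = c(rna_counts = 2000),
                                      phi = 0.05, seed = 23))
  z <- cv_profile(co$tables$rna_counts, co$samples)
  ok <- !z$flagged & is.finite(z$cv_z)
  expect_lt(cor(z$mean_abundance[ok], z$raw_cv[ok], method = "spearman"), -0.5)
  expect_lt(abs(cor(z$mean_abundance[ok], z$cv_z[ok], method = "spearman")), 0.15)
})
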