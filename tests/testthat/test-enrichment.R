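ranked_fixture <- function(n = 10, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(analyte_id = sprintf("g%02d", 1:n),
                   score = sort(rnorm(n, 0, 2), decreasing = TRUE))
  })
}

test_that("the running-sum ES matches hand enumeration and its extremes", {
  r <- ranked_fixture(10)
  # a set covering the whole list never decrements: ES = 1
  expect_equal(preranked_es(r, r$analyte_id)$es, 1)
  expect_equal(preranked_es(r, r$analyte_id, weight = 0)$es, 1)

  top3 <- r$analyte_id[1:3]
  fit <- preranked_es(r, top3, weight = 0)
  expect_equal(fit$es, oracle_es(r$analyte_id, r$score, top3, 0), tolerance = 1e-12)
  expect_equal(fit$es, 1)   # top block peaks before any miss

  bottom3 <- r$analyte_id[8:10]
  fit_b <- preranked_es(r, bottom3, weight = 0)
  expect_equal(fit_b$es, -fit$es, tolerance = 1e-12)  # unweighted symmetry

  expect_error(preranked_es(r, c("zz1", "zz2")), "no members")
})

test_that("weighted ES equals the brute-force running sum on random instances", {
  for (seed in 1:5) {
    r <- ranked_fixture(40, seed = seed)
    withr::with_seed(seed + 100, {
      set <- sample(r$analyte_id, 8)
    })
    for (w in c(0, 1, 1.5)) {
      expect_equal(preranked_es(r, set, weight = w)$es,
                   oracle_es(r$analyte_id, r$score, set, w), tolerance = 1e-12)
    }
  }
})

test_that("unweighted |ES| equals the two-sample KS statistic on hit/miss ranks", {
  for (seed in 1:4) {
    r <- ranked_fixture(50, seed = seed)
    withr::with_seed(seed, set <- sample(r$analyte_id, 12))
    es <- preranked_es(r, set, weight = 0)$es
    pos <- seq_len(50)
    hit <- pos[r$analyte_id %in% set]
    ks <- suppressWarnings(ks.test(hit, setdiff(pos, hit))$statistic)
    expect_equal(abs(es), unname(ks), tolerance = 1e-12)
  }
})

test_that("weighted ES agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  for (seed in 1:3) {
    r <- ranked_fixture(60, seed = seed)
    withr::with_seed(seed, set <- sample(r$analyte_id, 10))
    stats <- setNames(r$score, r$analyte_id)
    idx <- which(r$analyte_id %in% set)
    ref <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = 1)
    expect_equal(preranked_es(r, set, weight = 1)$es, ref, tolerance = 1e-10)
  }
})

test_that("the permutation null is deterministic and NES behaves at the edges", {
  r <- ranked_fixture(30, seed = 2)
  a <- preranked_null(r, k = 5, n_perm = 50, seed = 4)
  b <- preranked_null(r, k = 5, n_perm = 50, seed = 4)
  expect_identical(a, b)

  # whole-list sets always score 1
  null_full <- preranked_null(r, k = 30, n_perm = 10, seed = 1)
  expect_equal(null_full, rep(1, 10))
  np <- nes_and_p(1, null_full)
  expect_equal(np$nes, 1)
  expect_equal(np$p_value, 1)

  # an observed ES near the null median gets p near 0.5
  null_big <- preranked_null(r, k = 5, n_perm = 500, seed = 9)
  med <- median(null_big[null_big > 0])
  np2 <- nes_and_p(med, null_big)
  expect_gt(np2$p_value, 0.3)
  expect_lt(np2$p_value, 0.7)
})

test_that("gsea_preranked returns coherent records over a collection", {
  r <- ranked_fixture(80, seed = 6)
  collection <- list(top = r$analyte_id[1:10],
                     bottom = r$analyte_id[71:80],
                     random = withr::with_seed(8, sample(r$analyte_id, 10)))
  res <- gsea_preranked(r, collection, n_perm = 200, seed = 3)
  expect_setequal(res$set, names(collection))
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_equal(res$direction[res$set == "top"], "up")
  expect_equal(res$direction[res$set == "bottom"], "down")
  expect_lt(res$p_value[res$set == "top"], 0.05)
  top_row <- res[res$set == "top", ]
  expect_true(all(unlist(top_row$leading_edge) %in% collection$top))
})

test_that("hypergeometric ORA matches the exact tail sum", {
  uni <- sprintf("u%02d", 1:20)
  set <- uni[1:5]
  hits <- c(uni[1:3], uni[10:11])   # overlap 3 of 5
  res <- ora_hypergeometric(hits, list(S = set), uni)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_value, oracle_hyper_tail(3, 5, 20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0726, tolerance = 1e-3)
  expect_equal(res$enrichment_ratio, 3 / (5 * 5 / 20))

  # disjoint hit list: overlap 0 is certain, p = 1
  res0 <- ora_hypergeometric(uni[10:14], list(S = set), uni)
  expect_equal(res0$p_value, 1)
  # hits = universe: overlap equals the set size with certainty
  resU <- ora_hypergeometric(uni, list(S = set), uni)
  expect_equal(resU$overlap, 5)
  expect_equal(resU$p_value, 1)

  expect_error(ora_hypergeometric(c("zzz"), list(S = set), uni), "outside")
  for (seed in 1:3) {
    withr::with_seed(seed, {
      s2 <- sample(uni, 8); h2 <- sample(uni, 7)
    })
    r2 <- ora_hypergeometric(h2, list(S = s2), uni)
    expect_equal(r2$p_value,
                 oracle_hyper_tail(r2$overlap, 8, 20, 7), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the spelled-out step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  for (seed in 1:4) {
    p <- withr::with_seed(seed, runif(25))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q <= 1))
  }
})

test_that("pathway reporting keeps the top-40 / FDR<0.05 union", {
  rec <- tibble::tibble(set = sprintf("P%03d", 1:100), fdr = 0.5)
  expect_equal(nrow(filter_pathways(rec)), 40)

  rec2 <- tibble::tibble(set = sprintf("P%03d", 1:60), fdr = 0.01)
  expect_equal(nrow(filter_pathways(rec2)), 60)

  withr::with_seed(7, {
    rec3 <- tibble::tibble(set = sprintf("P%03d", 1:120), fdr = runif(120, 0, 0.2))
  })
  got <- filter_pathways(rec3)
  ord <- rec3[order(rec3$fdr, rec3$set), ]
  manual <- union(head(ord$set, 40), rec3$set[rec3$fdr < 0.05])
  expect_setequal(got$set, manual)
})

test_that("preranked and ORA p-values are calibrated under random inputs", {
  r <- ranked_fixture(200, seed = 11)
  null_es <- preranked_null(r, k = 15, n_perm = 400, seed = 12)
  ps <- vapply(seq_len(200), function(i) {
    set <- withr::with_seed(1000 + i, sample(r$analyte_id, 15))
    nes_and_p(preranked_es(r, set)$es, null_es)$p_value
  }, double(1))
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.12)
})
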