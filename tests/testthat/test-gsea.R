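test_that("median-log2FC ranking scores genes against the cohort median", {
  m <- toy_matrix(rbind(c(8, 2, 2), c(2, 2, 2), c(1, 4, 16)),
                  genes = c("UP", "FLAT", "LOW"), samples = c("s1", "s2", "s3"))
  rk <- rank_by_median_logfc(m, "s1", pseudocount = 0)
  expect_identical(rk$gene[1], "UP")
  expect_equal(rk$score[rk$gene == "UP"], 2)      # log2(8 / 2)
  expect_equal(rk$score[rk$gene == "FLAT"], 0)
  expect_equal(rk$score[rk$gene == "LOW"], -2)    # log2(1 / 4)
  expect_error(rank_by_median_logfc(m, "nope"), "unknown sample")
})

test_that("a sample identical to the cohort median yields a degenerate ranking", {
  # S02 holds exactly the per-gene medians, so every log2FC is 0
  m <- toy_matrix(rbind(c(1, 2, 4), c(3, 5, 9), c(6, 7, 8)))
  expect_error(rank_by_median_logfc(m, "S02", pseudocount = 0),
               "degenerate ranking")
})

test_that("ranking matches a brute-force per-gene recomputation", {
  withr::local_seed(21)
  m <- toy_matrix(matrix(abs(rnorm(1000, 10, 3)), nrow = 100))
  rk <- rank_by_median_logfc(m, "S05", pseudocount = 1)
  v <- unclass(m)
  for (g in sample(rownames(m), 20)) {
    expect_equal(rk$score[rk$gene == g],
                 log2((v[g, "S05"] + 1) / (median(v[g, ]) + 1)),
                 tolerance = 1e-12)
  }
  # log2 input is de-logged before ranking
  rk2 <- rank_by_median_logfc(toy_matrix(log2(v), scale = "log2"), "S05",
                              pseudocount = 1)
  expect_equal(rk2$score, rk$score, tolerance = 1e-10)
})

test_that("hand-computed enrichment-score anchors hold", {
  rk <- tibble::tibble(gene = paste0("g", 1:4), score = c(4, 3, 2, 1))
  top <- enrichment_score(rk, "g1", weight_p = 1, min_set_size = 1)
  expect_equal(top$es, 1)
  expect_equal(top$running_sum, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  bottom <- enrichment_score(rk, "g4", weight_p = 1, min_set_size = 1)
  expect_equal(bottom$es, -1)
  expect_equal(bottom$running_sum, c(-1 / 3, -2 / 3, -1, 0), tolerance = 1e-12)
})

test_that("enrichment score matches the naive oracle and conserves its endpoint", {
  withr::local_seed(31)
  for (i in 1:60) {
    n <- sample(50:200, 1)
    k <- sample(5:20, 1)
    p <- sample(c(0, 0.5, 1, 2), 1)
    rk <- random_ranked(n)
    set <- sample(rk$gene, k)
    got <- enrichment_score(rk, set, weight_p = p)
    want <- naive_es(rk$gene, rk$score, set, p)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$running_sum, want$run, tolerance = 1e-12)
    expect_lt(abs(got$running_sum[n]), 1e-9)
    expect_lte(abs(got$es), 1)
  }
})

test_that("fast position-based permutation scores agree with the full trace", {
  withr::local_seed(32)
  rk <- random_ranked(300)
  w <- abs(rk$score)^1
  for (i in 1:40) {
    pos <- sort(sample.int(300, 12))
    fast <- ovasig:::.es_from_positions(pos, w, 300)
    full <- enrichment_score(rk, rk$gene[pos], weight_p = 1)$es
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("ES is invariant to monotone transforms at p = 0 and to rescaling at any p", {
  withr::local_seed(33)
  rk <- random_ranked(150)
  set <- sample(rk$gene, 12)
  base0 <- enrichment_score(rk, set, weight_p = 0)
  mono <- rk
  mono$score <- exp(rk$score)        # strictly monotone, preserves order
  expect_equal(enrichment_score(mono, set, weight_p = 0)$es, base0$es,
               tolerance = 1e-12)
  for (p in c(0, 1, 2)) {
    base <- enrichment_score(rk, set, weight_p = p)
    sc <- rk
    sc$score <- rk$score * 3.7
    expect_equal(enrichment_score(sc, set, weight_p = p)$es, base$es,
                 tolerance = 1e-12)
  }
  # reversing the list negates the unweighted ES
  rev_rk <- tibble::tibble(gene = rev(rk$gene), score = rev(-rk$score))
  expect_equal(enrichment_score(rev_rk, set, weight_p = 0)$es, -base0$es,
               tolerance = 1e-12)
})

test_that("enrichment scores agree with fgsea on random instances", {
  skip_if_not_installed("fgsea")
  withr::local_seed(34)
  for (i in 1:20) {
    rk <- random_ranked(200)
    set <- sample(rk$gene, 15)
    stats <- setNames(rk$score, rk$gene)
    ours <- enrichment_score(rk, set, weight_p = 1)$es
    theirs <- fgsea::calcGseaStat(stats, which(rk$gene %in% set), gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("set intersection, degenerate sets and zero weights raise contract errors", {
  rk <- random_ranked(50)
  expect_error(enrichment_score(rk, rk$gene[1:3], min_set_size = 5),
               "set too small after intersection")
  expect_error(enrichment_score(rk, rk$gene, min_set_size = 5),
               "at least one miss")
  flatk <- tibble::tibble(gene = c("a", "b", "c", "d"), score = c(2, 0, 0, -1))
  expect_error(enrichment_score(flatk, c("b", "c"), weight_p = 1, min_set_size = 2),
               "zero hit weight")
})

test_that("NES and permutation p-value are deterministic and extreme for a top-k set", {
  withr::local_seed(35)
  rk <- random_ranked(1000)
  set <- rk$gene[1:10]
  r1 <- normalized_enrichment(rk, set, n_perm = 999, seed = 7)
  r2 <- normalized_enrichment(rk, set, n_perm = 999, seed = 7)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$p_perm, r2$p_perm)
  # the top-k set attains the maximal ES of 1; no random subset matches it,
  # so the p-value sits at the floor of the same-sign null
  expect_equal(r1$es, 1)
  expect_equal(r1$p_perm, 1 / (1 + r1$n_same_sign))
  expect_lte(r1$p_perm, 1 / 500)
  expect_gt(r1$nes, 1)
  expect_error(normalized_enrichment(rk, set, n_perm = 0), "invalid n_perm")
})
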