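test_that("z-transformation standardizes every retained gene", {
  m <- toy_matrix(rbind(c(1, 2, 3), c(10, 20, 60)))
  z <- zscore_transform(m)
  expect_equal(unname(unclass(z)[1, ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(unclass(z))) < 1e-9))
  expect_true(all(abs(apply(unclass(z), 1, sd) - 1) < 1e-9))

  withr::local_seed(41)
  big <- toy_matrix(matrix(rnorm(6000), nrow = 200), scale = "log2")
  zb <- unclass(zscore_transform(big))
  v <- unclass(big)
  brute <- t(apply(v, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(zb, brute, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("constant genes are dropped with a warning; all-constant input errors", {
  m <- toy_matrix(rbind(c(1, 2, 3), c(2, 4, 8), c(5, 5, 5)))
  expect_warning(z <- zscore_transform(m), "constant gene")
  expect_identical(attr(z, "dropped_genes"), "G03")
  expect_equal(nrow(z), 2L)
  flat <- toy_matrix(rbind(c(5, 5, 5), c(7, 7, 7)))
  expect_error(zscore_transform(flat), "no variable genes")
})

test_that("signature scores reduce to column means and honor the missing-gene policy", {
  withr::local_seed(43)
  m <- toy_matrix(matrix(rnorm(50, 5), nrow = 10), scale = "log2")
  z <- zscore_transform(m)
  all_genes <- signature_score(z, rownames(z))
  expect_equal(all_genes$score, unname(colMeans(unclass(z))), tolerance = 1e-12)

  one <- signature_score(z, c("G01", "NOT_A_GENE"))
  expect_equal(one$score, unname(unclass(z)["G01", ]), tolerance = 1e-12)
  expect_identical(attr(one, "genes_missing"), "NOT_A_GENE")
  expect_identical(attr(one, "genes_used"), 1L)
  expect_error(signature_score(z, "NOT_A_GENE"), "signature absent")
})

test_that("the embedded RBP signature separates C5 from non-C5 across seeds", {
  gaps <- vapply(1:30, function(s) {
    sim <- simulate_subtype_cohort(n_per_subtype = c(C1 = 10, C5 = 10),
                                   n_genes = 100, signature_size = 15,
                                   effect_size = 2, seed = s)
    sc <- signature_score(zscore_transform(sim$matrix), sim$signatures$RBP)
    is_c5 <- sim$labels$subtype == "C5"
    mean(sc$score[is_c5]) - mean(sc$score[!is_c5])
  }, numeric(1))
  expect_true(all(gaps > 0))
})

test_that("AUC anchors: perfect separation, all ties, and the 4-point case", {
  expect_equal(roc_auc(c(a = 1, b = 2, c = 10, d = 20),
                       c(a = FALSE, b = FALSE, c = TRUE, d = TRUE))$auc, 1)
  expect_equal(roc_auc(c(a = 3, b = 3, c = 3, d = 3),
                       c(a = FALSE, b = TRUE, c = FALSE, d = TRUE))$auc, 0.5)
  # brute force over the 4 (pos, neg) pairs: 3 of 4 concordant
  s4 <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  l4 <- c(s1 = "negative", s2 = "positive", s3 = "negative", s4 = "positive")
  expect_equal(roc_auc(s4, l4)$auc, 0.75)
  expect_equal(pairwise_auc(s4, l4 == "positive"), 0.75)
  expect_error(roc_auc(c(a = 1, b = 2), c(a = TRUE, b = TRUE)), "degenerate labels")
})

test_that("AUC equals the pairwise oracle, the trapezoid, and flips under negation", {
  withr::local_seed(47)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    scores <- setNames(sample(1:10, n, replace = TRUE) + 0, paste0("s", 1:n))
    labs <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), names(scores))
    if (all(labs) || !any(labs)) labs[1:2] <- c(TRUE, FALSE)
    r <- roc_auc(scores, labs)
    expect_equal(r$auc, pairwise_auc(scores, labs), tolerance = 1e-12)
    trap <- sum(diff(r$curve$fpr) * (head(r$curve$tpr, -1) + r$curve$tpr[-1]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    expect_equal(roc_auc(-scores, labs)$auc, 1 - r$auc, tolerance = 1e-12)
    expect_equal(roc_auc(exp(scores / 3), labs)$auc, r$auc, tolerance = 1e-12)
    expect_true(!is.unsorted(r$curve$fpr) && !is.unsorted(r$curve$tpr))
    expect_equal(c(r$curve$fpr[1], r$curve$tpr[1]), c(0, 0))
    expect_equal(c(dplyr::last(r$curve$fpr), dplyr::last(r$curve$tpr)), c(1, 1))
  }
})

test_that("AUC agrees with pROC on tied data", {
  skip_if_not_installed("pROC")
  withr::local_seed(53)
  scores <- sample(1:6, 40, replace = TRUE) + 0
  labs <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  ours <- roc_auc(setNames(scores, paste0("s", 1:40)),
                  setNames(labs, paste0("s", 1:40)))$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labs, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("empirical signature AUC converges to the generator's closed-form AUC", {
  # score ~ mean z over m signature genes; groups differ by delta in log2
  # space, so AUC -> Phi(delta * sqrt(m) / (sigma * sqrt(2))) under the
  # generator's Gaussian model (z-normalization scales both groups alike).
  delta <- 0.3; sigma <- 1; m <- 20
  sim <- simulate_subtype_cohort(n_per_subtype = c(C1 = 5000, C5 = 5000),
                                 n_genes = 60, signature_size = m,
                                 effect_size = delta, noise_sd = sigma,
                                 seed = 59)
  sc <- signature_score(zscore_transform(sim$matrix), sim$signatures$C5)
  auc <- roc_auc(sc, setNames(sim$labels$subtype == "C5",
                              sim$labels$sample_id))$auc
  oracle <- pnorm(delta * sqrt(m) / (sigma * sqrt(2)))
  expect_equal(auc, oracle, tolerance = 0.01)
})

test_that("stratified bootstrap CI brackets the AUC and is seeded", {
  withr::local_seed(61)
  scores <- setNames(c(rnorm(30, 1), rnorm(30)), paste0("s", 1:60))
  labs <- setNames(rep(c(TRUE, FALSE), each = 30), names(scores))
  ci1 <- roc_auc_ci(scores, labs, n_boot = 200, seed = 3)
  ci2 <- roc_auc_ci(scores, labs, n_boot = 200, seed = 3)
  expect_identical(ci1, ci2)
  expect_lte(ci1$conf_low, ci1$auc)
  expect_gte(ci1$conf_high, ci1$auc)
})
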