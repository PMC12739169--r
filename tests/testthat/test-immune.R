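test_that("cumulative marker scores are column sums over present panel genes", {
  m <- toy_matrix(rbind(c(3, 1), c(4, 2), c(100, 100)),
                  genes = c("A", "B", "OTHER"))
  sc <- cumulative_marker_score(m, c("A", "B"))
  expect_equal(sc$score, c(7, 3))
  with_missing <- cumulative_marker_score(m, c("A", "B", "C"))
  expect_equal(with_missing$score, sc$score)
  expect_identical(attr(with_missing, "genes_missing"), "C")
  expect_error(cumulative_marker_score(m, "NOPE"), "panel absent")

  withr::local_seed(71)
  big <- toy_matrix(matrix(abs(rnorm(600, 10)), nrow = 30))
  panel <- sample(rownames(big), 7)
  expect_equal(cumulative_marker_score(big, panel)$score,
               unname(colSums(unclass(big)[panel, ])), tolerance = 1e-12)
})

test_that("MHC-I/PD-L1 ratio arithmetic, symmetry and pseudocount guard", {
  m <- toy_matrix(rbind(c(3, 2), c(4, 2), c(1, 4)),
                  genes = c("HLA-A", "HLA-B", "CD274"))
  rt <- mhc1_pdl1_ratio(m, numerator = c("HLA-A", "HLA-B"),
                        denominator = "CD274", pseudocount = 1)
  expect_equal(rt$log2_ratio[1], 2)   # log2((7+1)/(1+1))
  same <- mhc1_pdl1_ratio(m, numerator = c("HLA-A", "HLA-B"),
                          denominator = c("HLA-A", "HLA-B"), pseudocount = 1)
  expect_equal(same$log2_ratio, c(0, 0))
  flipped <- mhc1_pdl1_ratio(m, numerator = "CD274",
                             denominator = c("HLA-A", "HLA-B"), pseudocount = 1)
  expect_equal(flipped$log2_ratio, -rt$log2_ratio, tolerance = 1e-12)

  z <- toy_matrix(rbind(c(3, 2), c(0, 0)), genes = c("HLA-A", "CD274"))
  expect_error(mhc1_pdl1_ratio(z, numerator = "HLA-A", denominator = "CD274",
                               pseudocount = 0), "division by zero")
})

test_that("Pearson test matches identities and the textbook recomputation", {
  id <- pearson_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$r, 1)
  expect_equal(id$p, 0)
  expect_true(id$perfect)
  expect_equal(pearson_test(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")

  withr::local_seed(73)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10)
  got <- pearson_test(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r * sqrt(8) / sqrt(1 - r^2)
  expect_equal(got$r, r, tolerance = 1e-10)
  expect_equal(got$t, t_stat, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(abs(t_stat), 8, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(got$fisher_z, atanh(r), tolerance = 1e-10)
  expect_equal(got$z_variance, 1 / 7)

  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)
})

test_that("meta-analysis degeneracies: single study and exact homogeneity", {
  one <- random_effects_meta(tibble::tibble(label = "only", r = 0.5, n = 50))
  expect_equal(one$pooled_r, 0.5, tolerance = 1e-12)
  expect_equal(one$Q, 0)
  expect_equal(one$I2, 0)
  expect_equal(one$tau2, 0)

  two <- random_effects_meta(tibble::tibble(label = c("a", "b"),
                                            r = 0.3, n = 100))
  expect_equal(two$pooled_r, 0.3, tolerance = 1e-12)
  expect_equal(two$Q, 0, tolerance = 1e-12)
  expect_equal(two$I2, 0)
})

test_that("DerSimonian-Laird pooling matches the step-by-step worksheet", {
  studies <- tibble::tibble(label = c("A", "B", "C"),
                            r = c(0.10, 0.45, 0.62), n = c(40, 120, 60))
  got <- random_effects_meta(studies)

  # worksheet: every quantity recomputed longhand
  z <- atanh(studies$r)
  v <- 1 / (studies$n - 3)
  w <- 1 / v
  zf <- sum(w * z) / sum(w)
  q <- sum(w * (z - zf)^2)
  c_scale <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - 2) / c_scale)
  wr <- 1 / (v + tau2)
  zr <- sum(wr * z) / sum(wr)
  se <- sqrt(1 / sum(wr))
  expect_equal(got$Q, q, tolerance = 1e-8)
  expect_equal(got$tau2, tau2, tolerance = 1e-8)
  expect_equal(got$I2, max(0, (q - 2) / q) * 100, tolerance = 1e-8)
  expect_equal(got$pooled_r, tanh(zr), tolerance = 1e-8)
  expect_equal(got$ci95, c(tanh(zr - qnorm(0.975) * se),
                           tanh(zr + qnorm(0.975) * se)), tolerance = 1e-8)

  expect_error(random_effects_meta(tibble::tibble(label = "x", r = 1, n = 10)),
               "Fisher transform undefined")
  expect_error(random_effects_meta(tibble::tibble(label = "x", r = 0.2, n = 3)),
               "study too small")
})

test_that("pooling agrees with metafor and stays within the study range", {
  skip_if_not_installed("metafor")
  withr::local_seed(79)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    studies <- tibble::tibble(label = paste0("s", 1:k),
                              r = runif(k, -0.7, 0.7),
                              n = sample(10:300, k, replace = TRUE))
    got <- random_effects_meta(studies)
    expect_gte(got$pooled_r, min(studies$r) - 1e-12)
    expect_lte(got$pooled_r, max(studies$r) + 1e-12)
    fit <- metafor::rma(yi = atanh(studies$r), vi = 1 / (studies$n - 3),
                        method = "DL")
    expect_equal(got$pooled_r, tanh(as.numeric(fit$b)), tolerance = 1e-8)
    expect_equal(got$tau2, fit$tau2, tolerance = 1e-8)
    expect_equal(got$I2, fit$I2, tolerance = 1e-6)
    expect_equal(got$Q, fit$QE, tolerance = 1e-8)
  }
})
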