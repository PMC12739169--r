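#' Cumulative marker-panel score per sample
#'
#' Sum of linear-scale expression (e.g., reads) over the panel genes
#' present in the matrix, per column. Missing panel genes are dropped and
#' reported.
#'
#' @param x An [expr_matrix()] on the linear scale.
#' @param genes Character vector of panel gene identifiers.
#' @return A tibble (`sample_id`, `score`) with attribute `genes_missing`.
#' @export
cumulative_marker_score <- function(x, genes) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_scale(x) != "linear") abort("cumulative scores need linear-scale values.")
  genes <- unique(as.character(genes))
  present <- intersect(genes, rownames(x))
  if (length(present) == 0L) abort("panel absent from matrix.")
  sc <- colSums(unclass(x)[present, , drop = FALSE])
  out <- tibble(sample_id = colnames(x), score = unname(sc))
  attr(out, "genes_missing") <- setdiff(genes, present)
  out
}

#' MHC-I / PD-L1 expression ratio per sample
#'
#' Log2 ratio of cumulative numerator-panel expression to cumulative
#' denominator expression, with a shared pseudocount:
#' `log2((sum numerator + eps) / (sum denominator + eps))`. With the
#' default panels (class-I HLA genes over CD274), low values mark an
#' immune-evasive surface-receptor landscape. Group the output tibble by
#' cell-cluster labels to aggregate per cluster.
#'
#' @param x An [expr_matrix()] on the linear scale (e.g., counts).
#' @param numerator Character vector of numerator panel genes
#'   (default class-I HLA).
#' @param denominator Character vector (often a single gene; default CD274,
#'   i.e. PD-L1).
#' @param pseudocount Shared pseudocount eps; must be > 0 if zero
#'   denominators are possible.
#' @return A tibble (`sample_id`, `log2_ratio`).
#' @examples
#' mns <- cell_population_means(c("evasive", "inflamed"), mhc_pdl1_ratio = c(0.5, 10))
#' pop <- simulate_cell_population(
#'   tibble::tibble(cluster = c("evasive", "inflamed"), n_cells = c(20, 20)),
#'   mns, seed = 1)
#' mhc1_pdl1_ratio(pop$matrix)
#' @export
mhc1_pdl1_ratio <- function(x, numerator = c("HLA-A", "HLA-B", "HLA-C"),
                            denominator = "CD274", pseudocount = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_scale(x) != "linear") abort("ratio metrics need linear-scale values.")
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  num <- cumulative_marker_score(x, numerator)$score
  den <- cumulative_marker_score(x, denominator)$score
  if (pseudocount == 0 && any(den == 0)) {
    abort("division by zero; set pseudocount > 0.")
  }
  tibble(sample_id = colnames(x),
         log2_ratio = log2((num + pseudocount) / (den + pseudocount)))
}

#' Pearson correlation with parametric two-sided t test
#'
#' Product-moment correlation with significance from the t distribution:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-sided. Also returns the Fisher z transform `atanh(r)` and its
#' large-sample variance `1 / (n - 3)`, the inputs to random-effects
#' pooling across datasets.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return A one-row tibble: `r`, `n`, `t`, `p`, `fisher_z`, `z_variance`,
#'   `perfect` (TRUE when |r| = 1, in which case `p` = 0 and `t` is
#'   infinite).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3L) abort("need at least 3 paired observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite.")
  if (sd(x) <= .eps || sd(y) <= .eps) abort("zero variance input.")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  perfect <- abs(r) >= 1 - .eps
  if (perfect) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  }
  tibble(r = r, n = n, t = t_stat, p = p,
         fisher_z = atanh(max(-1 + .eps, min(1 - .eps, r))),
         z_variance = 1 / (n - 3),
         perfect = perfect)
}

#' Random-effects pooling of Pearson correlations
#'
#' DerSimonian-Laird random-effects meta-analysis on the Fisher z scale,
#' the classic closed-form estimator behind forest plots of per-dataset
#' correlations. Per study: z = atanh(r), variance v = 1/(n-3),
#' fixed-effect weight w = 1/v. Heterogeneity: Cochran
#' `Q = sum w (z - z_fixed)^2`, `tau2 = max(0, (Q - df) / (sum w - sum
#' w^2 / sum w))`, `I2 = max(0, (Q - df) / Q) * 100`. Random-effect
#' weights `1 / (v + tau2)` give the pooled z and its 95% CI, which are
#' back-transformed to the correlation scale with `tanh`.
#'
#' @param studies A data frame with columns `label`, `r`, `n` (one row per
#'   dataset); every `n` >= 4 and every `|r|` < 1.
#' @return A `meta_result`: list with `studies` (per-study tibble including
#'   z, variance, weights and 95% CI), `pooled_r`, `ci95`, `Q`, `tau2`,
#'   `I2`. `tidy()` returns the per-study table with the pooled row
#'   appended, `glance()` the one-row summary.
#' @examples
#' random_effects_meta(tibble::tibble(
#'   label = c("TCGA", "AOCS"), r = c(-0.35, -0.22), n = c(121, 105)))
#' @export
random_effects_meta <- function(studies) {
  studies <- as_tibble(studies)
  if (!all(c("label", "r", "n") %in% names(studies))) {
    abort("`studies` needs columns label, r, n.")
  }
  if (any(studies$n < 4)) abort("study too small: every n must be >= 4.")
  if (any(abs(studies$r) >= 1)) abort("Fisher transform undefined for |r| = 1.")
  k <- nrow(studies)
  z <- atanh(studies$r)
  v <- 1 / (studies$n - 3)
  w <- 1 / v
  z_fixed <- sum(w * z) / sum(w)
  q <- sum(w * (z - z_fixed)^2)
  df <- k - 1
  tau2 <- if (k > 1) max(0, (q - df) / (sum(w) - sum(w^2) / sum(w))) else 0
  i2 <- if (k > 1 && q > 0) max(0, (q - df) / q) * 100 else 0
  w_re <- 1 / (v + tau2)
  z_pooled <- sum(w_re * z) / sum(w_re)
  se_pooled <- sqrt(1 / sum(w_re))
  crit <- qnorm(0.975)
  per_study <- studies |>
    dplyr::mutate(
      fisher_z = z, z_variance = v,
      weight_fixed = w / sum(w), weight_random = w_re / sum(w_re),
      conf_low = tanh(z - crit * sqrt(v)),
      conf_high = tanh(z + crit * sqrt(v))
    )
  structure(
    list(studies = per_study,
         pooled_r = tanh(z_pooled),
         ci95 = c(tanh(z_pooled - crit * se_pooled),
                  tanh(z_pooled + crit * se_pooled)),
         Q = q, tau2 = tau2, I2 = i2),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d studies: pooled r = %.3f [%.3f, %.3f], Q = %.3f, tau2 = %.4f, I2 = %.1f%%\n",
              nrow(x$studies), x$pooled_r, x$ci95[1L], x$ci95[2L],
              x$Q, x$tau2, x$I2))
  invisible(x)
}

#' @rdname random_effects_meta
#' @param x A `meta_result`.
#' @param ... Unused.
#' @export
tidy.meta_result <- function(x, ...) {
  dplyr::bind_rows(
    x$studies |> dplyr::mutate(pooled = FALSE),
    tibble(label = "Random effects", r = x$pooled_r, n = sum(x$studies$n),
           conf_low = x$ci95[1L], conf_high = x$ci95[2L], pooled = TRUE)
  )
}

#' @rdname random_effects_meta
#' @export
glance.meta_result <- function(x, ...) {
  tibble(pooled_r = x$pooled_r, conf_low = x$ci95[1L], conf_high = x$ci95[2L],
         Q = x$Q, tau2 = x$tau2, I2 = x$I2, n_studies = nrow(x$studies))
}
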