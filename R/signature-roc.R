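#' Score samples by the mean z-value of a gene signature
#'
#' Per sample, the mean of per-gene z-scores over the signature genes
#' present in the matrix. Missing signature genes are dropped, never
#' imputed, and reported so the intersection is auditable.
#'
#' @param z An [expr_matrix()] on the z-score scale (see
#'   [zscore_transform()]).
#' @param signature Character vector of signature gene identifiers.
#' @return A tibble (`sample_id`, `score`) with attributes `genes_used`
#'   (count) and `genes_missing` (identifiers absent from the matrix).
#' @examples
#' sim <- simulate_subtype_cohort(n_per_subtype = c(C1 = 5, C5 = 5),
#'                                n_genes = 120, signature_size = 20, seed = 1)
#' z <- zscore_transform(sim$matrix)
#' signature_score(z, sim$signatures$RBP)
#' @export
signature_score <- function(z, signature) {
  stopifnot(inherits(z, "expr_matrix"))
  if (expr_scale(z) != "zscore") {
    abort("`z` must be z-scored; call zscore_transform() first.")
  }
  signature <- unique(as.character(signature))
  present <- intersect(signature, rownames(z))
  if (length(present) == 0L) abort("signature absent from matrix.")
  sc <- colMeans(unclass(z)[present, , drop = FALSE])
  out <- tibble(sample_id = colnames(z), score = unname(sc))
  attr(out, "genes_used") <- length(present)
  attr(out, "genes_missing") <- setdiff(signature, present)
  out
}

#' ROC curve and AUC of a score against binary labels
#'
#' The AUC is the tie-corrected Mann-Whitney statistic
#' `U / (n_pos * n_neg)` (ties count 1/2), which equals the trapezoidal
#' area under the empirical ROC curve built from all distinct score
#' thresholds. The positive class is the one the score is directed at
#' (here: C5-like, signature-high).
#'
#' @param scores A tibble (`sample_id`, `score`) as returned by
#'   [signature_score()], or a named numeric vector.
#' @param labels Labels for the scored samples: a named vector (names =
#'   sample ids) or a tibble (`sample_id`, `label`); values must be
#'   `"positive"`/`"negative"` (logical `TRUE`/`FALSE` also accepted).
#' @return A `roc_result`: list with `auc`, `n_pos`, `n_neg`, and `curve`
#'   (tibble `threshold`, `fpr`, `tpr` from (0,0) to (1,1)). `tidy()`
#'   returns the curve, `glance()` the one-row summary.
#' @export
roc_auc <- function(scores, labels) {
  if (is.data.frame(scores)) {
    s <- setNames(scores$score, scores$sample_id)
  } else {
    s <- scores
  }
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$sample_id)
  }
  if (!is.null(names(s)) && !is.null(names(labels))) {
    if (!all(names(s) %in% names(labels))) abort("labels missing for some scored samples.")
    labels <- labels[names(s)]
  }
  if (length(labels) != length(s)) abort("scores and labels differ in length.")
  if (is.logical(labels)) {
    pos <- labels
  } else {
    if (!all(labels %in% c("positive", "negative"))) {
      abort("labels must be \"positive\"/\"negative\" (or logical).")
    }
    pos <- labels == "positive"
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) abort("degenerate labels: need both classes.")
  r <- rank(s)   # midranks handle ties with the 1/2 convention
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos & s >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!pos & s >= t), numeric(1))
  curve <- tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Stratified bootstrap confidence interval for an AUC
#'
#' Percentile CI from class-stratified resampling: positives and negatives
#' are resampled independently with replacement so both classes survive
#' every replicate. Useful when comparing a compact signature against a
#' large panel on the same cohort.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return A tibble: `auc`, `conf_low`, `conf_high`, `n_boot`.
#' @export
roc_auc_ci <- function(scores, labels, n_boot = 2000, conf = 0.95, seed = NULL) {
  base <- roc_auc(scores, labels)
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$sample_id)
  if (is.data.frame(labels)) labels <- setNames(labels$label, labels$sample_id)
  if (!is.null(names(scores))) labels <- labels[names(scores)]
  pos <- if (is.logical(labels)) labels else labels == "positive"
  sp <- scores[pos]
  sn <- scores[!pos]
  draw <- function() {
    vapply(seq_len(n_boot), function(i) {
      bp <- sample(sp, replace = TRUE)
      bn <- sample(sn, replace = TRUE)
      roc_auc(c(bp, bn), c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))$auc
    }, numeric(1))
  }
  reps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  q <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble(auc = base$auc, conf_low = q[1L], conf_high = q[2L], n_boot = n_boot)
}
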