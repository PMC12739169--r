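#' Classify one sample into a molecular subtype
#'
#' Scores the sample against every subtype signature by single-sample
#' preranked GSEA (cohort-median log2FC ranking, gene-set-permutation NES)
#' and assigns the subtype with the highest NES. The delta-NES margin (top
#' NES minus second NES) drives the ambiguity filter: a sample whose margin
#' falls below `delta_cutoff` is effectively assigned to more than one
#' cluster and is excluded. Samples with no positively enriched subtype
#' (top NES <= 0) are also excluded.
#'
#' Permutation nulls are shared across signatures with the same intersected
#' size, so the per-sample cost is one null per distinct size.
#'
#' @param x An [expr_matrix()] (linear or log2) with >= 3 samples.
#' @param sample Sample identifier.
#' @param signatures A [gene_sets()] collection of >= 2 subtype signatures.
#' @param delta_cutoff Ambiguity cutoff on the top-two NES margin
#'   (default 0.4).
#' @param weight_p,min_set_size,pseudocount GSEA parameters (see
#'   [enrichment_score()] and [rank_by_median_logfc()]).
#' @param n_perm Permutations per null.
#' @param seed Integer seed for the permutation draws.
#' @return A one-row tibble: `sample_id`, one `nes_<subtype>` column per
#'   signature, `top_subtype` (or "unclassified"), `delta_nes`, `ambiguous`,
#'   `excluded`.
#' @export
classify_sample <- function(x, sample, signatures, delta_cutoff = 0.4,
                            weight_p = 1, n_perm = 1000, min_set_size = 5,
                            pseudocount = 1, seed = NULL) {
  stopifnot(inherits(signatures, "gene_set_collection"))
  if (length(signatures) < 2L) abort("need at least 2 subtype signatures.")
  if (delta_cutoff < 0) abort("`delta_cutoff` must be >= 0.")
  ranked <- rank_by_median_logfc(x, sample, pseudocount = pseudocount)
  sizes <- vapply(signatures, function(g) sum(ranked$gene %in% g), integer(1))
  too_small <- sizes < min_set_size
  if (any(too_small)) {
    abort(paste0("signature unusable (too small after intersection): ",
                 paste(names(signatures)[too_small], collapse = ", ")))
  }
  run <- function() {
    nulls <- lapply(unique(sizes), function(k) {
      perm_null_es(ranked, k, weight_p = weight_p, n_perm = n_perm)
    })
    names(nulls) <- as.character(unique(sizes))
    vapply(names(signatures), function(nm) {
      normalized_enrichment(ranked, signatures[[nm]], weight_p = weight_p,
                            min_set_size = min_set_size,
                            null_es = nulls[[as.character(sizes[[nm]])]])$nes
    }, numeric(1))
  }
  nes <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  .call_from_nes(sample, nes, delta_cutoff)
}

# Deterministic per-sample seed: mixes the cohort seed with a hash of the
# sample identifier so results do not depend on column order. NULL passes
# through (no seeding).
.sample_seed <- function(seed, sample_id) {
  if (is.null(seed)) return(NULL)
  bytes <- utf8ToInt(sample_id)
  h <- sum(bytes * seq_along(bytes)) %% 104729L
  as.integer((as.numeric(seed) * 104729 + h) %% 2147483629)
}

# Assemble a one-row call tibble from a named NES vector. Ties in the
# argmax resolve to the alphabetically first subtype.
.call_from_nes <- function(sample, nes, delta_cutoff) {
  ord <- order(-nes, names(nes), method = "radix")
  top <- names(nes)[ord[1L]]
  delta <- unname(nes[ord[1L]] - nes[ord[2L]])
  ambiguous <- delta < delta_cutoff
  excluded <- ambiguous || nes[[ord[1L]]] <= 0
  out <- tibble(sample_id = sample)
  for (nm in names(nes)) out[[paste0("nes_", nm)]] <- unname(nes[[nm]])
  out$top_subtype <- if (excluded) "unclassified" else top
  out$delta_nes <- unname(delta)
  out$ambiguous <- ambiguous
  out$excluded <- excluded
  out
}

#' Classify a whole cohort
#'
#' Runs [classify_sample()] over every column of the matrix. Per-sample
#' failures (degenerate rankings, undefined NES) do not abort the cohort:
#' the sample is recorded as excluded with the error message in `reason`.
#'
#' @inheritParams classify_sample
#' @return A `cohort_classification`: list with `calls` (one row per
#'   sample), `summary` (counts and frequencies per label, including
#'   "unclassified"), and the parameters used. `tidy()` returns the calls,
#'   `glance()` the summary.
#' @examples
#' sim <- simulate_subtype_cohort(n_per_subtype = c(C1 = 4, C5 = 4),
#'                                n_genes = 150, signature_size = 20, seed = 1)
#' cc <- classify_cohort(sim$matrix, sim$signatures[c("C1", "C5")],
#'                       n_perm = 100, seed = 1)
#' glance(cc)
#' @export
classify_cohort <- function(x, signatures, delta_cutoff = 0.4, weight_p = 1,
                            n_perm = 1000, min_set_size = 5, pseudocount = 1,
                            seed = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  samples <- colnames(x)
  # Per-sample seeds are derived from (seed, sample_id), so the cohort
  # result is a pure function of the inputs and invariant to column order.
  calls <- purrr::map(samples, function(s) {
    tryCatch(
      classify_sample(x, s, signatures, delta_cutoff = delta_cutoff,
                      weight_p = weight_p, n_perm = n_perm,
                      min_set_size = min_set_size, pseudocount = pseudocount,
                      seed = .sample_seed(seed, s)) |>
        dplyr::mutate(reason = NA_character_),
      error = function(e) {
        tibble(sample_id = s, top_subtype = "unclassified",
               delta_nes = NA_real_, ambiguous = NA, excluded = TRUE,
               reason = conditionMessage(e))
      }
    )
  }) |> purrr::list_rbind()
  labels <- c(names(signatures), "unclassified")
  summary <- tibble(label = labels) |>
    dplyr::mutate(
      count = vapply(labels, function(l) sum(calls$top_subtype == l), integer(1)),
      frequency = .data$count / nrow(calls)
    )
  structure(
    list(calls = calls, summary = summary,
         parameters = list(delta_cutoff = delta_cutoff, weight_p = weight_p,
                           n_perm = n_perm, min_set_size = min_set_size,
                           pseudocount = pseudocount, seed = seed)),
    class = "cohort_classification"
  )
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("<cohort_classification> %d samples, delta-NES cutoff %.2f\n",
              nrow(x$calls), x$parameters$delta_cutoff))
  print(x$summary)
  invisible(x)
}

#' @rdname classify_cohort
#' @param x A `cohort_classification`.
#' @param ... Unused.
#' @export
tidy.cohort_classification <- function(x, ...) x$calls

#' @rdname classify_cohort
#' @export
glance.cohort_classification <- function(x, ...) x$summary

#' Re-apply a delta-NES ambiguity cutoff to existing calls
#'
#' The NES matrix is the expensive part of a cohort classification; the
#' ambiguity filter is pure arithmetic on it. This recomputes
#' `top_subtype`, `ambiguous` and `excluded` from the stored per-subtype
#' NES columns under a new cutoff, without re-running GSEA. Samples that
#' failed outright (no NES) remain excluded.
#'
#' @param classification A `cohort_classification` from [classify_cohort()].
#' @param delta_cutoff New ambiguity cutoff (>= 0).
#' @return A `cohort_classification` with updated calls and summary.
#' @export
apply_delta_cutoff <- function(classification, delta_cutoff) {
  stopifnot(inherits(classification, "cohort_classification"))
  if (delta_cutoff < 0) abort("`delta_cutoff` must be >= 0.")
  calls <- classification$calls
  nes_cols <- grep("^nes_", names(calls), value = TRUE)
  if (length(nes_cols) < 2L) abort("calls carry fewer than 2 NES columns.")
  subtypes <- sub("^nes_", "", nes_cols)
  redone <- purrr::map(seq_len(nrow(calls)), function(i) {
    nes <- unlist(calls[i, nes_cols])
    if (anyNA(nes)) {
      return(calls[i, ])
    }
    names(nes) <- subtypes
    out <- .call_from_nes(calls$sample_id[i], nes, delta_cutoff)
    out$reason <- calls$reason[i]
    out
  }) |> purrr::list_rbind()
  labels <- c(subtypes, "unclassified")
  summary <- tibble(label = labels) |>
    dplyr::mutate(
      count = vapply(labels, function(l) sum(redone$top_subtype == l), integer(1)),
      frequency = .data$count / nrow(redone)
    )
  out <- classification
  out$calls <- redone
  out$summary <- summary
  out$parameters$delta_cutoff <- delta_cutoff
  out
}

#' Rank samples by NES over target gene sets
#'
#' Scores every sample against each target set (single-sample preranked
#' GSEA) and orders samples by composite rank: the mean of the per-set rank
#' positions (rank 1 = highest NES), ties broken by sample identifier.
#' Used to prioritize cell lines by target-signature enrichment.
#'
#' @inheritParams classify_cohort
#' @param target_sets A [gene_sets()] collection.
#' @return A tibble ordered by `composite_rank`: `sample_id`, one
#'   `nes_<set>` column per target set, `composite_rank`.
#' @export
rank_samples_by_target_nes <- function(x, target_sets, weight_p = 1,
                                       n_perm = 1000, min_set_size = 5,
                                       pseudocount = 1, seed = NULL) {
  stopifnot(inherits(x, "expr_matrix"), inherits(target_sets, "gene_set_collection"))
  if (ncol(x) < 3L) abort("ranking needs at least 3 samples.")
  samples <- colnames(x)
  per_sample <- function(s) {
    ranked <- rank_by_median_logfc(x, s, pseudocount = pseudocount)
    sizes <- vapply(target_sets, function(g) sum(ranked$gene %in% g), integer(1))
    nulls <- lapply(unique(sizes), function(k) {
      perm_null_es(ranked, k, weight_p = weight_p, n_perm = n_perm)
    })
    names(nulls) <- as.character(unique(sizes))
    out <- tibble(sample_id = s)
    for (nm in names(target_sets)) {
      out[[paste0("nes_", nm)]] <- normalized_enrichment(
        ranked, target_sets[[nm]], weight_p = weight_p,
        min_set_size = min_set_size,
        null_es = nulls[[as.character(sizes[[nm]])]])$nes
    }
    out
  }
  tab <- purrr::map(samples, function(s) {
    sseed <- .sample_seed(seed, s)
    if (is.null(sseed)) per_sample(s) else withr::with_seed(sseed, per_sample(s))
  }) |> purrr::list_rbind()
  nes_cols <- paste0("nes_", names(target_sets))
  pos <- vapply(nes_cols, function(cl) rank(-tab[[cl]], ties.method = "average"),
                numeric(nrow(tab)))
  tab$composite_rank <- rowMeans(matrix(pos, nrow = nrow(tab)))
  dplyr::arrange(tab, .data$composite_rank, .data$sample_id)
}
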