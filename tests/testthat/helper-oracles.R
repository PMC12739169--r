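# Independent oracles used across the suite. Each recomputes the target
# quantity by explicit, unoptimized loops so it shares no code path with
# the implementation it checks.

# Naive weighted running-sum enrichment score: walk the list one gene at a
# time.
naive_es <- function(genes, scores, set, p = 1) {
  n <- length(genes)
  hit <- genes %in% set
  k <- sum(hit)
  w <- abs(scores)^p
  sw <- sum(w[hit])
  cur <- 0
  run <- numeric(n)
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) w[i] / sw else -1 / (n - k)
    run[i] <- cur
  }
  mx <- max(run)
  mn <- min(run)
  # same near-tie convention as the package: positive wins a tied deviation
  list(es = if (mx + mn >= -1e-9) mx else mn, run = run)
}

# Brute-force AUC over all (positive, negative) pairs, ties counting 1/2.
pairwise_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# Random ranked list with unique scores, sorted descending.
random_ranked <- function(n, prefix = "g") {
  tibble::tibble(
    gene = sprintf("%s%05d", prefix, seq_len(n)),
    score = sort(rnorm(n), decreasing = TRUE)
  )
}

# A small expression matrix with known values.
toy_matrix <- function(vals, genes = NULL, samples = NULL, scale = "linear") {
  m <- as.matrix(vals)
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  expr_matrix(m, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
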