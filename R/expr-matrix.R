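#' Expression matrix container
#'
#' A genes-by-samples numeric matrix carrying an explicit expression scale.
#' The scale is declared by the caller, never sniffed from the values:
#' downstream log-fold-change ranking silently corrupts if a log2 matrix is
#' treated as linear, so the contract is explicit.
#'
#' @param x Numeric matrix (genes in rows, samples in columns) with unique,
#'   non-empty rownames (gene identifiers, case-sensitive) and colnames
#'   (sample identifiers).
#' @param scale One of `"linear"` (counts/TPM-like, values must be >= 0),
#'   `"log2"`, or `"zscore"` (produced by [zscore_transform()]).
#'
#' @return An `expr_matrix`: the input matrix with a `scale` attribute.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expr_matrix(m, scale = "linear")
#' @export
expr_matrix <- function(x, scale = c("linear", "log2", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix (genes x samples).")
  }
  if (nrow(x) < 2L || ncol(x) < 1L) {
    abort("expression matrix needs at least 2 genes and 1 sample.")
  }
  gid <- rownames(x)
  sid <- colnames(x)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid))) {
    abort("expression matrix needs non-empty row (gene) and column (sample) names.")
  }
  if (anyDuplicated(gid)) {
    abort(paste0("duplicate gene identifier: ",
                 paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    abort(paste0("duplicate sample identifier: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  if (any(!is.finite(x))) abort("expression values must all be finite.")
  if (scale == "linear" && any(x < 0)) {
    abort("scale violation: negative values are not allowed on the linear scale.")
  }
  structure(x, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  print(head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

#' Scale of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"linear"`, `"log2"` or `"zscore"`.
#' @export
expr_scale <- function(x) attr(x, "scale", exact = TRUE)

# De-log to linear scale; identity for already-linear input.
to_linear <- function(x) {
  switch(expr_scale(x),
    linear = x,
    log2   = expr_matrix(2^unclass(x), scale = "linear"),
    abort("cannot convert a z-scored matrix back to the linear scale.")
  )
}

#' Read an expression matrix from TSV
#'
#' Expects UTF-8 tab-separated text: first column gene identifiers (header
#' `gene_id` by convention), remaining columns one per sample, numeric body.
#' Row and column order are preserved from the file.
#'
#' @param path Path to the TSV file.
#' @param scale Declared scale of the stored values ("linear" or "log2").
#' @return An [expr_matrix()].
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L) abort("expression TSV needs a gene column plus >= 1 sample column.")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene \"", genes[duplicated(genes)][1L], "\" in ", path))
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("parse error: non-numeric value \"%s\" at gene %s, sample %s",
                  body[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                  colnames(body)[bad[1L, 2L]]))
  }
  if (anyNA(vals)) abort("parse error: missing values are not supported.")
  dimnames(vals) <- list(genes, colnames(df)[-1L])
  expr_matrix(vals, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Full double precision is retained so that write-then-read round-trips
#' reproduce every value.
#'
#' @param x An [expr_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- tibble::as_tibble(unclass(x), rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Per-gene z-score transformation
#'
#' Standardizes each gene across samples: z = (x - mean) / sd, with the
#' sample standard deviation (denominator n - 1). Genes with zero variance
#' carry no ranking information and are dropped with a warning that lists
#' them.
#'
#' @param x An [expr_matrix()] with at least 2 samples (any scale).
#' @return An [expr_matrix()] with `scale = "zscore"`; dropped constant genes
#'   are recorded in the `dropped_genes` attribute.
#' @examples
#' m <- expr_matrix(matrix(c(1, 2, 3, 4, 6, 8), nrow = 2, byrow = TRUE,
#'                  dimnames = list(c("A", "B"), c("s1", "s2", "s3"))), "linear")
#' zscore_transform(m)
#' @export
zscore_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x) < 2L) abort("z-scoring needs at least 2 samples.")
  v <- unclass(x)
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  const <- s <= .eps
  if (all(const)) abort("no variable genes: every gene is constant across samples.")
  if (any(const)) {
    warn(paste0("dropping ", sum(const), " constant gene(s): ",
                paste(rownames(v)[const], collapse = ", ")))
  }
  z <- (v[!const, , drop = FALSE] - mu[!const]) / s[!const]
  out <- expr_matrix(z, scale = "zscore")
  attr(out, "dropped_genes") <- rownames(v)[const]
  out
}
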