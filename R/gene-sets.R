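#' Gene set collections
#'
#' Following the convention of GSEA tooling, a collection is a named list of
#' character vectors (one per set) with a parallel `descriptions` attribute.
#' Gene identifiers are matched case-sensitively throughout the package and
#' never auto-mapped across species; supply murine panels as separate sets.
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional character vector, one description per set.
#' @return A `gene_set_collection`.
#' @examples
#' gene_sets(list(RBP8 = c("IGF2BP1", "LIN28B"), MHC1 = c("HLA-A", "HLA-B")))
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || length(sets) == 0L) abort("`sets` must be a non-empty named list.")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) abort("every gene set needs a name.")
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set \"", nm[duplicated(nm)][1L], "\""))
  }
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (length(g) == 0L) abort("gene sets must be non-empty.")
    unique(g)
  })
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets)) {
    abort("`descriptions` must have one entry per set.")
  }
  structure(sets, descriptions = setNames(as.character(descriptions), nm),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s)\n", length(x)))
  for (nm in head(names(x), 10L)) {
    cat(sprintf("  %s (%d genes): %s%s\n", nm, length(x[[nm]]),
                paste(head(x[[nm]], 5L), collapse = ", "),
                if (length(x[[nm]]) > 5L) ", ..." else ""))
  }
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_sets(unclass(x)[i], descriptions = attr(x, "descriptions")[i])
}

#' @rdname gene_sets
#' @param x A `gene_set_collection`.
#' @param ... Unused.
#' @export
tidy.gene_set_collection <- function(x, ...) {
  desc <- attr(x, "descriptions")
  purrr::imap(unclass(x), function(g, nm) {
    tibble(set = nm, description = desc[[nm]], gene = g)
  }) |>
    purrr::list_rbind()
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name TAB description TAB gene1 TAB gene2 ...`. Duplicate genes within a
#' line are collapsed with a warning; duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty GMT file.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  desc <- character(length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    f <- f[nzchar(f) | seq_along(f) <= 2L]   # trailing empty gene fields are noise
    if (length(f) < 3L) abort(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    genes <- f[-c(1L, 2L)]
    if (anyDuplicated(genes)) {
      warn(sprintf("GMT set \"%s\": %d duplicate gene entr%s collapsed",
                   f[1L], sum(duplicated(genes)),
                   if (sum(duplicated(genes)) == 1L) "y" else "ies"))
      genes <- unique(genes)
    }
    nms[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate set \"", nms[duplicated(nms)][1L], "\" in ", path))
  }
  gene_sets(setNames(sets, nms), descriptions = desc)
}

#' Write gene sets to a GMT file
#'
#' @param x A [gene_sets()] collection.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  desc <- attr(x, "descriptions")
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, desc[[nm]], x[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
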