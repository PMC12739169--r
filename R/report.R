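#' Analysis report container
#'
#' A lightweight record of a computation: package version, RNG seed (if
#' any), the parameter map and the result map. Serializes to JSON without
#' loss (full double precision) and to a flat two-column TSV.
#'
#' @param results Named list of result values (numbers, strings, or nested
#'   named lists).
#' @param parameters Named list of parameters the computation used.
#' @param seed Integer seed used for any randomized step, or `NULL`.
#' @return An `analysis_report`.
#' @examples
#' r <- analysis_report(results = list(CI = 0.64), parameters = list(b = 5))
#' @export
analysis_report <- function(results = list(), parameters = list(), seed = NULL) {
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(
      tool_version = as.character(utils::packageVersion("ovasig")),
      seed = seed,
      parameters = parameters,
      results = results
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> ovasig %s, seed = %s\n", x$tool_version,
              if (is.null(x$seed)) "none" else x$seed))
  cat(" results:", paste(names(x$results), collapse = ", "), "\n")
  invisible(x)
}

#' Write an analysis report
#'
#' JSON is the canonical schema (numbers written at full precision, so a
#' read-back reproduces them beyond 12 significant digits). TSV flattens the
#' result keys to `key<TAB>value` rows for spreadsheet use.
#'
#' @param report An [analysis_report()].
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = "json") {
  stopifnot(inherits(report, "analysis_report"))
  if (!format %in% c("json", "tsv")) {
    abort(paste0("unsupported format \"", format, "\" (use \"json\" or \"tsv\")"))
  }
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else {
    flat <- .flatten_map(report$results)
    df <- tibble(key = names(flat),
                 value = vapply(flat, function(v) format(v, digits = 15L), character(1)))
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return An [analysis_report()].
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(
    list(
      tool_version = x$tool_version,
      seed = if (is.null(x$seed)) NULL else as.integer(x$seed),
      parameters = as.list(x$parameters),
      results = as.list(x$results)
    ),
    class = "analysis_report"
  )
}

# Flatten a nested named list to dotted keys.
.flatten_map <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, .flatten_map(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}
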