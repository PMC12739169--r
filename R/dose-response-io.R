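#' Read a dose-response viability table
#'
#' CSV with header columns `drug, arm, concentration, conc_unit, viability,
#' replicate`. Viability is a fraction of the vehicle control; concentrations
#' must be positive and, within one (drug, arm) fit group, expressed in a
#' single unit.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble (one row per observation).
#' @seealso [fit_four_pl()], [simulate_dose_response()]
#' @export
read_dose_response <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    drug = readr::col_character(),
    arm = readr::col_character(),
    concentration = readr::col_character(),
    conc_unit = readr::col_character(),
    viability = readr::col_character(),
    replicate = readr::col_character()
  ), progress = FALSE)
  need <- c("drug", "arm", "concentration", "conc_unit", "viability", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("dose-response CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      abort(sprintf("parse error: non-numeric %s \"%s\" in row %d",
                    col, df[[col]][bad[1L]], bad[1L]))
    }
    v
  }
  out <- tibble(
    drug = df$drug,
    arm = df$arm,
    concentration = num("concentration"),
    conc_unit = df$conc_unit,
    viability = num("viability"),
    replicate = as.integer(num("replicate"))
  )
  validate_dose_response(out)
}

#' Validate a dose-response table
#'
#' Checks the invariants assumed by [fit_four_pl()]: positive concentrations,
#' finite non-negative viabilities, arms limited to mono/combo, one
#' concentration unit and at least 4 distinct concentrations per
#' (drug, arm) group, replicate indices >= 1.
#'
#' @param x A data frame with the dose-response columns.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_dose_response <- function(x) {
  x <- as_tibble(x)
  if (any(!x$arm %in% c("mono", "combo"))) {
    abort("`arm` must be \"mono\" or \"combo\".")
  }
  bad <- which(!is.finite(x$concentration) | x$concentration <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("nonpositive concentration in row %d", bad[1L]))
  }
  if (any(!is.finite(x$viability) | x$viability < 0)) {
    abort("viability must be finite and >= 0.")
  }
  if (any(x$replicate < 1L)) abort("replicate indices must be >= 1.")
  chk <- x |>
    dplyr::summarise(
      n_units = dplyr::n_distinct(.data$conc_unit),
      n_conc = dplyr::n_distinct(.data$concentration),
      .by = c("drug", "arm")
    )
  mixed <- chk |> dplyr::filter(.data$n_units > 1L)
  if (nrow(mixed) > 0L) {
    abort(sprintf("unit mismatch: (%s, %s) mixes concentration units",
                  mixed$drug[1L], mixed$arm[1L]))
  }
  thin <- chk |> dplyr::filter(.data$n_conc < 4L)
  if (nrow(thin) > 0L) {
    abort(sprintf("(%s, %s) has fewer than 4 distinct concentrations",
                  thin$drug[1L], thin$arm[1L]))
  }
  x
}

#' Write a dose-response table to CSV
#'
#' @param x A dose-response tibble (see [read_dose_response()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(x, path) {
  validate_dose_response(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
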