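#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `v(c) = bottom + (top - bottom) / (1 + (c / ec50)^hill)` to the
#' viability observations of one (drug, arm) group by bounded least squares
#' on log10 concentration. Initialization is deterministic — top/bottom from
#' the extreme per-concentration means, EC50 from linear interpolation of
#' the half-range crossing, hill = 1 — and refinement uses bounded
#' Levenberg-Marquardt with no random restarts, so fits are reproducible
#' across platforms. EC50 is constrained to the tested concentration range
#' extended by one dilution step on each side.
#'
#' @param table A dose-response tibble (see [read_dose_response()]).
#' @param drug Drug name selecting the fit group.
#' @param arm `"mono"` or `"combo"`.
#' @return A `fourpl_fit`: list with `top`, `bottom`, `ec50`, `hill`,
#'   `rss`, `converged`, `conc_unit`, `drug`, `arm`, and the observations
#'   in `data`. `tidy()` gives the parameter table, `glance()` the fit
#'   summary; `predict()` evaluates the curve.
#' @examples
#' tab <- simulate_dose_response(noise_sd = 0, replicates = 1, seed = 1)
#' fit_four_pl(tab, "antibody", "mono")
#' @export
fit_four_pl <- function(table, drug, arm = c("mono", "combo")) {
  arm <- match.arg(arm)
  table <- validate_dose_response(table)
  obs <- table |> dplyr::filter(.data$drug == !!drug, .data$arm == !!arm)
  if (nrow(obs) == 0L) abort(sprintf("no observations for (%s, %s)", drug, arm))

  means <- obs |>
    dplyr::summarise(v = mean(.data$viability), .by = "concentration") |>
    dplyr::arrange(.data$concentration)
  if (diff(range(obs$viability)) <= .eps) abort("no dose response: all viabilities equal.")

  top0 <- max(means$v)
  bottom0 <- min(means$v)
  half <- (top0 + bottom0) / 2
  lc <- log10(means$concentration)

  # Half-range crossing by linear interpolation on log10 concentration;
  # non-monotone data without a crossing fall back to the geometric center.
  cross <- NULL
  for (i in seq_len(nrow(means) - 1L)) {
    v1 <- means$v[i]; v2 <- means$v[i + 1L]
    if ((v1 - half) * (v2 - half) <= 0 && v1 != v2) {
      cross <- lc[i] + (half - v1) / (v2 - v1) * (lc[i + 1L] - lc[i])
      break
    }
  }
  if (is.null(cross)) {
    warn("no half-range crossing; initializing EC50 at the geometric center of the tested range.")
    cross <- mean(range(lc))
  }

  step <- mean(diff(sort(unique(lc))))
  lo_ec <- min(lc) - step
  hi_ec <- max(lc) + step
  start <- list(top = top0, bottom = bottom0,
                logec50 = min(max(cross, lo_ec), hi_ec), hill = 1)
  lower <- c(top = bottom0, bottom = 0, logec50 = lo_ec, hill = 1e-3)
  upper <- c(top = max(top0 * 1.5, top0 + 0.1), bottom = top0,
             logec50 = hi_ec, hill = 10)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      viability ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(concentration) - logec50))),
      data = obs, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) abort(paste0("4PL fit failed: ", conditionMessage(e)))
  )
  par <- as.list(stats::coef(fit))
  if (par$bottom >= par$top) abort("no dose response: fitted bottom >= top.")
  structure(
    list(top = par$top, bottom = par$bottom, ec50 = 10^par$logec50,
         hill = par$hill, rss = sum(stats::resid(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE,
         conc_unit = obs$conc_unit[1L], drug = drug, arm = arm, data = obs),
    class = "fourpl_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit> %s (%s): EC50 = %.4g %s, hill = %.3f, top = %.3f, bottom = %.3f, rss = %.3g\n",
              x$drug, x$arm, x$ec50, x$conc_unit, x$hill, x$top, x$bottom, x$rss))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, concentration, ...) {
  four_pl(concentration, object$top, object$bottom, object$ec50, object$hill)
}

#' @rdname fit_four_pl
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(term = c("top", "bottom", "ec50", "hill"),
         estimate = c(x$top, x$bottom, x$ec50, x$hill))
}

#' @rdname fit_four_pl
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(drug = x$drug, arm = x$arm, ec50 = x$ec50, conc_unit = x$conc_unit,
         hill = x$hill, top = x$top, bottom = x$bottom, rss = x$rss,
         n_obs = nrow(x$data), converged = x$converged)
}

#' Combination index from EC50 values
#'
#' `CI = a/A + b/B`, where `A` and `B` are the EC50 values (or fixed dose,
#' for the partner held constant) of the single treatments and `a`, `b`
#' the corresponding values under the combination. Synergy is indicated by
#' values < 1; values > 1 indicate antagonism. The index is unit-free as
#' long as each drug's pair shares one unit, which is enforced when units
#' are supplied.
#'
#' @param A,a EC50 of drug 1 alone / in combination (same unit).
#' @param B,b EC50 or fixed dose of drug 2 alone / in combination (same
#'   unit).
#' @param unit_1,unit_2 Optional unit strings checked for within-drug
#'   consistency; each may be length 1 (shared) or 2 (mono, combo).
#' @return A `synergy_result`: `ci`, `fold_change` (A/a, the potentiation
#'   of drug 1 by the combination), `verdict`.
#' @examples
#' combination_index(A = 87.7, a = 5.3, B = 8.6, b = 5,
#'                   unit_1 = "ng/mL", unit_2 = "uM")
#' @export
combination_index <- function(A, a, B, b, unit_1 = NULL, unit_2 = NULL) {
  for (u in list(unit_1, unit_2)) {
    if (!is.null(u) && length(unique(u)) > 1L) {
      abort("unit mismatch: a drug's mono and combination values must share one unit.")
    }
  }
  vals <- c(A = A, a = a, B = B, b = b)
  if (any(!is.finite(vals) | vals <= 0)) abort("invalid EC50/dose: all inputs must be > 0.")
  ci <- a / A + b / B
  structure(
    list(ci = ci, cdi = NULL, fold_change = A / a, verdict = .synergy_verdict(ci)),
    class = "synergy_result"
  )
}

#' Coefficient of drug interaction from viabilities
#'
#' `CDI = AB / (A x B)`, where `A` and `B` are the viabilities (fractions
#' of control) under each single treatment and `AB` the viability of the
#' combination at the same concentrations. CDI = 1 is the
#' Bliss-independence expectation; values < 1 indicate synergy.
#'
#' @param viability_a,viability_b Single-treatment viability fractions (> 0).
#' @param viability_ab Combination-treatment viability fraction (>= 0).
#' @return A `synergy_result` with `cdi` and `verdict`.
#' @examples
#' coefficient_of_drug_interaction(0.6, 0.5, 0.15)
#' @export
coefficient_of_drug_interaction <- function(viability_a, viability_b, viability_ab) {
  if (!is.finite(viability_a) || !is.finite(viability_b) || !is.finite(viability_ab) ||
      viability_a < 0 || viability_b < 0 || viability_ab < 0) {
    abort("viabilities must be finite and >= 0.")
  }
  if (viability_a * viability_b == 0) abort("division by zero: single-treatment viabilities must be > 0.")
  cdi <- viability_ab / (viability_a * viability_b)
  structure(
    list(ci = NULL, cdi = cdi, fold_change = NULL, verdict = .synergy_verdict(cdi)),
    class = "synergy_result"
  )
}

#' EC50 fold change between monotherapy and combination
#'
#' `fold = mono_ec50 / combo_ec50` (> 1 means the combination potentiates
#' the drug). Both values must be in the same unit.
#'
#' @param mono_ec50,combo_ec50 Positive EC50 values sharing a unit.
#' @return The fold change (bare numeric).
#' @examples
#' ec50_fold_change(87.7, 5.3)   # ~17-fold potentiation
#' @export
ec50_fold_change <- function(mono_ec50, combo_ec50) {
  if (!is.finite(mono_ec50) || !is.finite(combo_ec50) ||
      mono_ec50 <= 0 || combo_ec50 <= 0) {
    abort("invalid EC50: both values must be > 0.")
  }
  mono_ec50 / combo_ec50
}

.synergy_verdict <- function(v) {
  if (v < 1) "synergy" else if (v > 1) "antagonism" else "additivity"
}

#' @export
print.synergy_result <- function(x, ...) {
  # Report-layer rounding: CI/CDI at 2 decimals, fold change to the nearest
  # integer; full precision is retained in the object.
  if (!is.null(x$ci)) {
    cat(sprintf("<synergy_result> CI = %.2f (%s), EC50 fold change = %d\n",
                x$ci, x$verdict, round(x$fold_change)))
  } else {
    cat(sprintf("<synergy_result> CDI = %.2f (%s)\n", x$cdi, x$verdict))
  }
  invisible(x)
}

#' @rdname combination_index
#' @param x A `synergy_result`.
#' @param ... Unused.
#' @export
glance.synergy_result <- function(x, ...) {
  tibble(ci = x$ci %||% NA_real_, cdi = x$cdi %||% NA_real_,
         fold_change = x$fold_change %||% NA_real_, verdict = x$verdict)
}
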