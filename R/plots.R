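#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fourpl_fit <- function(object, n_points = 200, ...) {
  rng <- range(object$data$concentration)
  grid <- tibble(
    concentration = 10^seq(log10(rng[1L]), log10(rng[2L]), length.out = n_points)
  )
  grid$viability <- predict(object, grid$concentration)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$viability)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166AC", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$ec50, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("Concentration (%s)", object$conc_unit),
                  y = "Viability (fraction of control)",
                  title = sprintf("%s (%s): EC50 = %.3g %s", object$drug,
                                  object$arm, object$ec50, object$conc_unit)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meta_result <- function(object, ...) {
  d <- tidy(object)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n, shape = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::labs(x = "Pearson r (95% CI)", y = NULL,
                  title = sprintf("Random-effects pooling (I² = %.0f%%)",
                                  object$I2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_classification <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$label, y = .data$frequency)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(x = NULL, y = "Frequency",
                  title = "Subtype call frequencies") +
    ggplot2::theme_minimal()
}
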