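#' Reliability diagram
#'
#' Plots per-bin positive-class prevalence against mean predicted
#' probability from an [ece()] result; the dashed diagonal marks perfect
#' calibration.
#'
#' @param x An `afuq_calibration` (from [ece()]) or a prediction tibble.
#' @param n_bins Bin count used when `x` is a prediction tibble.
#' @return A ggplot object.
#' @export
plot_reliability <- function(x, n_bins = 10) {
  if (!inherits(x, "afuq_calibration")) x <- ece(x, n_bins)
  d <- filter(x$bins, .data$n > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conf, y = .data$acc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), show.legend = FALSE) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability (confidence)",
                  y = "Prevalence of AF (accuracy)",
                  title = sprintf("Reliability curve (ECE = %.3f)", x$ece)) +
    ggplot2::theme_minimal()
}

#' @method autoplot afuq_calibration
#' @export
autoplot.afuq_calibration <- function(object, ...) plot_reliability(object)

#' Confidence-versus-count curve plot
#'
#' @param preds Prediction tibble (see [confidence_count_curve()]).
#' @param thresholds Threshold grid.
#' @return A ggplot object.
#' @export
plot_confidence_count <- function(preds, thresholds = seq(0, 1, by = 0.1)) {
  d <- confidence_count_curve(preds, thresholds)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Confidence threshold",
                  y = "AF samples predicted above threshold") +
    ggplot2::theme_minimal()
}

#' Uncertainty density plot by segment group
#'
#' Density comparison of per-segment uncertainty estimates between clean,
#' noisy and OOD segments.
#'
#' @param preds Prediction tibble from [batch_uncertainty()].
#' @return A ggplot object.
#' @export
plot_uncertainty_density <- function(preds) {
  d <- mutate(preds, group = dplyr::case_when(
    .data$ood ~ "OOD (abstain)",
    .data$noisy ~ "noisy",
    TRUE ~ "clean"
  ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$uncertainty, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "Uncertainty (sd of predicted probability)",
                  y = "Density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Uncertainty-versus-confidence scatter plot
#'
#' @param preds Prediction tibble from [batch_uncertainty()].
#' @return A ggplot object.
#' @export
plot_uncertainty_confidence <- function(preds) {
  d <- mutate(preds, group = dplyr::case_when(
    .data$ood ~ "OOD (abstain)",
    .data$y_true %in% 1 ~ "AF",
    TRUE ~ "sinus"
  ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p, y = .data$uncertainty,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "Mean predicted probability of AF",
                  y = "Uncertainty (sd)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot af_classifier
#' @export
autoplot.af_classifier <- function(object, ...) {
  h <- tidy(object)
  d <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Binary cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot af_experiment
#' @export
autoplot.af_experiment <- function(object, ...) {
  bins <- purrr::imap_dfr(object$predictions, function(preds, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    b <- filter(ece(preds)$bins, .data$n > 0)
    b$model <- parts[1]
    b$uncertainty <- parts[2]
    b
  })
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$conf, y = .data$acc,
                                     colour = .data$uncertainty)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$model) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Confidence", y = "AF prevalence") +
    ggplot2::theme_minimal()
}
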