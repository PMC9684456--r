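#' Uncertainty estimation configuration
#'
#' Configures how predictive uncertainty is sampled: `"none"` is the
#' always-confident single deterministic pass (uncertainty defined as 0);
#' `"epistemic"` is Monte Carlo dropout (T dropout-active passes on the
#' unaugmented input); `"aleatoric"` is test-time augmentation (T
#' dropout-inactive passes on independently masked views of the input,
#' 10% random masking by default); `"combined"` draws both sources jointly
#' (each pass uses an independent masked view with dropout active).
#'
#' @param mode One of `"none"`, `"epistemic"`, `"aleatoric"`, `"combined"`.
#' @param n_passes Number of stochastic passes T (>= 2 for any mode other
#'   than `"none"`).
#' @param mask_fraction Fraction of time points zeroed per augmented view.
#' @param seed Integer seed.
#' @return An `uncertainty_config` list.
#' @export
uncertainty_config <- function(mode = c("none", "epistemic", "aleatoric", "combined"),
                               n_passes = 30, mask_fraction = 0.10, seed = 1) {
  mode <- match.arg(mode)
  check_number(n_passes, "n_passes", 1, Inf)
  if (mask_fraction < 0 || mask_fraction >= 1) {
    abort("`mask_fraction` must be in [0, 1).", class = "afuq_config_error")
  }
  if (mode != "none" && n_passes < 2) {
    abort("`n_passes` must be >= 2 for stochastic uncertainty modes.",
          class = "afuq_config_error")
  }
  structure(list(mode = mode, n_passes = as.integer(n_passes),
                 mask_fraction = mask_fraction, seed = as.integer(seed)),
            class = "uncertainty_config")
}

#' Randomly mask a fraction of time points in a signal
#'
#' Zeroes exactly `round(fraction * samples)` time points, drawn uniformly
#' without replacement; the same positions are zeroed across all leads, so
#' the input length is preserved. This is the test-time augmentation used
#' for aleatoric uncertainty estimation.
#'
#' @param signal Leads x samples matrix.
#' @param fraction Fraction of time points to mask, in \[0, 1).
#' @param seed Integer seed making the mask deterministic.
#' @return The masked signal matrix.
#' @export
mask_augment <- function(signal, fraction, seed = NULL) {
  if (!is.matrix(signal)) abort("`signal` must be a leads x samples matrix.")
  if (fraction < 0 || fraction >= 1) {
    abort("`fraction` must be in [0, 1).", class = "afuq_parameter_error")
  }
  n_mask <- round(fraction * ncol(signal))
  if (n_mask == 0) return(signal)
  with_seed(seed, {
    signal[, sample.int(ncol(signal), n_mask)] <- 0
    signal
  })
}

new_predictive_dist <- function(samples, mode) {
  structure(
    list(samples = samples, mean = mean(samples),
         std = if (length(samples) > 1) sd(samples) else 0,
         mode = mode),
    class = "predictive_dist"
  )
}

#' @export
print.predictive_dist <- function(x, ...) {
  cat(sprintf("<predictive_dist> mode=%s T=%d mean=%.4f std=%.4f\n",
              x$mode, length(x$samples), x$mean, x$std))
  invisible(x)
}

#' Predictive distribution for one segment
#'
#' Samples the model's predictive distribution for a single segment under
#' the configured uncertainty mode and summarises it by the mean predicted
#' probability (used for classification) and the sample standard deviation
#' (the uncertainty estimate). Reproducible given `config$seed`.
#'
#' @param model A trained `af_classifier`.
#' @param segment An `ecg_segment`, a leads x samples matrix, or a one-row
#'   cohort tibble.
#' @param config An [uncertainty_config()].
#' @return A `predictive_dist` with fields `samples`, `mean`, `std`, `mode`.
#' @export
predict_with_uncertainty <- function(model, segment,
                                     config = uncertainty_config("combined")) {
  sig <- if (inherits(segment, "ecg_segment")) {
    segment$signal
  } else if (is.data.frame(segment)) segment$signal[[1]] else segment
  if (config$mode == "none") {
    p <- predict(model, sig, dropout_active = FALSE)
    return(new_predictive_dist(p, "none"))
  }
  with_seed(config$seed, {
    samples <- vapply(seq_len(config$n_passes), function(t) {
      x <- if (config$mode %in% c("aleatoric", "combined")) {
        mask_augment(sig, config$mask_fraction, seed = NULL)
      } else sig
      drop_on <- config$mode %in% c("epistemic", "combined")
      predict_signals(model, list(x),
                      mode = if (drop_on) "mc" else "eval", seed = NULL)
    }, numeric(1))
    new_predictive_dist(samples, config$mode)
  })
}

#' Batched uncertainty estimation over a cohort
#'
#' Applies the configured uncertainty mode to every segment of a cohort and
#' returns a prediction-set tibble for downstream evaluation. Segments are
#' processed in batched stochastic passes (each pass draws an independent
#' dropout mask elementwise and an independent masked view per segment), so
#' results for the whole cohort are reproducible from the single master
#' seed in `config`. The cohort's `y_true`, `noisy` and `ood` flags are
#' carried through for grouping.
#'
#' @param model A trained `af_classifier`.
#' @param cohort Cohort tibble with a `signal` list-column.
#' @param config An [uncertainty_config()].
#' @return A tibble with one row per segment: `segment_id`, `p` (mean
#'   predicted probability of AF), `uncertainty` (sample standard
#'   deviation; 0 in mode `"none"`), `mode`, `n_passes`, plus `y_true`,
#'   `noisy` and `ood` when present in the cohort.
#' @export
batch_uncertainty <- function(model, cohort,
                              config = uncertainty_config("combined")) {
  if (nrow(cohort) == 0) abort("`cohort` must be non-empty.",
                               class = "afuq_parameter_error")
  n <- nrow(cohort)
  if (config$mode == "none") {
    p_mean <- predict(model, cohort, dropout_active = FALSE)
    p_sd <- rep(0, n)
    n_passes <- 1L
  } else {
    acc <- matrix(0, n, config$n_passes)
    with_seed(config$seed, {
      for (t in seq_len(config$n_passes)) {
        sigs <- cohort$signal
        if (config$mode %in% c("aleatoric", "combined")) {
          sigs <- lapply(sigs, mask_augment, fraction = config$mask_fraction,
                         seed = NULL)
        }
        drop_on <- config$mode %in% c("epistemic", "combined")
        acc[, t] <- predict_signals(model, sigs,
                                    mode = if (drop_on) "mc" else "eval",
                                    seed = NULL)
      }
    })
    p_mean <- rowMeans(acc)
    p_sd <- apply(acc, 1, sd)
    n_passes <- config$n_passes
  }
  out <- tibble(
    segment_id = cohort$segment_id %||% sprintf("S%05d", seq_len(n)),
    p = p_mean, uncertainty = p_sd,
    mode = config$mode, n_passes = n_passes
  )
  for (col in c("y_true", "noisy", "ood", "true_rhythm")) {
    if (!is.null(cohort[[col]])) out[[col]] <- cohort[[col]]
  }
  out
}
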