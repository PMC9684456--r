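#' Map source rhythm class names to the binary AF task
#'
#' Maps annotation classes from a 12-lead diagnostic ECG source to the
#' binary task: the sinus family (Sinus Bradycardia, Sinus Rhythm, Sinus
#' Irregularity) maps to 0, the atrial family (Atrial Flutter, Atrial
#' Fibrillation) maps to 1, and every other class is excluded (`NA`).
#' Matching is case-insensitive on the trimmed class name.
#'
#' @param source_label Character vector of rhythm class names.
#' @return Integer vector: 0, 1 or `NA` (excluded).
#' @export
map_rhythm_classes <- function(source_label) {
  key <- tolower(trimws(as.character(source_label)))
  sinus <- c("sinus bradycardia", "sinus rhythm", "sinus irregularity")
  af <- c("atrial flutter", "atrial fibrillation")
  out <- rep(NA_integer_, length(key))
  out[key %in% sinus] <- 0L
  out[key %in% af] <- 1L
  out
}

#' Resample a multi-lead signal to a new sampling rate
#'
#' Rate conversion by zero-phase low-pass filtering (8th-order Butterworth
#' run forward and backward with [signal::filtfilt()], cutoff at 0.45 of
#' the target rate) followed by spline interpolation onto the new time
#' grid. The anti-aliasing filter is applied only when down-sampling.
#' Output length is `round(samples * fs_out / fs_in)`, e.g. 10 s at 500 Hz
#' (5000 samples) down-samples to 2400 samples at 240 Hz.
#'
#' @param x Numeric vector or leads x samples matrix.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Resampled vector or matrix with the same number of leads.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  check_number(fs_in, "fs_in", 1e-9, Inf)
  check_number(fs_out, "fs_out", 1e-9, Inf)
  mat <- is.matrix(x)
  xm <- if (mat) x else matrix(x, nrow = 1)
  if (any(!is.finite(xm))) {
    abort("`x` must be finite.", class = "afuq_parameter_error")
  }
  n_in <- ncol(xm)
  n_out <- round(n_in * fs_out / fs_in)
  if (fs_out == fs_in) return(x)
  t_in <- (seq_len(n_in) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  # order 4: higher-order transfer-function Butterworths are numerically
  # ill-conditioned (DC gain error ~1e-5 at order 8)
  lp <- if (fs_out < fs_in) signal::butter(4, 0.45 * fs_out / (fs_in / 2)) else NULL
  out <- matrix(0, nrow(xm), n_out)
  # odd-reflection padding suppresses the zero-initial-condition edge
  # transients of filtfilt; the pad is discarded after filtering
  pad <- min(n_in - 1L, 48L)
  for (l in seq_len(nrow(xm))) {
    xi <- xm[l, ]
    if (!is.null(lp) && n_in > 24) {
      xp <- c(2 * xi[1] - rev(xi[2:(pad + 1)]),
              xi,
              2 * xi[n_in] - rev(xi[(n_in - pad):(n_in - 1)]))
      xi <- signal::filtfilt(lp, xp)[(pad + 1):(pad + n_in)]
    }
    out[l, ] <- stats::spline(t_in, xi, xout = t_out)$y
  }
  if (mat) out else out[1, ]
}

#' Per-patient segment cap from the boxplot upper whisker
#'
#' Computes the cap on segments per patient as the upper whisker of a
#' boxplot of the per-patient count distribution: Q3 + 1.5 * IQR, with
#' quartiles by linear interpolation between order statistics (R's default
#' type-7 convention), rounded down to an integer.
#'
#' @param per_patient_counts Non-empty vector of per-patient segment counts.
#' @return Integer cap.
#' @export
compute_patient_cap <- function(per_patient_counts) {
  if (length(per_patient_counts) == 0 || !is.numeric(per_patient_counts)) {
    abort("`per_patient_counts` must be a non-empty numeric vector.",
          class = "afuq_parameter_error")
  }
  q <- unname(quantile(per_patient_counts, c(0.25, 0.75), type = 7))
  as.integer(floor(q[2] + 1.5 * (q[2] - q[1])))
}

#' Curation rules for a segment index
#'
#' @param min_spacing Minimum spacing (s) between a patient's retained
#'   segments (default one hour).
#' @param max_initial_per_patient Hard initial cap on segments per patient.
#' @param reject_dropoff Drop segments with any sensor drop-off.
#' @param apply_whisker_cap Apply the boxplot-upper-whisker per-patient cap
#'   ([compute_patient_cap()]) after the other filters.
#' @return A `curation_rules` list.
#' @export
curation_rules <- function(min_spacing = 3600, max_initial_per_patient = 1000,
                           reject_dropoff = TRUE, apply_whisker_cap = TRUE) {
  check_number(min_spacing, "min_spacing", 1e-9, Inf)
  check_number(max_initial_per_patient, "max_initial_per_patient", 1, Inf)
  structure(list(min_spacing = min_spacing,
                 max_initial_per_patient = as.integer(max_initial_per_patient),
                 reject_dropoff = isTRUE(reject_dropoff),
                 apply_whisker_cap = isTRUE(apply_whisker_cap)),
            class = "curation_rules")
}

#' Curate a segment index
#'
#' Applies the cohort curation filters in order: (1) reject segments with
#' sensor drop-off; (2) per patient, enforce the minimum spacing between
#' segments greedily in time order (keep the first, drop any segment closer
#' than `min_spacing` to the last kept one); (3) truncate each patient to
#' the initial per-patient maximum; (4) cap every patient at the boxplot
#' upper whisker of the post-filter per-patient count distribution. The
#' result is always a subset of the input, and the operation is idempotent.
#'
#' @param index A tibble with at least `patient_id` and `timestamp`
#'   columns; a `dropoff` column is used when present.
#' @param rules A [curation_rules()].
#' @return The curated tibble (same columns, subset of rows).
#' @export
curate_segments <- function(index, rules = curation_rules()) {
  if (!is.data.frame(index)) abort("`index` must be a data frame.")
  if (nrow(index) == 0) return(index)
  out <- index
  if (rules$reject_dropoff && "dropoff" %in% names(out)) {
    out <- filter(out, !.data$dropoff)
  }
  if (nrow(out) == 0) return(out)
  out <- out |>
    group_by(.data$patient_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    filter(keep_spaced(.data$timestamp, rules$min_spacing)) |>
    slice_head(n = rules$max_initial_per_patient) |>
    ungroup()
  if (rules$apply_whisker_cap && nrow(out) > 0) {
    counts <- dplyr::count(out, .data$patient_id)$n
    cap <- compute_patient_cap(counts)
    out <- out |>
      group_by(.data$patient_id) |>
      arrange(.data$timestamp, .by_group = TRUE) |>
      slice_head(n = cap) |>
      ungroup()
  }
  out
}

# Greedy minimum-spacing filter over sorted timestamps: keep the first
# segment, then each segment at least `min_spacing` after the last kept.
keep_spaced <- function(ts, min_spacing) {
  keep <- logical(length(ts))
  last <- -Inf
  for (i in seq_along(ts)) {
    if (ts[i] - last >= min_spacing || is.infinite(last)) {
      keep[i] <- TRUE
      last <- ts[i]
    }
  }
  keep
}

#' Assign weak labels to an unlabelled pool with a surrogate model
#'
#' Runs the trained surrogate classifier (dropout inactive, deterministic)
#' on every segment of the pool and stores both the predicted probability
#' of AF and the thresholded hard label. A probability strictly greater
#' than `threshold` yields the AF label 1; a tie at the threshold resolves
#' to sinus rhythm (the conservative negative default). The resulting
#' labels are "weak": generated by a model, never verified by a human.
#'
#' @param pool Cohort tibble with a `signal` list-column.
#' @param surrogate A trained `af_classifier`.
#' @param threshold Decision threshold on p(AF).
#' @param provenance Identifier recorded for the label source.
#' @return The pool tibble with added columns `p_weak`, `label`
#'   (hard weak label) and `provenance`.
#' @export
assign_weak_labels <- function(pool, surrogate, threshold = 0.5,
                               provenance = "surrogate") {
  if (nrow(pool) == 0) abort("`pool` must be non-empty.",
                             class = "afuq_parameter_error")
  check_fraction(threshold, "threshold")
  p <- predict(surrogate, pool, dropout_active = FALSE)
  pool$p_weak <- p
  pool$label <- as.integer(p > threshold)
  pool$provenance <- provenance
  pool
}
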