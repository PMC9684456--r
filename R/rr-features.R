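#' Detect R-peaks in an ECG signal
#'
#' Simple amplitude-threshold peak picker: local maxima above a fraction of
#' the global maximum, thinned greedily (largest first) so that retained
#' peaks are at least `min_dist` seconds apart. Operates on a single lead
#' (the first row of a matrix). Intended as a transparent rhythm oracle for
#' the synthetic generator and as a feature extractor for the RR-interval
#' baseline classifier, not as a clinical QRS detector.
#'
#' @param signal Numeric vector, or leads x samples matrix (first lead used).
#' @param fs Sampling rate in Hz.
#' @param min_dist Minimum peak separation in seconds.
#' @param rel_height Detection threshold as a fraction of the signal maximum.
#' @return Numeric vector of peak times in seconds.
#' @export
detect_r_peaks <- function(signal, fs, min_dist = 0.25, rel_height = 0.5) {
  x <- if (is.matrix(signal)) signal[1, ] else as.numeric(signal)
  n <- length(x)
  if (n < 3) return(numeric(0))
  thr <- rel_height * max(x)
  i <- 2:(n - 1)
  cand <- i[x[i] >= x[i - 1] & x[i] > x[i + 1] & x[i] > thr]
  if (length(cand) == 0) return(numeric(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  gap <- min_dist * fs
  for (c in cand) {
    if (all(abs(c - keep) >= gap)) keep <- c(keep, c)
  }
  (sort(keep) - 1) / fs
}

#' RR-interval summary features
#'
#' Detects R-peaks and summarises the beat-to-beat (RR) intervals. The RR
#' coefficient of variation is the classic hand-crafted discriminator
#' between sinus rhythm (regular) and AF (irregular).
#'
#' @inheritParams detect_r_peaks
#' @return A one-row tibble: `n_peaks`, `rr_mean`, `rr_cv` (both `NA` when
#'   fewer than 3 peaks are found).
#' @export
rr_features <- function(signal, fs, min_dist = 0.25, rel_height = 0.5) {
  pk <- detect_r_peaks(signal, fs, min_dist, rel_height)
  if (length(pk) < 3) {
    return(tibble(n_peaks = length(pk), rr_mean = NA_real_, rr_cv = NA_real_))
  }
  rr <- diff(pk)
  tibble(n_peaks = length(pk), rr_mean = mean(rr), rr_cv = sd(rr) / mean(rr))
}

#' RR-irregularity baseline classifier
#'
#' Labels each cohort segment AF when its detected RR coefficient of
#' variation exceeds `threshold`. Serves as a transparent non-neural
#' baseline and as the separability check for synthetic cohorts.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param threshold RR-CV decision threshold.
#' @return The cohort tibble with added `rr_cv` and `rr_pred` (0/1) columns;
#'   segments with too few detected peaks are predicted AF (irregular).
#' @export
classify_by_rr_cv <- function(cohort, threshold = 0.1) {
  feats <- purrr::map2_dfr(cohort$signal, cohort$fs, function(sig, fs) {
    rr_features(sig, fs)
  })
  cohort$rr_cv <- feats$rr_cv
  cohort$rr_pred <- as.integer(is.na(feats$rr_cv) | feats$rr_cv > threshold)
  cohort
}
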