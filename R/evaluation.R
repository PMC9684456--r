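#' Classification metrics at a decision threshold
#'
#' Computes F1, positive predictive value (precision), sensitivity
#' (recall) and specificity from the 2x2 confusion table of `p > threshold`
#' against the binary labels. F1 is the harmonic mean of PPV and
#' sensitivity (0 when both TP counts vanish).
#'
#' @param preds Prediction tibble with columns `p` (probability of AF) and
#'   `y_true` (0/1); rows with `NA` labels (e.g. OOD segments) are dropped.
#' @param threshold Decision threshold on `p`.
#' @return One-row tibble: `f1`, `ppv`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(preds, threshold = 0.5) {
  d <- filter(preds, !is.na(.data$y_true))
  y <- as.integer(d$y_true)
  if (!any(y == 1) || !any(y == 0)) {
    abort("Both classes must be present to compute classification metrics.",
          class = "afuq_metric_error")
  }
  yhat <- as.integer(d$p > threshold)
  tp <- sum(yhat == 1 & y == 1)
  fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1)
  tn <- sum(yhat == 0 & y == 0)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  tibble(f1 = f1, ppv = ppv, sensitivity = sens, specificity = spec)
}

#' Brier score
#'
#' Mean squared difference between the predicted probability of AF and the
#' binary label: \eqn{\frac{1}{N}\sum_i (p_i - y_i)^2}. A proper scoring
#' rule in \[0, 1\]; lower is better.
#'
#' @inheritParams classification_metrics
#' @return The Brier score (single number).
#' @export
brier <- function(preds) {
  d <- filter(preds, !is.na(.data$y_true))
  if (nrow(d) == 0) abort("`preds` must be non-empty.", class = "afuq_metric_error")
  mean((d$p - d$y_true)^2)
}

#' Negative log-likelihood
#'
#' Mean binary cross-entropy of the predicted probabilities against the
#' labels, with probabilities clamped to \[1e-7, 1 - 1e-7\] before the log
#' (the same clamping used in training). A proper scoring rule; lower is
#' better.
#'
#' @inheritParams classification_metrics
#' @return The NLL (single number).
#' @export
nll <- function(preds) {
  d <- filter(preds, !is.na(.data$y_true))
  if (nrow(d) == 0) abort("`preds` must be non-empty.", class = "afuq_metric_error")
  bce_loss(d$p, as.integer(d$y_true))
}

#' Expected calibration error and reliability-curve bins
#'
#' Partitions \[0, 1\] into `n_bins` equal-width bins (right-open except
#' the last, which is closed) and compares, in each bin, the prevalence of
#' the positive class `acc(b)` with the mean predicted probability
#' `conf(b)`:
#' \deqn{ECE = \sum_b \frac{|b|}{N} |acc(b) - conf(b)|.}
#' Empty bins contribute nothing. The returned bin table is the data behind
#' a reliability diagram.
#'
#' @inheritParams classification_metrics
#' @param n_bins Number of equal-width bins (>= 1).
#' @return An `afuq_calibration` list with elements `ece` (scalar) and
#'   `bins` (tibble: `bin`, `lower`, `upper`, `n`, `acc`, `conf`).
#' @export
ece <- function(preds, n_bins = 10) {
  check_number(n_bins, "n_bins", 1, Inf)
  n_bins <- as.integer(n_bins)
  d <- filter(preds, !is.na(.data$y_true))
  if (nrow(d) == 0) abort("`preds` must be non-empty.", class = "afuq_metric_error")
  sample_bin <- pmin(floor(d$p * n_bins) + 1L, n_bins)
  bin_n <- vapply(seq_len(n_bins), function(b) sum(sample_bin == b), integer(1))
  bin_acc <- vapply(seq_len(n_bins), function(b) {
    if (any(sample_bin == b)) mean(d$y_true[sample_bin == b]) else NA_real_
  }, numeric(1))
  bin_conf <- vapply(seq_len(n_bins), function(b) {
    if (any(sample_bin == b)) mean(d$p[sample_bin == b]) else NA_real_
  }, numeric(1))
  bins <- tibble(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) / n_bins,
    upper = seq_len(n_bins) / n_bins,
    n = bin_n,
    acc = bin_acc,
    conf = bin_conf
  )
  occ <- bins$n > 0
  value <- sum(bins$n[occ] / nrow(d) * abs(bins$acc[occ] - bins$conf[occ]))
  structure(list(ece = value, bins = bins, n = nrow(d)),
            class = "afuq_calibration")
}

#' @export
print.afuq_calibration <- function(x, ...) {
  cat(sprintf("<afuq_calibration> ECE = %.4f over %d samples, %d bins\n",
              x$ece, x$n, nrow(x$bins)))
  invisible(x)
}

#' @method tidy afuq_calibration
#' @export
tidy.afuq_calibration <- function(x, ...) x$bins

#' Confidence-versus-count curve
#'
#' For each confidence threshold, counts the positive-label (AF) samples
#' predicted with probability strictly greater than the threshold. The
#' counts are non-increasing in the threshold; a well-calibrated model
#' shows a steady decline rather than a pile-up at high confidence.
#'
#' @inheritParams classification_metrics
#' @param thresholds Grid of confidence thresholds.
#' @return Tibble with columns `threshold`, `count`.
#' @export
confidence_count_curve <- function(preds, thresholds = seq(0, 1, by = 0.1)) {
  d <- filter(preds, !is.na(.data$y_true), .data$y_true == 1)
  tibble(
    threshold = thresholds,
    count = vapply(thresholds, function(th) sum(d$p > th), numeric(1))
  )
}

#' Cohen's kappa inter-rater agreement
#'
#' Chance-corrected agreement \eqn{(p_o - p_e) / (1 - p_e)} between two
#' equal-length categorical label vectors, with expected agreement from the
#' product of the marginal label distributions.
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return Kappa (1 = perfect agreement, 0 = chance level).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0) {
    abort("`labels_a` and `labels_b` must be non-empty and equal length.",
          class = "afuq_parameter_error")
  }
  cats <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = cats)
  b <- factor(labels_b, levels = cats)
  po <- mean(a == b)
  pe <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (abs(1 - pe) < 1e-15) {
    abort("Expected agreement is 1; kappa is undefined.",
          class = "afuq_metric_error")
  }
  (po - pe) / (1 - pe)
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The U statistic counts, over all
#' pairs, how often an `x` exceeds a `y`, with half credit for ties
#' (computed via midranks). The two-tailed p-value uses the exact null
#' distribution when `n1 * n2 <= 400` and the data are tie-free, and
#' otherwise a normal approximation with tie correction (no continuity
#' correction).
#'
#' @param x,y Non-empty numeric samples.
#' @return One-row tibble: `n1`, `n2`, `u` (U statistic for `x`),
#'   `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.", class = "afuq_parameter_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)

  if (!has_ties && n1 * n2 <= 400) {
    # exact null distribution of U
    p <- if (u > n1 * n2 / 2) {
      2 * (1 - pwilcox(u - 1, n1, n2))
    } else {
      2 * pwilcox(u, n1, n2)
    }
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  tibble(n1 = n1, n2 = n2, u = u, p_value = min(1, p), method = method)
}

#' Bonferroni-Holm step-down decisions
#'
#' Controls the family-wise error rate at `alpha` by Holm's step-down
#' procedure: the ordered p-values \eqn{p_{(i)}} are compared against
#' \eqn{\alpha / (m - i + 1)}, stopping at the first failure. Decisions are
#' monotone: once one test fails, all larger p-values fail.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param alpha Family-wise significance level.
#' @return Tibble with `p_value`, `p_holm` (Holm-adjusted) and `reject`,
#'   in the input order.
#' @export
holm_correct <- function(p_values, alpha = 0.01) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("`p_values` must lie in [0, 1].", class = "afuq_parameter_error")
  }
  check_fraction(alpha, "alpha")
  adj <- p.adjust(p_values, method = "holm")
  tibble(p_value = p_values, p_holm = adj, reject = adj <= alpha)
}

#' Compare uncertainty distributions between segment groups
#'
#' Runs two-tailed Mann-Whitney U tests on the per-segment uncertainty
#' values between named groups of a prediction set, then applies
#' Bonferroni-Holm correction across the requested family of comparisons.
#' Available groupings: `clean_vs_noisy` (artifact-flag criterion),
#' `id_vs_ood` (in-distribution vs the abstain-analog class),
#' `sinus_vs_abstain` and `af_vs_abstain`. Comparisons with an empty group
#' are skipped with a message and excluded from the family.
#'
#' @param preds Prediction tibble from [batch_uncertainty()] (needs
#'   `uncertainty`, `noisy`, `ood` and, for the class groupings, `y_true`).
#' @param groupings Character vector of grouping names (family of tests).
#' @param alpha Family-wise level for the Holm correction.
#' @return Tibble with one row per performed comparison: group sizes, U,
#'   raw and Holm-adjusted p-values and the corrected `reject` decision.
#' @export
compare_uncertainty_groups <- function(preds,
                                       groupings = c("clean_vs_noisy", "id_vs_ood"),
                                       alpha = 0.01) {
  groupings <- match.arg(groupings,
                         c("clean_vs_noisy", "id_vs_ood",
                           "sinus_vs_abstain", "af_vs_abstain"),
                         several.ok = TRUE)
  pick <- function(g) {
    switch(g,
      clean_vs_noisy = list(a = preds$uncertainty[!preds$noisy & !preds$ood],
                            b = preds$uncertainty[preds$noisy & !preds$ood]),
      id_vs_ood = list(a = preds$uncertainty[!preds$ood],
                       b = preds$uncertainty[preds$ood]),
      sinus_vs_abstain = list(a = preds$uncertainty[!preds$ood & preds$y_true %in% 0],
                              b = preds$uncertainty[preds$ood]),
      af_vs_abstain = list(a = preds$uncertainty[!preds$ood & preds$y_true %in% 1],
                           b = preds$uncertainty[preds$ood])
    )
  }
  rows <- list()
  for (g in groupings) {
    gr <- pick(g)
    if (length(gr$a) == 0 || length(gr$b) == 0) {
      rlang::inform(sprintf("Skipping comparison `%s`: empty group.", g))
      next
    }
    res <- mann_whitney_u(gr$b, gr$a) # U for the putatively noisier group
    res$comparison <- g
    rows[[g]] <- res
  }
  if (!length(rows)) return(tibble())
  out <- bind_rows(rows)
  hc <- holm_correct(out$p_value, alpha)
  out$p_holm <- hc$p_holm
  out$reject <- hc$reject
  dplyr::relocate(out, "comparison")
}
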