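#' Per-class confidence thresholds
#'
#' The threshold for class *j* is the mean predicted probability of class
#' *j* over the samples whose observed label is *j*:
#' \deqn{t_j = \frac{1}{N_j} \sum_{i: \tilde y_i = j} p(\tilde y_i = j \mid x_i, \theta).}
#' Thresholds are only defined for classes with at least one observed
#' sample.
#'
#' @param probs Predicted probability of the positive class (AF), one per
#'   sample; p(class 0) is `1 - probs`.
#' @param observed Observed (possibly noisy) binary labels.
#' @return A tibble with columns `class`, `threshold`, `n`.
#' @export
class_thresholds <- function(probs, observed) {
  observed <- as.integer(observed)
  if (length(probs) != length(observed)) {
    abort("`probs` and `observed` must have equal length.",
          class = "afuq_parameter_error")
  }
  if (!all(observed %in% 0:1)) {
    abort("`observed` must be binary (0/1).", class = "afuq_parameter_error")
  }
  for (cl in 0:1) {
    if (!any(observed == cl)) {
      abort(sprintf("Class %d has no observed samples; its threshold is undefined.", cl),
            class = "afuq_threshold_error")
    }
  }
  tibble(
    class = 0:1,
    threshold = c(mean(1 - probs[observed == 0]), mean(probs[observed == 1])),
    n = c(sum(observed == 0), sum(observed == 1))
  )
}

# Confident class per sample: the argmax over classes whose predicted
# probability meets that class's threshold (ties qualify); an exact
# probability tie between two qualifying classes resolves to the observed
# label. NA when no class qualifies.
confident_class <- function(probs, observed, thresholds) {
  t0 <- thresholds$threshold[thresholds$class == 0]
  t1 <- thresholds$threshold[thresholds$class == 1]
  p0 <- 1 - probs
  q0 <- p0 >= t0
  q1 <- probs >= t1
  out <- rep(NA_integer_, length(probs))
  out[q0 & !q1] <- 0L
  out[q1 & !q0] <- 1L
  both <- q0 & q1
  out[both & (probs > p0)] <- 1L
  out[both & (probs < p0)] <- 0L
  out[both & (probs == p0)] <- as.integer(observed[both & (probs == p0)])
  out
}

#' Construct the confident joint
#'
#' Builds the 2x2 count matrix \eqn{C_{\tilde y, y^*}} linking observed
#' labels (rows) to confidently estimated true labels (columns). A sample
#' contributes to the cell of its observed label and its confident class
#' (see [class_thresholds()]); samples for which no class's probability
#' reaches its threshold are not counted, so the entries sum to at most the
#' sample count. Diagonal entries count samples whose confident class
#' agrees with the observed label; off-diagonal entries are candidate label
#' errors.
#'
#' @inheritParams class_thresholds
#' @param thresholds Output of [class_thresholds()]; computed from
#'   `probs`/`observed` when omitted.
#' @return A 2x2 integer matrix with dimnames `observed` x `estimated`.
#' @export
confident_joint <- function(probs, observed, thresholds = NULL) {
  observed <- as.integer(observed)
  thresholds <- thresholds %||% class_thresholds(probs, observed)
  est <- confident_class(probs, observed, thresholds)
  C <- matrix(0L, 2, 2,
              dimnames = list(observed = c("0", "1"), estimated = c("0", "1")))
  ok <- !is.na(est)
  for (a in 0:1) for (b in 0:1) {
    C[a + 1, b + 1] <- sum(ok & observed == a & est == b)
  }
  C
}

#' Identify likely-mislabelled samples
#'
#' Returns the indices counted off-diagonal in the confident joint: samples
#' whose confident class is defined and disagrees with their observed
#' label. The size of this set always equals the sum of the off-diagonal
#' entries of [confident_joint()] on the same inputs.
#'
#' @inheritParams confident_joint
#' @return Integer vector of flagged sample indices (possibly empty).
#' @export
identify_label_issues <- function(probs, observed, thresholds = NULL) {
  observed <- as.integer(observed)
  thresholds <- thresholds %||% class_thresholds(probs, observed)
  est <- confident_class(probs, observed, thresholds)
  which(!is.na(est) & est != observed)
}

#' Confident-learning cleaning hook for training
#'
#' Creates the in-training label-cleaning schedule: at every `interval`-th
#' epoch, [train_classifier()] computes dropout-inactive probabilities on
#' the currently active training samples, recomputes the per-class
#' thresholds and the confident joint from those active samples only, and
#' permanently removes the flagged (off-diagonal) samples from subsequent
#' epochs. Removals are cumulative; a round that would empty a class is
#' skipped with a warning.
#'
#' Confident learning assumes the predicted probabilities come from a
#' reasonably fitted model; probabilities from the first epochs of a
#' from-scratch run cluster near the per-class thresholds and make the
#' off-diagonal set large and unreliable. `warmup` holds the cleaner idle
#' for that many initial epochs, so the first cleaning round sees a fitted
#' model; rounds then fire every `interval` epochs after the warm-up.
#'
#' @param interval Cleaning interval in epochs (default 3: cleaning is
#'   applied every 3 epochs until the end of training).
#' @param warmup Number of initial epochs during which the cleaner stays
#'   idle (default 0: the schedule starts immediately).
#' @return An `afuq_cleaner` list with fields `interval`, `warmup` and
#'   `flag`.
#' @export
confident_cleaner <- function(interval = 3, warmup = 0) {
  check_number(interval, "interval", 1, Inf)
  check_number(warmup, "warmup", 0, Inf)
  structure(
    list(
      interval = as.integer(interval),
      warmup = as.integer(warmup),
      flag = function(probs, observed) identify_label_issues(probs, observed)
    ),
    class = "afuq_cleaner"
  )
}
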