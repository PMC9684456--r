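#' Training configuration
#'
#' Hyperparameters for supervised training: Adam at learning rate 0.01 with
#' weight decay 1e-4 and batch size 128, up to 200 epochs with early
#' stopping once the monitored loss has not improved for `patience`
#' consecutive epochs. The monitored loss is the binary cross-entropy on a
#' held-out validation split (fraction `val_fraction`, stratified by
#' label).
#'
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight decay coefficient.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param val_fraction Validation fraction in (0, 1).
#' @param seed Integer seed controlling the split, shuffling, dropout and
#'   initial state of training.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 128, learning_rate = 0.01,
                         weight_decay = 1e-4, max_epochs = 200,
                         patience = 10, val_fraction = 0.1, seed = 1) {
  check_number(batch_size, "batch_size", 1, Inf)
  check_number(learning_rate, "learning_rate", 1e-12, Inf)
  check_number(weight_decay, "weight_decay", 0, Inf)
  check_number(max_epochs, "max_epochs", 1, Inf)
  check_number(patience, "patience", 1, Inf)
  if (val_fraction <= 0 || val_fraction >= 1) {
    abort("`val_fraction` must be in (0, 1).", class = "afuq_parameter_error")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# Early-stopping bookkeeping: strict improvement of the monitored loss
# resets the counter; `stop` turns on after `patience` consecutive
# non-improving epochs.
early_stop_state <- function(patience) {
  list(patience = as.integer(patience), best = Inf, stale = 0L,
       improved = FALSE, stop = FALSE)
}

early_stop_update <- function(state, loss) {
  if (loss < state$best) {
    state$best <- loss
    state$stale <- 0L
    state$improved <- TRUE
  } else {
    state$stale <- state$stale + 1L
    state$improved <- FALSE
    if (state$stale >= state$patience) state$stop <- TRUE
  }
  state
}

# Stratified index split: returns validation indices.
stratified_val_split <- function(labels, val_fraction) {
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train the AF classifier
#'
#' Optimises binary cross-entropy with Adam on the labelled segments of
#' `data`, monitoring validation loss for early stopping. If a `cleaner`
#' (see [confident_cleaner()]) is supplied, it is invoked on its epoch
#' schedule with the model's current out-of-loop (dropout-inactive)
#' probabilities on the active training samples, and may only shrink the
#' active set: samples it flags are removed permanently from subsequent
#' epochs. Because the monitored loss is computed against the observed
#' (possibly mislabelled) validation labels, every cleaning round that
#' prunes a material share of the data (at least 1% of the active set)
#' starts a fresh early-stopping phase, so the returned weights come
#' from training on the cleaned set rather than from a spurious
#' pre-cleaning optimum of the noisy monitored loss.
#' After every epoch the batch-norm population statistics are
#' re-estimated at the current weights with a dropout-free pass over the
#' active training samples, so evaluation-mode probabilities track the
#' trained weights; at the end of training the weights from the epoch with
#' the best validation loss are restored. Fully reproducible given
#' `config$seed`.
#'
#' @param model An untrained (or pre-trained) `af_classifier`.
#' @param data A cohort tibble with a `signal` list-column and a binary
#'   `label` column (0 = sinus rhythm, 1 = AF).
#' @param config A [train_config()].
#' @param cleaner Optional cleaning hook from [confident_cleaner()].
#' @return The trained `af_classifier`, with `history` (per-epoch train and
#'   validation losses and active-sample counts), `cleaning_report`,
#'   `active` (final active mask over rows of `data`) and `flagged_ids`
#'   (segment ids pruned by the cleaner). Retrieve the history tidily with
#'   [tidy.af_classifier()].
#' @export
train_classifier <- function(model, data, config = train_config(),
                             cleaner = NULL) {
  if (!inherits(model, "af_classifier")) abort("`model` must be an af_classifier.")
  if (!is.data.frame(data) || is.null(data$signal) || is.null(data$label)) {
    abort("`data` must be a tibble with `signal` and `label` columns.",
          class = "afuq_parameter_error")
  }
  y_all <- as.integer(data$label)
  if (length(unique(y_all)) < 2) {
    abort("Training data must contain both classes.",
          class = "afuq_training_error")
  }
  check_signal_input(model, data$signal)

  with_seed(config$seed, {
    n <- nrow(data)
    val_idx <- stratified_val_split(y_all, config$val_fraction)
    train_idx <- setdiff(seq_len(n), val_idx)
    active <- rep(TRUE, n)
    active[val_idx] <- FALSE # validation never trains

    params <- model$params
    state <- adam_init(params)
    cfg <- model$config
    es <- early_stop_state(config$patience)
    best_params <- params
    history <- vector("list", config$max_epochs)
    clean_rows <- list()

    eval_probs <- function(idx) {
      p <- numeric(length(idx))
      for (start in seq(1L, length(idx), by = 512L)) {
        take <- idx[start:min(start + 511L, length(idx))]
        p[start:(start + length(take) - 1L)] <-
          nn_forward(params, cfg, data$signal[take], mode = "eval")$p
      }
      p
    }

    epoch <- 0L
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      act <- which(active)
      ord <- act[sample.int(length(act))]
      tr_loss_num <- 0
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        fw <- nn_forward(params, cfg, data$signal[take], mode = "train",
                         keep_cache = TRUE)
        params <- fw$params # running BN stats updated
        grads <- nn_backward(params, cfg, fw, y_all[take])
        stepped <- adam_step(params, grads, state, config$learning_rate,
                             config$weight_decay)
        params <- stepped$params
        state <- stepped$state
        tr_loss_num <- tr_loss_num + bce_loss(fw$p, y_all[take]) * length(take)
      }
      train_loss <- tr_loss_num / length(ord)
      # refresh the batch-norm population statistics at the new weights so
      # evaluation-mode probabilities (validation, cleaning, inference)
      # reflect this epoch's parameters rather than a stale running average
      params <- bn_recalibrate(params, cfg, data$signal[act])
      val_loss <- bce_loss(eval_probs(val_idx), y_all[val_idx])

      # confident-learning hook: prune likely-mislabelled active samples
      warmup <- if (is.null(cleaner)) 0L else cleaner$warmup %||% 0L
      pruned_now <- FALSE
      if (!is.null(cleaner) && epoch > warmup &&
          (epoch - warmup) %% cleaner$interval == 0L) {
        p_act <- eval_probs(act)
        flagged_local <- cleaner$flag(p_act, y_all[act])
        if (length(flagged_local)) {
          keep_labels <- y_all[act][-flagged_local]
          if (length(unique(keep_labels)) < 2) {
            warn(sprintf("Epoch %d: cleaning skipped; it would remove a whole class.",
                         epoch))
          } else {
            active[act[flagged_local]] <- FALSE
            # a materially sized prune; trivial ones (under 1% of the
            # active set) do not meaningfully change the optimization
            # problem and should not discard the early-stopping evidence
            pruned_now <- length(flagged_local) >= 0.01 * length(act)
          }
        }
        clean_rows[[length(clean_rows) + 1L]] <- tibble(
          epoch = epoch, flagged = length(flagged_local),
          active_after = sum(active)
        )
      }

      history[[epoch]] <- tibble(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        active_count = sum(active)
      )

      # Material pruning changes the training set, and the monitored
      # loss is computed against the observed (possibly wrong) labels,
      # so a post-pruning rise in it can reflect the model ceasing to
      # fit labels just identified as mislabelled rather than a genuine
      # regression. Comparing it against pre-pruning epochs would stop
      # training (and restore weights) for exactly the wrong reason, so
      # every material round starts a fresh early-stopping phase.
      if (pruned_now) {
        es <- early_stop_state(config$patience)
      }
      es <- early_stop_update(es, val_loss)
      if (es$improved) best_params <- params
      if (es$stop) break
    }

    model$params <- best_params # restore the best-validation-loss weights
    model$trained <- TRUE
    model$history <- bind_rows(history[!vapply(history, is.null, logical(1))])
    model$cleaning_report <- if (length(clean_rows)) bind_rows(clean_rows) else NULL
    model$active <- active
    model$val_idx <- val_idx
    model$flagged_ids <- if (!is.null(data$segment_id)) {
      data$segment_id[!active & !seq_len(n) %in% val_idx]
    } else {
      which(!active & !seq_len(n) %in% val_idx)
    }
    model$train_config <- config
    model
  })
}

#' Mean binary cross-entropy of a model on a labelled dataset
#'
#' Evaluates the dropout-inactive model on every row of `data` (or only the
#' rows selected by `active`) and returns the mean of
#' \eqn{-[y \log p + (1-y)\log(1-p)]}, with probabilities clamped to
#' \[1e-7, 1 - 1e-7\] before the log.
#'
#' @param model A built `af_classifier`.
#' @param data Cohort tibble with `signal` and `label` columns.
#' @param active Optional logical mask selecting the rows to score.
#' @return The mean binary cross-entropy (a single number).
#' @export
evaluate_loss <- function(model, data, active = NULL) {
  if (!is.null(active)) data <- data[active, , drop = FALSE]
  if (nrow(data) == 0) {
    abort("No active samples to evaluate.", class = "afuq_parameter_error")
  }
  p <- predict(model, data)
  bce_loss(p, as.integer(data$label))
}

#' Tidy the training history of a classifier
#'
#' @param x A trained `af_classifier`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `active_count`.
#' @method tidy af_classifier
#' @export
tidy.af_classifier <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), train_loss = double(),
                        val_loss = double(), active_count = integer())
}

#' One-row summary of a trained classifier
#'
#' @param x A trained `af_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs run, final losses and
#'   final active-sample count.
#' @method glance af_classifier
#' @export
glance.af_classifier <- function(x, ...) {
  h <- tidy(x)
  tibble(
    n_parameters = n_parameters(x),
    epochs = nrow(h),
    final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    final_val_loss = if (nrow(h)) h$val_loss[nrow(h)] else NA_real_,
    best_val_loss = if (nrow(h)) min(h$val_loss) else NA_real_,
    final_active = if (nrow(h)) h$active_count[nrow(h)] else NA_integer_
  )
}
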