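#' Network configuration for the AF classifier
#'
#' Configures the binary ECG rhythm classifier: a stack of `n_blocks` 1D
#' convolution blocks (convolution, batch normalisation, ReLU, dropout)
#' with per-block dilation rising from 1 to 8, dilated max-pooling applied
#' selectively after the blocks in `pool_blocks` (defaults 6 and 11),
#' global average pooling over time, and a single-logit linear head with a
#' sigmoid, so inputs of any sufficient length map to one probability of
#' AF. The default 13-block geometry, 30% dropout and pooling placement
#' follow the dilated CNN family widely used for single-lead arrhythmia
#' classification; channel widths are configurable since published
#' descriptions constrain only the block structure.
#'
#' @param n_blocks Number of convolution blocks.
#' @param channels Channels per block: a single width or a vector of length
#'   `n_blocks`.
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param pool_blocks Indices of blocks followed by dilated max-pooling
#'   (window 2, stride 2, dilation equal to the block's dilation).
#' @param dilation_schedule Per-block dilations: non-decreasing, starting
#'   at 1; the default rises to 8 over 13 blocks.
#' @param n_leads Number of input leads (signal rows).
#' @param kernel_size Convolution kernel width (odd).
#' @param scale Width multiplier applied to `channels`, for scaled-down
#'   runs; parameter count is monotone in `scale`.
#'
#' @return A `network_config` list.
#' @export
network_config <- function(n_blocks = 13, channels = 16, dropout_rate = 0.3,
                           pool_blocks = NULL, dilation_schedule = NULL,
                           n_leads = 4, kernel_size = 3, scale = 1) {
  check_number(n_blocks, "n_blocks", 1, Inf)
  check_number(scale, "scale", 1e-6, Inf)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1).", class = "afuq_config_error")
  }
  if (kernel_size %% 2 != 1) {
    abort("`kernel_size` must be odd (same padding).", class = "afuq_config_error")
  }
  n_blocks <- as.integer(n_blocks)
  if (is.null(dilation_schedule)) {
    dilation_schedule <- if (n_blocks == 13) {
      c(1, 1, 2, 2, 2, 4, 4, 4, 4, 8, 8, 8, 8)
    } else if (n_blocks == 1) 1 else {
      # non-decreasing powers of two from 1 to 8
      round(2^seq(0, 3, length.out = n_blocks))
    }
  }
  if (length(dilation_schedule) != n_blocks ||
      dilation_schedule[1] != 1 ||
      any(diff(dilation_schedule) < 0) ||
      any(dilation_schedule < 1)) {
    abort("`dilation_schedule` must have length `n_blocks`, start at 1 and be non-decreasing.",
          class = "afuq_config_error")
  }
  if (is.null(pool_blocks)) pool_blocks <- intersect(c(6L, 11L), seq_len(n_blocks))
  if (length(pool_blocks) && (any(pool_blocks < 1) || any(pool_blocks > n_blocks))) {
    abort("`pool_blocks` must be block indices.", class = "afuq_config_error")
  }
  channels <- pmax(1L, as.integer(round(rep_len(channels, n_blocks) * scale)))

  structure(
    list(n_blocks = n_blocks, channels_per_block = channels,
         dropout_rate = dropout_rate, pool_blocks = as.integer(pool_blocks),
         dilation_schedule = as.integer(dilation_schedule),
         n_leads = as.integer(n_leads), kernel_size = as.integer(kernel_size),
         scale = scale),
    class = "network_config"
  )
}

#' Build an AF classifier
#'
#' Initialises all parameters (He-scaled convolution weights, unit-gain
#' batch-norm, zero-initialised head) reproducibly from `seed`.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return An `af_classifier` object.
#' @export
build_classifier <- function(config = network_config(), seed = 1) {
  if (!inherits(config, "network_config")) {
    abort("`config` must be a network_config.", class = "afuq_config_error")
  }
  k <- config$kernel_size
  with_seed(seed, {
    c_in <- config$n_leads
    blocks <- vector("list", config$n_blocks)
    for (i in seq_len(config$n_blocks)) {
      c_out <- config$channels_per_block[i]
      fan_in <- c_in * k
      blocks[[i]] <- list(
        W = matrix(rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)), c_out, fan_in),
        b = numeric(c_out),
        gamma = rep(1, c_out), beta = numeric(c_out),
        run_mean = numeric(c_out), run_var = rep(1, c_out)
      )
      c_in <- c_out
    }
    head <- list(w = matrix(rnorm(c_in, sd = sqrt(1 / c_in)), 1, c_in), b = 0)
    structure(
      list(config = config, params = list(blocks = blocks, head = head),
           trained = FALSE, history = NULL, cleaning_report = NULL,
           seed = seed),
      class = "af_classifier"
    )
  })
}

#' Number of trainable parameters
#' @param model An `af_classifier`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  tr <- c(lapply(model$params$blocks, function(b) b[c("W", "b", "gamma", "beta")]),
          list(model$params$head))
  sum(rapply(tr, length, how = "unlist"))
}

#' @export
print.af_classifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<af_classifier> %d blocks, channels %s, dropout %.2f, %s | %d params%s\n",
    cfg$n_blocks, paste(unique(cfg$channels_per_block), collapse = "/"),
    cfg$dropout_rate,
    if (length(cfg$pool_blocks)) paste("pool after", paste(cfg$pool_blocks, collapse = ",")) else "no pooling",
    n_parameters(x), if (x$trained) " | trained" else ""
  ))
  invisible(x)
}

check_signal_input <- function(model, signals) {
  for (s in signals) {
    if (!is.matrix(s) || nrow(s) != model$config$n_leads) {
      abort(sprintf("Signals must be matrices with %d lead rows.",
                    model$config$n_leads),
            class = "afuq_shape_error")
    }
    if (any(!is.finite(s))) {
      abort("Signals must be finite.", class = "afuq_shape_error")
    }
  }
  invisible(TRUE)
}

# Predict p(AF) for a list of signal matrices; groups by length so
# variable-length inputs batch correctly. mode "eval" or "mc".
predict_signals <- function(model, signals, mode = "eval", seed = NULL,
                            batch_size = 512L) {
  check_signal_input(model, signals)
  with_seed(seed, {
    out <- numeric(length(signals))
    lens <- vapply(signals, ncol, integer(1))
    for (L in unique(lens)) {
      idx <- which(lens == L)
      for (start in seq(1L, length(idx), by = batch_size)) {
        take <- idx[start:min(start + batch_size - 1L, length(idx))]
        fw <- nn_forward(model$params, model$config, signals[take],
                         mode = mode)
        out[take] <- fw$p
      }
    }
    out
  })
}

#' Predict AF probabilities
#'
#' Runs the classifier on one signal matrix, a list of signal matrices, or
#' a cohort tibble with a `signal` list-column, and returns p(AF) per
#' segment. With `dropout_active = FALSE` the output is deterministic for
#' fixed parameters; with `dropout_active = TRUE` dropout units stay active
#' (one Monte Carlo dropout sample per call).
#'
#' @param object An `af_classifier`.
#' @param signal Signal matrix, list of matrices, or cohort tibble.
#' @param dropout_active Keep dropout active at inference.
#' @param seed Integer seed for the dropout draw.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.af_classifier <- function(object, signal, dropout_active = FALSE,
                                  seed = NULL, ...) {
  signals <- if (is.data.frame(signal)) {
    signal$signal
  } else if (is.matrix(signal)) list(signal) else signal
  predict_signals(object, signals,
                  mode = if (dropout_active) "mc" else "eval", seed = seed)
}
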