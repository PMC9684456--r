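# Internal neural-network engine.
#
# The full forward and backward passes live in src/nn.cpp, operating on
# single-precision, time-major workspaces; the forward pass returns the
# probabilities plus an opaque cache handle that the backward pass
# consumes. This file wraps those calls, maintains the batch-norm running
# statistics, computes the loss, and runs the Adam optimizer.

sigmoid <- function(z) 1 / (1 + exp(-z))

.bn_momentum <- 0.1

# mode: "train" (BN batch stats + dropout), "eval" (running stats, no
# dropout), "mc" (running stats, dropout active). `signals` is a list of
# leads x samples matrices of equal length.
nn_forward <- function(params, config, signals, mode = "eval",
                       keep_cache = FALSE) {
  mode_i <- match(mode, c("eval", "train", "mc")) - 1L
  out <- nn_fwd_cpp(params, config, signals, mode_i, keep_cache)
  if (mode == "train") {
    for (i in seq_along(params$blocks)) {
      ru <- out$run_updates[[i]]
      params$blocks[[i]]$run_mean <-
        (1 - .bn_momentum) * params$blocks[[i]]$run_mean + .bn_momentum * ru$mean
      params$blocks[[i]]$run_var <-
        (1 - .bn_momentum) * params$blocks[[i]]$run_var + .bn_momentum * ru$var
    }
  }
  list(p = as.numeric(out$p), cache = out$cache, params = params)
}

# Backward pass for mean BCE loss over the batch. `fw` must come from
# nn_forward(..., mode = "train", keep_cache = TRUE).
nn_backward <- function(params, config, fw, y) {
  nn_bwd_cpp(params, config, fw$cache, as.numeric(y))
}

# Re-estimate the batch-norm population statistics at the current weights
# by streaming dropout-free batch statistics over `signals` and pooling
# them. The exponential running average kept during training lags the
# rapidly moving weights, and the deep stack amplifies that staleness into
# a large train/eval probability gap; re-estimating after each epoch makes
# the evaluation-mode forward pass consistent with the trained weights.
# The statistics are channel means over every time step, so a fixed-size,
# evenly spaced subsample of the data estimates them with ample precision
# at a fraction of the cost.
bn_recalibrate <- function(params, config, signals, batch_size = 512L,
                           max_samples = 1024L) {
  if (length(signals) > max_samples) {
    take <- unique(round(seq(1L, length(signals), length.out = max_samples)))
    signals <- signals[take]
  }
  cfg0 <- config
  cfg0$dropout_rate <- 0
  nb <- length(params$blocks)
  acc_m <- vector("list", nb)
  acc_s <- vector("list", nb)
  w_tot <- 0
  lens <- vapply(signals, ncol, integer(1))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    for (start in seq(1L, length(idx), by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1L, length(idx))]
      out <- nn_fwd_cpp(params, cfg0, signals[take], 1L, FALSE)
      wt <- length(take)
      w_tot <- w_tot + wt
      for (i in seq_len(nb)) {
        ru <- out$run_updates[[i]]
        m <- as.numeric(ru$mean)
        s <- as.numeric(ru$var) + m * m # E[x^2] per channel
        acc_m[[i]] <- (acc_m[[i]] %||% 0) + wt * m
        acc_s[[i]] <- (acc_s[[i]] %||% 0) + wt * s
      }
    }
  }
  for (i in seq_len(nb)) {
    mu <- acc_m[[i]] / w_tot
    params$blocks[[i]]$run_mean <- mu
    params$blocks[[i]]$run_var <- pmax(0, acc_s[[i]] / w_tot - mu * mu)
  }
  params
}

bce_loss <- function(p, y) {
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  trainable <- list(blocks = lapply(params$blocks, function(b) b[c("W", "b", "gamma", "beta")]),
                    head = params$head)
  list(m = zero_like(trainable), v = zero_like(trainable), t = 0L)
}

# One Adam step with L2 weight decay folded into the gradient (coupled
# decay, matching the common framework default for Adam's weight_decay).
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t

  upd <- function(p, g, m, v) {
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }

  for (i in seq_along(params$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      r <- upd(params$blocks[[i]][[nm]], grads$blocks[[i]][[nm]],
               state$m$blocks[[i]][[nm]], state$v$blocks[[i]][[nm]])
      params$blocks[[i]][[nm]] <- r$p
      state$m$blocks[[i]][[nm]] <- r$m
      state$v$blocks[[i]][[nm]] <- r$v
    }
  }
  for (nm in c("w", "b")) {
    r <- upd(params$head[[nm]], grads$head[[nm]],
             state$m$head[[nm]], state$v$head[[nm]])
    params$head[[nm]] <- r$p
    state$m$head[[nm]] <- r$m
    state$v$head[[nm]] <- r$v
  }
  list(params = params, state = state)
}
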