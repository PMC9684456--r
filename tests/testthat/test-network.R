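# Network architecture, prediction contracts and gradient correctness.

tiny_cfg <- function(dropout = 0) {
  network_config(n_blocks = 3, channels = 4, dropout_rate = dropout,
                 pool_blocks = 2, dilation_schedule = c(1, 1, 2), n_leads = 2)
}
tiny_signals <- function(n, len = 64, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    matrix(rnorm(2 * len), nrow = 2)
  }))
}

test_that("default configuration matches the documented architecture", {
  cfg <- network_config()
  expect_equal(cfg$n_blocks, 13L)
  expect_equal(cfg$pool_blocks, c(6L, 11L))
  expect_equal(cfg$dilation_schedule,
               as.integer(c(1, 1, 2, 2, 2, 4, 4, 4, 4, 8, 8, 8, 8)))
  expect_equal(cfg$dropout_rate, 0.3)
  expect_equal(cfg$n_leads, 4L)
})

test_that("configuration validation errors", {
  expect_error(network_config(dropout_rate = 1), class = "afuq_config_error")
  expect_error(network_config(dilation_schedule = c(2, 2, 4), n_blocks = 3),
               class = "afuq_config_error") # must start at 1
  expect_error(network_config(dilation_schedule = c(1, 4, 2), n_blocks = 3),
               class = "afuq_config_error") # must be non-decreasing
  expect_error(network_config(dilation_schedule = c(1, 2), n_blocks = 3),
               class = "afuq_config_error") # wrong length
  expect_error(network_config(kernel_size = 4), class = "afuq_config_error")
  expect_error(network_config(pool_blocks = 14), class = "afuq_config_error")
})

test_that("initialisation is reproducible and width scales parameters", {
  m1 <- build_classifier(network_config(scale = 0.25), seed = 5)
  m2 <- build_classifier(network_config(scale = 0.25), seed = 5)
  expect_identical(m1$params, m2$params)
  m_full <- build_classifier(network_config(scale = 1), seed = 5)
  expect_lt(n_parameters(m1), n_parameters(m_full))
})

test_that("deterministic prediction contracts hold", {
  model <- build_classifier(tiny_cfg(dropout = 0.3), seed = 1)
  sig <- tiny_signals(1)[[1]]
  p1 <- predict(model, sig)
  p2 <- predict(model, sig)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 < 1)
})

test_that("dropout-active prediction varies across seeds, and not with rate 0", {
  model <- build_classifier(tiny_cfg(dropout = 0.5), seed = 1)
  sig <- tiny_signals(1, len = 128)[[1]]
  ps <- vapply(1:10, function(s) predict(model, sig, dropout_active = TRUE,
                                         seed = s), numeric(1))
  expect_gt(length(unique(ps)), 1)

  model0 <- build_classifier(tiny_cfg(dropout = 0), seed = 1)
  ps0 <- vapply(1:10, function(s) predict(model0, sig, dropout_active = TRUE,
                                          seed = s), numeric(1))
  expect_equal(max(ps0) - min(ps0), 0)
})

test_that("variable-length inputs both produce valid probabilities", {
  model <- build_classifier(network_config(scale = 0.25), seed = 2)
  sig5 <- matrix(rnorm(4 * 1200), nrow = 4)
  sig10 <- matrix(rnorm(4 * 2400), nrow = 4)
  p <- predict(model, list(sig5, sig10))
  expect_length(p, 2)
  expect_true(all(p > 0 & p < 1))
})

test_that("wrong lead count and non-finite input raise shape errors", {
  model <- build_classifier(tiny_cfg(), seed = 1)
  expect_error(predict(model, matrix(0, 3, 64)), class = "afuq_shape_error")
  bad <- matrix(0, 2, 64)
  bad[1, 1] <- NA
  expect_error(predict(model, bad), class = "afuq_shape_error")
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg(dropout = 0)
  model <- build_classifier(cfg, seed = 3)
  sigs <- tiny_signals(4, len = 48, seed = 4)
  y <- c(1, 0, 1, 0)

  loss_at <- function(params) {
    fw <- afuq:::nn_forward(params, cfg, sigs, mode = "train")
    afuq:::bce_loss(fw$p, y)
  }
  fw <- afuq:::nn_forward(model$params, cfg, sigs, mode = "train",
                          keep_cache = TRUE)
  grads <- afuq:::nn_backward(model$params, cfg, fw, y)

  # The forward pass runs in single precision, so use a coarse step and a
  # relative tolerance matched to that precision.
  eps <- 5e-3
  check <- function(path_get, path_set, g, idx) {
    for (i in idx) {
      pp <- model$params
      v <- path_get(pp)
      v[i] <- v[i] + eps; pp <- path_set(pp, v)
      up <- loss_at(pp)
      v[i] <- v[i] - 2 * eps; pp <- path_set(pp, v)
      dn <- loss_at(pp)
      v[i] <- v[i] + eps
      fd <- (up - dn) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 0.08,
                   label = sprintf("analytic grad [%d]", i))
    }
  }
  # a spread of parameters in the first and last blocks plus the head
  check(function(p) p$blocks[[1]]$W,
        function(p, v) { p$blocks[[1]]$W <- v; p },
        grads$blocks[[1]]$W, c(1, 7, 13))
  check(function(p) p$blocks[[3]]$W,
        function(p, v) { p$blocks[[3]]$W <- v; p },
        grads$blocks[[3]]$W, c(2, 20))
  check(function(p) p$blocks[[2]]$gamma,
        function(p, v) { p$blocks[[2]]$gamma <- v; p },
        grads$blocks[[2]]$gamma, c(1, 3))
  check(function(p) p$blocks[[2]]$beta,
        function(p, v) { p$blocks[[2]]$beta <- v; p },
        grads$blocks[[2]]$beta, c(2, 4))
  check(function(p) p$head$w,
        function(p, v) { p$head$w <- v; p },
        grads$head$w, c(1, 4))
  check(function(p) p$head$b,
        function(p, v) { p$head$b <- v; p },
        grads$head$b, 1)
})

test_that("one small optimisation step decreases the batch loss", {
  cfg <- tiny_cfg(dropout = 0)
  model <- build_classifier(cfg, seed = 6)
  sigs <- tiny_signals(8, len = 64, seed = 7)
  y <- rep(c(1, 0), 4)
  fw <- afuq:::nn_forward(model$params, cfg, sigs, mode = "train",
                          keep_cache = TRUE)
  loss0 <- afuq:::bce_loss(fw$p, y)
  grads <- afuq:::nn_backward(model$params, cfg, fw, y)
  st <- afuq:::adam_init(model$params)
  stepped <- afuq:::adam_step(model$params, grads, st, lr = 1e-3,
                              weight_decay = 0)
  fw1 <- afuq:::nn_forward(stepped$params, cfg, sigs, mode = "train")
  expect_lt(afuq:::bce_loss(fw1$p, y), loss0)
})
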