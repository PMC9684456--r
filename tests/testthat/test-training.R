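# Training recipe: configuration, early stopping, loss, cleaning hook
# integration and determinism.

small_task <- function(n_per_class = 12, len = 96, seed = 1) {
  # linearly separable toy "signals": class decides the mean level
  withr::with_seed(seed, {
    y <- rep(0:1, each = n_per_class)
    sigs <- lapply(y, function(cl) {
      matrix(rnorm(2 * len, mean = if (cl == 1) 0.8 else -0.8, sd = 0.3),
             nrow = 2)
    })
    tibble::tibble(signal = sigs, label = y,
                   segment_id = sprintf("S%03d", seq_along(y)))
  })
}
small_net <- function() {
  network_config(n_blocks = 3, channels = 4, dropout_rate = 0.1,
                 pool_blocks = 2, dilation_schedule = c(1, 1, 2), n_leads = 2)
}

test_that("train_config validates its fields", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$max_epochs, 200L)
  expect_equal(cfg$patience, 10L)
  expect_error(train_config(patience = 0), class = "afuq_parameter_error")
  expect_error(train_config(val_fraction = 1), class = "afuq_parameter_error")
  expect_error(train_config(batch_size = 0), class = "afuq_parameter_error")
})

test_that("early stopping never triggers under strict improvement", {
  es <- afuq:::early_stop_state(10)
  for (e in 1:50) {
    es <- afuq:::early_stop_update(es, 1 / e)
    expect_false(es$stop)
  }
})

test_that("constant monitored loss from epoch 1 stops at epoch 11", {
  es <- afuq:::early_stop_state(10)
  stopped_at <- NA
  for (e in 1:30) {
    es <- afuq:::early_stop_update(es, 1.0)
    if (es$stop) { stopped_at <- e; break }
  }
  expect_equal(stopped_at, 11)
})

test_that("bce loss hand values", {
  expect_equal(afuq:::bce_loss(rep(0.5, 4), c(1, 0, 1, 0)), log(2))
  expect_equal(afuq:::bce_loss(0.8, 1), -log(0.8))
  expect_lt(afuq:::bce_loss(c(1, 0), c(1, 0)), 1e-6) # clamped limit
})

test_that("training runs, records history, and is deterministic", {
  data <- small_task()
  cfg <- train_config(batch_size = 8, max_epochs = 3, patience = 2,
                      val_fraction = 0.2, seed = 11)
  m1 <- train_classifier(build_classifier(small_net(), seed = 1), data, cfg)
  m2 <- train_classifier(build_classifier(small_net(), seed = 1), data, cfg)
  expect_true(m1$trained)
  expect_identical(m1$params, m2$params)
  expect_identical(tidy(m1), tidy(m2))
  h <- tidy(m1)
  expect_equal(nrow(h), 3)
  expect_named(h, c("epoch", "train_loss", "val_loss", "active_count"))
  expect_true(all(is.finite(h$train_loss)))
  g <- glance(m1)
  expect_equal(g$epochs, 3)
  expect_equal(g$n_parameters, n_parameters(m1))
})

test_that("single-class training data raises a training error", {
  data <- small_task()
  data$label <- 0L
  expect_error(
    train_classifier(build_classifier(small_net(), seed = 1), data,
                     train_config(max_epochs = 1)),
    class = "afuq_training_error"
  )
})

test_that("a cleaner that never flags leaves the active set untouched", {
  data <- small_task()
  idle <- structure(list(interval = 1L,
                         flag = function(probs, observed) integer(0)),
                    class = "afuq_cleaner")
  m <- train_classifier(build_classifier(small_net(), seed = 2), data,
                        train_config(batch_size = 8, max_epochs = 3,
                                     patience = 3, val_fraction = 0.2,
                                     seed = 3),
                        cleaner = idle)
  # everything except the validation split stays active
  expect_equal(sum(m$active), nrow(data) - length(m$val_idx))
  expect_length(m$flagged_ids, 0)
  expect_equal(m$cleaning_report$flagged, rep(0, 3))
})

test_that("cleaning fires on schedule and pruning is monotone", {
  data <- small_task(n_per_class = 16)
  # flag one fixed sample per invocation, to exercise cumulative pruning
  greedy <- structure(list(interval = 3L,
                           flag = function(probs, observed) 1L),
                      class = "afuq_cleaner")
  m <- train_classifier(build_classifier(small_net(), seed = 4), data,
                        train_config(batch_size = 8, max_epochs = 10,
                                     patience = 10, val_fraction = 0.2,
                                     seed = 5),
                        cleaner = greedy)
  expect_equal(m$cleaning_report$epoch, c(3, 6, 9))
  h <- tidy(m)
  expect_true(all(diff(h$active_count) <= 0))
  expect_equal(sum(!m$active) - length(m$val_idx), 3)
})

test_that("a cleaner warm-up delays the schedule", {
  data <- small_task(n_per_class = 16)
  greedy <- structure(list(interval = 3L, warmup = 4L,
                           flag = function(probs, observed) 1L),
                      class = "afuq_cleaner")
  m <- train_classifier(build_classifier(small_net(), seed = 4), data,
                        train_config(batch_size = 8, max_epochs = 10,
                                     patience = 10, val_fraction = 0.2,
                                     seed = 5),
                        cleaner = greedy)
  # idle through epoch 4, then every 3rd epoch after the warm-up
  expect_equal(m$cleaning_report$epoch, c(7, 10))
})

test_that("an effective cleaning round restarts the early-stopping phase", {
  data <- small_task(n_per_class = 16)
  # scrambled labels: the val loss has no steady descent, so with
  # patience 1 and no cleaner the run stops well before the epoch cap
  data$label <- withr::with_seed(42, sample(data$label))
  m0 <- train_classifier(build_classifier(small_net(), seed = 4), data,
                         train_config(batch_size = 8, max_epochs = 12,
                                      patience = 1, val_fraction = 0.2,
                                      seed = 5))
  expect_lt(nrow(tidy(m0)), 12)
  # a cleaner that prunes one sample every epoch resets the stale counter
  # each time, so the same run reaches the epoch cap
  greedy <- structure(list(interval = 1L,
                           flag = function(probs, observed) 1L),
                      class = "afuq_cleaner")
  m1 <- train_classifier(build_classifier(small_net(), seed = 4), data,
                         train_config(batch_size = 8, max_epochs = 12,
                                      patience = 1, val_fraction = 0.2,
                                      seed = 5),
                         cleaner = greedy)
  expect_equal(nrow(tidy(m1)), 12)
})

test_that("a cleaner that would empty a class is skipped with a warning", {
  data <- small_task(n_per_class = 6)
  nuke <- structure(list(interval = 1L,
                         flag = function(probs, observed) which(observed == 1)),
                    class = "afuq_cleaner")
  expect_warning(
    m <- train_classifier(build_classifier(small_net(), seed = 6), data,
                          train_config(batch_size = 8, max_epochs = 1,
                                       patience = 1, val_fraction = 0.2,
                                       seed = 7),
                          cleaner = nuke),
    "skipped"
  )
  expect_true(any(m$active))
})

test_that("evaluate_loss matches the closed forms", {
  data <- small_task(n_per_class = 4)
  m <- build_classifier(small_net(), seed = 8)
  l <- evaluate_loss(m, data)
  p <- predict(m, data)
  expect_equal(l, afuq:::bce_loss(p, data$label))
  expect_error(evaluate_loss(m, data, active = rep(FALSE, nrow(data))),
               class = "afuq_parameter_error")
})
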