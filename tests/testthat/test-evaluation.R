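# Evaluation statistics: hand examples, invariants, and agreement with
# brute-force oracles.

ptab <- function(p, y) tibble::tibble(p = p, y_true = y)

test_that("classification metrics reproduce a hand confusion table", {
  # TP=2, FP=1, FN=1, TN=6
  p <- c(0.9, 0.8, 0.3, 0.7, rep(0.2, 6))
  y <- c(1, 1, 1, 0, rep(0, 6))
  m <- classification_metrics(ptab(p, y))
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$f1, 2 / 3)
})

test_that("classification metrics handle degenerate predictions", {
  perfect <- classification_metrics(ptab(c(0.9, 0.1), c(1, 0)))
  expect_equal(unlist(perfect), c(f1 = 1, ppv = 1, sensitivity = 1,
                                  specificity = 1))
  all_neg <- classification_metrics(ptab(c(0.1, 0.2), c(1, 0)))
  expect_equal(all_neg$sensitivity, 0)
  expect_equal(all_neg$f1, 0)
  expect_equal(all_neg$specificity, 1)
  expect_error(classification_metrics(ptab(c(0.2, 0.8), c(1, 1))),
               class = "afuq_metric_error")
})

test_that("brier, nll and ece reproduce their hand examples", {
  expect_equal(brier(ptab(c(1, 0), c(1, 0))), 0)
  expect_equal(brier(ptab(c(0.5, 0.5), c(1, 0))), 0.25)
  expect_equal(brier(ptab(c(0.8, 0.4), c(1, 0))), 0.10)

  expect_equal(nll(ptab(0.5, 1)), log(2))
  expect_equal(nll(ptab(c(0.9, 0.9), c(1, 1))), -log(0.9))

  expect_equal(ece(ptab(c(1, 1, 0, 0), c(1, 1, 0, 0)))$ece, 0)
  expect_equal(ece(ptab(rep(0.8, 4), c(1, 1, 1, 0)))$ece, 0.05)
  expect_equal(ece(ptab(c(0.95, 0.9, 0.1, 0.05), c(1, 1, 0, 0)))$ece, 0.075)
})

test_that("ece bins are right-open except the last, and bin data is consistent", {
  # p = 0.1 falls in bin 2 [0.1, 0.2); p = 1 falls in the final closed bin
  r <- ece(ptab(c(0.1, 1), c(0, 1)))
  expect_equal(r$bins$n[2], 1L)
  expect_equal(r$bins$n[10], 1L)
  expect_equal(sum(r$bins$n), 2L)
  # weighted mean of |acc - conf| over occupied bins equals the scalar
  occ <- r$bins$n > 0
  expect_equal(sum(r$bins$n[occ] / r$n * abs(r$bins$acc[occ] - r$bins$conf[occ])),
               r$ece)
  # order invariance
  withr::with_seed(1, {
    p <- runif(200)
    y <- rbinom(200, 1, p)
    o <- sample(200)
    expect_equal(ece(ptab(p, y))$ece, ece(ptab(p[o], y[o]))$ece)
  })
})

test_that("confidence-count curve counts strictly-above-threshold positives", {
  d <- ptab(c(0.9, 0.6, 0.4), c(1, 1, 0))
  cc <- confidence_count_curve(d, thresholds = c(0, 0.7, 1))
  expect_equal(cc$count, c(2, 1, 0))
  full <- confidence_count_curve(d)
  expect_true(all(diff(full$count) <= 0))
})

test_that("cohen_kappa matches hand values and errors on degenerate margins", {
  expect_equal(cohen_kappa(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.5)
  expect_error(cohen_kappa(c(1, 1), c(1, 1)), class = "afuq_metric_error")
  expect_error(cohen_kappa(1, c(1, 0)), class = "afuq_parameter_error")
})

test_that("mann_whitney_u hand examples", {
  r <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r$u, 1)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$u, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$u, 4.5) # n1 n2 / 2
})

test_that("exact U p-values agree with wilcox.test on tie-free samples", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- rnorm(sample(3:8, 1))
      y <- rnorm(sample(3:8, 1))
      ours <- mann_whitney_u(x, y)
      expect_identical(ours$method, "exact")
      ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
      expect_equal(ours$p_value, ref$p.value)
    }
  })
})

test_that("U from the normal path agrees with enumeration for n1, n2 <= 8", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      n1 <- sample(2:8, 1)
      n2 <- sample(2:8, 1)
      x <- sample(1:6, n1, replace = TRUE) # tie-prone, forces normal path
      y <- sample(1:6, n2, replace = TRUE)
      ours <- mann_whitney_u(x, y)
      expect_equal(ours$u, oracle_u(x, y))
    }
  })
})

test_that("holm decisions follow the step-down hand example", {
  r <- holm_correct(c(0.002, 0.03), alpha = 0.01)
  expect_equal(r$reject, c(TRUE, FALSE))
  expect_false(any(holm_correct(rep(1, 5), alpha = 0.01)$reject))
  expect_true(holm_correct(0.009, alpha = 0.01)$reject)
  # monotone decisions
  withr::with_seed(2, {
    p <- runif(10)
    r2 <- holm_correct(p, alpha = 0.05)
    o <- order(p)
    expect_true(all(diff(!r2$reject[o]) >= 0))
  })
  expect_error(holm_correct(c(0.5, 1.2)), class = "afuq_parameter_error")
})

test_that("compare_uncertainty_groups separates shifted groups and skips empty ones", {
  withr::with_seed(3, {
    base <- tibble::tibble(
      uncertainty = c(runif(50), runif(50) + 2),
      noisy = rep(c(FALSE, TRUE), each = 50),
      ood = FALSE,
      y_true = rbinom(100, 1, 0.3)
    )
  })
  out <- compare_uncertainty_groups(base, groupings = "clean_vs_noisy",
                                    alpha = 0.01)
  expect_true(out$reject)
  # identical groups: no rejection
  same <- base
  same$uncertainty <- rep(seq(0, 1, length.out = 50), 2)
  out2 <- compare_uncertainty_groups(same, groupings = "clean_vs_noisy")
  expect_false(out2$reject)
  # ood group empty -> skipped with a message
  expect_message(
    out3 <- compare_uncertainty_groups(base,
                                       groupings = c("clean_vs_noisy",
                                                     "id_vs_ood")),
    "empty group"
  )
  expect_equal(nrow(out3), 1)
})

test_that("metric implementations agree with brute-force oracles", {
  withr::with_seed(11, {
    for (rep in 1:100) {
      n <- sample(5:60, 1)
      p <- round(runif(n), 2)
      y <- rbinom(n, 1, 0.5)
      d <- ptab(p, y)
      expect_equal(brier(d), oracle_brier(p, y))
      expect_equal(nll(d), oracle_nll(p, y))
      expect_equal(ece(d)$ece, oracle_ece(p, y))
      if (length(unique(y)) == 2) {
        ours <- classification_metrics(d)
        ref <- oracle_confusion(p, y)
        expect_equal(as.list(ours), ref)
      }
      a <- rbinom(n, 1, 0.5)
      if (length(unique(c(y, a))) > 1 &&
          !(all(y == a) && length(unique(y)) == 1)) {
        kap <- tryCatch(cohen_kappa(y, a), error = function(e) NULL)
        if (!is.null(kap)) expect_equal(kap, oracle_kappa(y, a))
      }
      x2 <- rnorm(sample(2:10, 1))
      y2 <- rnorm(sample(2:10, 1))
      expect_equal(mann_whitney_u(x2, y2)$u, oracle_u(x2, y2))
      pv <- runif(sample(1:6, 1))
      expect_equal(holm_correct(pv, alpha = 0.05)$reject,
                   oracle_holm(pv, 0.05))
    }
  })
})

test_that("brier and nll scale correctly under duplication", {
  d <- ptab(c(0.8, 0.3, 0.6), c(1, 0, 1))
  d2 <- dplyr::bind_rows(d, d)
  expect_equal(brier(d2), brier(d))
  expect_equal(nll(d2), nll(d))
})
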