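# Independent brute-force oracles. These deliberately use naive per-sample
# loops written straight from the definitions, so they share no code with
# the package's vectorized implementations.

oracle_brier <- function(p, y) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - y[i])^2
  s / length(p)
}

oracle_nll <- function(p, y, eps = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  s / length(p)
}

oracle_ece <- function(p, y, n_bins = 10) {
  total <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    inb <- if (b < n_bins) p >= lo & p < hi else p >= lo & p <= hi
    if (any(inb)) {
      total <- total + sum(inb) / length(p) * abs(mean(y[inb]) - mean(p[inb]))
    }
  }
  total
}

oracle_confusion <- function(p, y, thr = 0.5) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(p)) {
    pred <- p[i] > thr
    if (pred && y[i] == 1) tp <- tp + 1
    if (pred && y[i] == 0) fp <- fp + 1
    if (!pred && y[i] == 1) fn <- fn + 1
    if (!pred && y[i] == 0) tn <- tn + 1
  }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  list(f1 = f1, ppv = ppv, sensitivity = sens, specificity = spec)
}

oracle_kappa <- function(a, b) {
  cats <- union(unique(a), unique(b))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (k in cats) pe <- pe + (sum(a == k) / n) * (sum(b == k) / n)
  (po - pe) / (1 - pe)
}

# U statistic by literal pair counting with half credit for ties.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    if (xi > yi) u <- u + 1 else if (xi == yi) u <- u + 0.5
  }
  u
}

# Exact two-tailed p-value by enumeration of all group assignments,
# matching the "double the smaller tail" convention.
oracle_mwu_exact_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(idx) oracle_u(pool[idx], pool[-idx]))
  u_obs <- oracle_u(x, y)
  if (u_obs > n1 * length(y) / 2) {
    min(1, 2 * mean(us >= u_obs))
  } else {
    min(1, 2 * mean(us <= u_obs))
  }
}

oracle_holm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) {
      reject[ord[i]] <- TRUE
    } else {
      break
    }
  }
  reject
}

# Literal confident-learning reference: per-sample application of the
# threshold rule (class probabilities must reach the per-class mean; the
# largest qualifying probability wins; exact ties keep the observed label).
oracle_confident <- function(p1, observed) {
  p0 <- 1 - p1
  t0 <- mean(p0[observed == 0])
  t1 <- mean(p1[observed == 1])
  C <- matrix(0L, 2, 2)
  issues <- integer(0)
  for (i in seq_along(p1)) {
    q0 <- p0[i] >= t0
    q1 <- p1[i] >= t1
    est <- NA_integer_
    if (q0 && !q1) est <- 0L
    if (q1 && !q0) est <- 1L
    if (q0 && q1) {
      est <- if (p1[i] > p0[i]) 1L else if (p1[i] < p0[i]) 0L else observed[i]
    }
    if (!is.na(est)) {
      C[observed[i] + 1, est + 1] <- C[observed[i] + 1, est + 1] + 1L
      if (est != observed[i]) issues <- c(issues, i)
    }
  }
  list(C = C, issues = issues, t0 = t0, t1 = t1)
}

# Simple independent R-peak oracle used against the generator: local maxima
# above half the global maximum, at least `min_dist` seconds apart.
oracle_peaks <- function(x, fs, min_dist = 0.3) {
  thr <- 0.5 * max(x)
  n <- length(x)
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
                  x[2:(n - 1)] > thr) + 1
  keep <- numeric(0)
  for (c in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(c - keep) >= min_dist * fs)) keep <- c(keep, c)
  }
  sort(keep - 1) / fs
}
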