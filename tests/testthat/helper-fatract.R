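# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, direct formulas) so it stays independent of the package's
# implementation paths.

toy_atlas <- function(shape = c(6L, 6L, 6L), labels = 1:2) {
  arr <- array(0L, dim = shape)
  for (i in seq_along(labels)) arr[i, , ] <- labels[i]
  atlas_volume(arr, tibble::tibble(label = labels,
                                   tract_name = paste0("tract_", labels)))
}

random_fa <- function(shape = c(6L, 6L, 6L), seed = 1) {
  set.seed(seed)
  fa_volume(array(runif(prod(shape)), dim = shape), subject_id = "sub-test")
}

# tiny measurement matrix with named columns built directly
toy_matrix <- function(values, bmi, group) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%03d", seq_along(bmi)),
                   bmi = bmi, group = group),
    tibble::as_tibble(values)
  )
}

# --- brute-force statistic formulas (independent of compute_statistic) ----
oracle_statistic <- function(x, stat) {
  n <- length(x)
  m <- sum(x) / n
  switch(stat,
    arithmetic_mean = m,
    median = {
      s <- sort(x)
      if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    },
    standard_deviation = sqrt(sum((x - m)^2) / (n - 1)),
    range = max(x) - min(x),
    variance = sum((x - m)^2) / (n - 1),
    harmonic_mean = { x <- x[x > 0]; length(x) / sum(1 / x) },
    geometric_mean = { x <- x[x > 0]; prod(x)^(1 / length(x)) },
    interquartile_range = {
      # linear-interpolation (type 7) quartiles, written out
      q <- function(p) {
        s <- sort(x)
        h <- (n - 1) * p + 1
        lo <- floor(h)
        s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
      }
      q(0.75) - q(0.25)
    },
    maximum = max(x),
    minimum = min(x),
    mean_absolute_deviation = sum(abs(x - m)) / n,
    median_absolute_deviation = oracle_statistic(abs(x - oracle_statistic(x, "median")),
                                                 "median"),
    root_mean_square = sqrt(sum(x^2) / n)
  )
}

# midranks by explicit position averaging
oracle_midranks <- function(x) {
  s <- sort(x)
  vapply(x, function(v) mean(which(s == v)), numeric(1))
}

# Pearson by the direct sum formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# BH step-up by the textbook recursion
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# exact rank-sum null: enumerate every assignment of pooled indices
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- oracle_midranks(pooled)
  n1 <- length(x)
  idx <- combn(length(pooled), n1)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}

# hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(tp, K, M, k) {
  sum(vapply(tp:min(K, k), function(t) {
    choose(K, t) * choose(M - K, k - t) / choose(M, k)
  }, numeric(1)))
}

# small synthetic regression problem with named measurement columns
small_problem <- function(n = 40, p = 6, n_signal = 2, seed = 1,
                          noise = 1) {
  set.seed(seed)
  bmi <- sample(19:40, n, replace = TRUE)
  vals <- sapply(seq_len(p), function(j) {
    beta <- if (j <= n_signal) 0.02 * (-1)^j else 0
    0.5 + beta * (bmi - mean(bmi)) + rnorm(n, sd = 0.02 * noise)
  })
  colnames(vals) <- paste0("t", seq_len(p), "|arithmetic_mean")
  toy_matrix(vals, bmi, ifelse(bmi < 25, "NW", "OB"))
}
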