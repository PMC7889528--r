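# Independent brute-force oracles. Deliberately written as plain loops over
# the definitions, sharing no code with the package implementations.

oracle_otsu <- function(gray) {
  vals <- as.integer(gray)
  if (length(unique(vals)) == 1) return(vals[1] / 255)
  best_t <- NA_integer_
  best_within <- Inf
  for (t in 1:255) {
    lo <- vals[vals < t]
    hi <- vals[vals >= t]
    if (!length(lo) || !length(hi)) next
    vlo <- mean((lo - mean(lo))^2)
    vhi <- mean((hi - mean(hi))^2)
    within <- (length(lo) * vlo + length(hi) * vhi) / length(vals)
    if (within < best_within - 1e-12) {
      best_within <- within
      best_t <- t
    }
  }
  best_t / 255
}

oracle_moving_mean <- function(x, w) {
  n <- length(x)
  hb <- floor((w - 1) / 2)
  ha <- floor(w / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - hb):min(n, i + ha)
    out[i] <- sum(x[idx]) / length(idx)
  }
  out
}

# quartile by linear interpolation between order statistics (type 7)
oracle_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(s)) return(s[lo])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

oracle_tukey <- function(x, whisker = 0.75) {
  q1 <- oracle_quartile(x, 0.25)
  q3 <- oracle_quartile(x, 0.75)
  iqr <- q3 - q1
  x < q1 - whisker * iqr | x > q3 + whisker * iqr
}

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_mad <- function(x) {
  m <- oracle_median(x)
  oracle_median(abs(x - m))
}

oracle_rmse <- function(a, b) {
  sqrt(sum((a - b)^2) / length(a))
}

oracle_r_squared <- function(a, b) {
  sa <- a - mean(a)
  sb <- b - mean(b)
  (sum(sa * sb))^2 / (sum(sa^2) * sum(sb^2))
}

oracle_anova_f <- function(groups) {
  gm <- mean(unlist(groups))
  k <- length(groups)
  n <- length(unlist(groups))
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    ssw <- ssw + sum((g - mean(g))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

oracle_tid <- function(f, g) {
  tot <- 0
  for (ch in 1:3) {
    for (i in seq_len(dim(f)[1])) {
      for (j in seq_len(dim(f)[2])) {
        tot <- tot + abs(f[i, j, ch] - g[i, j, ch])
      }
    }
  }
  tot
}
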