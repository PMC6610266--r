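# Naive brute-force oracles: explicit loops and textbook formulas,
# deliberately independent of the package's vectorized implementations.

brute_emphysema <- function(ct, masks, thr = -950) {
  d <- dim(ct$values)
  n_low <- integer(5); n_tot <- integer(5)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    l <- masks$labels[i, j, k]
    if (l > 0L) {
      n_tot[l] <- n_tot[l] + 1L
      if (ct$values[i, j, k] < thr) n_low[l] <- n_low[l] + 1L
    }
  }
  c(100 * n_low / n_tot, 100 * sum(n_low) / sum(n_tot))
}

brute_defect <- function(sig, masks, frac = 0.05) {
  d <- dim(sig$values)
  lungv <- c()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (masks$labels[i, j, k] > 0L) lungv <- c(lungv, sig$values[i, j, k])
  }
  thr <- frac * quantile(lungv, 0.99, names = FALSE, type = 7)
  n_low <- integer(5); n_tot <- integer(5)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    l <- masks$labels[i, j, k]
    if (l > 0L) {
      n_tot[l] <- n_tot[l] + 1L
      if (sig$values[i, j, k] < thr) n_low[l] <- n_low[l] + 1L
    }
  }
  c(100 * n_low / n_tot, 100 * sum(n_low) / sum(n_tot))
}

brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

brute_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}
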