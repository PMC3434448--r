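# independent oracles, deliberately brute-force

# all permutations of 1..n (n small)
perms_all <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_all(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exact all-permutations average of the mean successive distance
exhaustive_perm_mean <- function(coords) {
  means <- vapply(perms_all(nrow(coords)), function(p) {
    mean_successive_distance(coords[p, , drop = FALSE])
  }, numeric(1))
  list(grand_mean = mean(means), means = means)
}

# UPGMA recomputing every cluster distance from the original matrix
upgma_bruteforce <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        m <- mean(cross)
        if (m < best[1]) best <- c(m, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Ljung-Box from the textbook formula
lb_oracle <- function(x, lags, fitdf = 0) {
  n <- length(x)
  rho <- stats::acf(x, lag.max = lags, plot = FALSE)$acf[-1]
  q <- n * (n + 2) * sum(rho^2 / (n - seq_len(lags)))
  list(statistic = q,
       p_value = stats::pchisq(q, df = lags - fitdf, lower.tail = FALSE))
}

# OLS by explicit normal equations
ols_normal_eq <- function(x, y) {
  xtx <- t(x) %*% x
  as.numeric(solve(xtx, t(x) %*% y))
}
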