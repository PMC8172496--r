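# Independent brute-force oracles; deliberately share no code with the
# package implementations they check.

# Benjamini-Hochberg step-up by explicit cutoff search: reject the k largest
# cutoff with p_(k) <= k q / m; adjusted p by the explicit min-over-j rule.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject_sorted <- seq_len(m) <= k
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adj <- reject <- numeric(m)
  adj[ord] <- adj_sorted
  reject[ord] <- reject_sorted
  list(p_adjusted = adj, reject = as.logical(reject))
}

# OLS extra-sum-of-squares F via normal equations solved by hand-rolled
# Gauss-Jordan elimination with partial pivoting.
oracle_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (col in seq_len(n)) {
    piv <- which.max(abs(M[col:n, col])) + col - 1L
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- M[col, ] / M[col, col]
    for (r in seq_len(n)[-col]) M[r, ] <- M[r, ] - M[r, col] * M[col, ]
  }
  M[, n + 1L]
}

oracle_f_test <- function(y, X, test_cols) {
  rss <- function(Xm) {
    beta <- oracle_solve(t(Xm) %*% Xm, as.vector(t(Xm) %*% y))
    sum((y - Xm %*% beta)^2)
  }
  rss_full <- rss(X)
  rss_red <- rss(X[, -test_cols, drop = FALSE])
  df1 <- length(test_cols)
  df2 <- nrow(X) - ncol(X)
  Fs <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(statistic = Fs, df1 = df1, df2 = df2,
       p = pf(Fs, df1, df2, lower.tail = FALSE))
}

# Arc-length resampling by an explicit per-position segment walk (no approx()).
oracle_resample <- function(poly, n_points) {
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                         poly[-nrow(poly), , drop = FALSE])^2))
  total <- sum(seg)
  out <- matrix(NA_real_, n_points, 2)
  for (i in seq_len(n_points)) {
    target <- (i - 1) / (n_points - 1) * total
    acc <- 0
    for (k in seq_along(seg)) {
      if (acc + seg[k] >= target - 1e-12) {
        f <- (target - acc) / seg[k]
        out[i, ] <- poly[k, ] * (1 - f) + poly[k + 1, ] * f
        break
      }
      acc <- acc + seg[k]
    }
  }
  out
}

# Arc-length position of each point along a source polyline, by a monotone
# walk over the source segments (points must lie on the source, in order).
oracle_arc_positions <- function(poly, pts, tol = 1e-6) {
  nseg <- nrow(poly) - 1L
  seg_len <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2))
  acc <- c(0, cumsum(seg_len))
  s <- numeric(nrow(pts))
  k <- 1L
  for (i in seq_len(nrow(pts))) {
    repeat {
      a <- poly[k, ]; v <- poly[k + 1L, ] - a
      t <- sum((pts[i, ] - a) * v) / sum(v^2)
      d <- sqrt(sum((pts[i, ] - (a + t * v))^2))
      if (t >= -1e-9 && t <= 1 + 1e-9 && d < tol) {
        s[i] <- acc[k] + max(0, min(1, t)) * seg_len[k]
        break
      }
      if (k == nseg) stop("point not found on source polyline")
      k <- k + 1L
    }
  }
  s
}

# Pointwise CDV by explicit loop (independent of compute_profile internals).
oracle_cdv <- function(upper, lower, n_points) {
  if (upper[1, 1] > upper[nrow(upper), 1]) upper <- upper[nrow(upper):1, ]
  if (lower[1, 1] > lower[nrow(lower), 1]) lower <- lower[nrow(lower):1, ]
  u <- oracle_resample(upper, n_points)
  l <- oracle_resample(lower, n_points)
  cdv <- numeric(n_points)
  for (i in seq_len(n_points)) {
    mid <- c((u[i, 1] + l[i, 1]) / 2, (u[i, 2] + l[i, 2]) / 2)
    cdv[i] <- sqrt((u[i, 1] - mid[1])^2 + (u[i, 2] - mid[2])^2)
  }
  cdv
}
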