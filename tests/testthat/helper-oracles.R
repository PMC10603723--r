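# Independent desk oracles used to cross-check the package's numerics.
# These are deliberately written from textbook definitions (normal
# equations, sum-of-squares decomposition, tridiagonal natural-spline
# system) and share no code with the implementation under test.

# OLS slope/intercept via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# One-way ANOVA F statistic from the sum-of-squares decomposition.
oracle_anova_F <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(g) - 1
  df_w <- length(y) - nlevels(g)
  (ss_between / df_b) / (ss_within / df_w)
}

# Natural cubic spline through (x, y) evaluated at xout: second
# derivatives from the tridiagonal system with M[1] = M[n] = 0, linear
# extrapolation beyond the knots (zero curvature at the boundary).
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  if (n == 2) {
    return(y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xout - x[1]))
  }
  h <- diff(x)
  A <- matrix(0, n - 2, n - 2)
  b <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    r <- i - 1
    if (r > 1) A[r, r - 1] <- h[i - 1]
    A[r, r] <- 2 * (h[i - 1] + h[i])
    if (r < n - 2) A[r, r + 1] <- h[i]
    b[r] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- c(0, solve(A, b), 0)
  d_left <- (y[2] - y[1]) / h[1] - h[1] * M[2] / 6
  d_right <- (y[n] - y[n - 1]) / h[n - 1] + h[n - 1] * M[n - 1] / 6
  vapply(xout, function(xq) {
    if (xq <= x[1]) return(y[1] + d_left * (xq - x[1]))
    if (xq >= x[n]) return(y[n] + d_right * (xq - x[n]))
    i <- findInterval(xq, x, rightmost.closed = TRUE)
    hi <- h[i]
    M[i] * (x[i + 1] - xq)^3 / (6 * hi) +
      M[i + 1] * (xq - x[i])^3 / (6 * hi) +
      (y[i] / hi - M[i] * hi / 6) * (x[i + 1] - xq) +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * (xq - x[i])
  }, numeric(1))
}

# Two-pass surface fill (rows with knots first, then columns) built on
# the oracle spline; mirrors the contract, not the implementation.
oracle_fill_surface <- function(values, determined, temp_axis, weight_axis) {
  v <- values
  for (i in seq_len(nrow(v))) {
    k <- determined[i, ]
    if (!any(k)) next
    v[i, !k] <- oracle_natural_spline(weight_axis[k], v[i, k], weight_axis[!k])
  }
  for (j in seq_len(ncol(v))) {
    have <- !is.na(v[, j])
    if (all(have)) next
    v[!have, j] <- oracle_natural_spline(temp_axis[have], v[have, j],
                                         temp_axis[!have])
  }
  v
}

# Random sparse surface instance shaped like the reference design:
# a handful of fully/partially determined temperature rows, the rest
# empty, every row used having >= 2 knots.
random_surface_instance <- function(n_temp = 5, n_wt = 8) {
  temp_axis <- sort(sample(5:30, n_temp))
  weight_axis <- sort(sample(seq(20, 200, by = 10), n_wt))
  det_rows <- sort(sample(seq_len(n_temp), sample(2:n_temp, 1)))
  determined <- matrix(FALSE, n_temp, n_wt)
  for (i in det_rows) {
    determined[i, sample(seq_len(n_wt), sample(2:n_wt, 1))] <- TRUE
  }
  values <- matrix(NA_real_, n_temp, n_wt)
  values[determined] <- round(runif(sum(determined), 5, 40), 2)
  list(values = values, determined = determined,
       temp_axis = temp_axis, weight_axis = weight_axis)
}

# Records table for build_surface() from a raw instance.
instance_records <- function(inst) {
  idx <- which(inst$determined, arr.ind = TRUE)
  tibble::tibble(
    temperature_C = inst$temp_axis[idx[, 1]],
    weight_class_g = inst$weight_axis[idx[, 2]],
    e_g = inst$values[cbind(idx[, 1], idx[, 2])]
  )
}
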