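# Independent reference implementations and small fixture builders used
# across the suite. These stay deliberately naive (exhaustive scans,
# textbook formulas) so they check the package by a different route.

# --- detection-rule oracles: exhaustive window scans ------------------------

oracle_nucleation_end <- function(deriv, t, baseline_n = 5, k_sd = 2,
                                  consecutive = 2) {
  b <- deriv[seq_len(baseline_n)]
  thr <- mean(b) + k_sd * stats::sd(b)
  for (i in seq_len(length(deriv) - consecutive + 1)) {
    if (all(deriv[i:(i + consecutive - 1)] > thr)) return(t[i])
  }
  NA_real_
}

oracle_plateau_start <- function(deriv, t, peak_index, threshold,
                                 consecutive = 2) {
  n <- length(deriv)
  lo <- peak_index + 1
  hi <- n - consecutive + 1
  if (lo <= hi) {
    for (i in lo:hi) {
      if (all(deriv[i:(i + consecutive - 1)] <= threshold)) return(t[i])
    }
  }
  NA_real_
}

oracle_peak <- function(deriv, t) {
  best <- -Inf
  bi <- NA_integer_
  for (i in seq_along(deriv)) {
    if (deriv[i] > best) {
      best <- deriv[i]
      bi <- i
    }
  }
  c(rate = best, t = t[bi])
}

# --- statistics oracles: textbook formulas ---------------------------------

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

oracle_anova1 <- function(values, groups) {
  g <- factor(groups)
  n <- length(values)
  k <- nlevels(g)
  gm <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tabulate(g)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[as.integer(g)])^2)
  dfb <- k - 1
  dfw <- n - k
  f <- (ssb / dfb) / (ssw / dfw)
  mse <- ssw / dfw
  pairs <- utils::combn(levels(g), 2)
  ph <- data.frame(a = pairs[1, ], b = pairs[2, ], diff = NA, p_adj = NA)
  for (i in seq_len(ncol(pairs))) {
    ia <- pairs[1, i]; ib <- pairs[2, i]
    se <- sqrt(mse / 2 * (1 / ns[which(levels(g) == ia)] +
                            1 / ns[which(levels(g) == ib)]))
    q <- abs(means[ia] - means[ib]) / se
    ph$diff[i] <- means[ib] - means[ia]
    ph$p_adj[i] <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
  }
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE), posthoc = ph)
}

# Type-II sums of squares for an unbalanced two-way factorial, via residual
# sums of nested least-squares fits.
oracle_anova2_type2 <- function(values, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  rss <- function(fml) sum(stats::resid(stats::lm(fml))^2)
  r_full <- rss(values ~ fa * fb)
  r_ab <- rss(values ~ fa + fb)
  r_a <- rss(values ~ fa)
  r_b <- rss(values ~ fb)
  df_a <- nlevels(fa) - 1
  df_b <- nlevels(fb) - 1
  df_ab <- df_a * df_b
  df_res <- length(values) - nlevels(fa) * nlevels(fb)
  mse <- r_full / df_res
  f <- c(A = (r_b - r_ab) / df_a, B = (r_a - r_ab) / df_b,
         `A:B` = (r_ab - r_full) / df_ab) / mse
  p <- stats::pf(f, c(df_a, df_b, df_ab), df_res, lower.tail = FALSE)
  list(F = f, p = p)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# --- geometry helpers -------------------------------------------------------

# 90 degree counter-clockwise rotation of a matrix.
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

point_segment_dist <- function(px, py, seg) {
  dx <- seg[3] - seg[1]; dy <- seg[4] - seg[2]
  len2 <- dx^2 + dy^2
  s <- if (len2 == 0) 0 else
    min(1, max(0, ((px - seg[1]) * dx + (py - seg[2]) * dy) / len2))
  sqrt((seg[1] + s * dx - px)^2 + (seg[2] + s * dy - py)^2)
}

min_dist_to_segments <- function(px, py, segs) {
  min(vapply(seq_len(nrow(segs)),
             function(i) point_segment_dist(px, py, segs[i, ]), 0))
}

# Binary plus-sign (cross) of arm length `arm` centred in an n x n matrix.
make_plus <- function(n = 15, arm = 5) {
  m <- matrix(0, n, n)
  c0 <- (n + 1) %/% 2
  m[c0, (c0 - arm):(c0 + arm)] <- 1
  m[(c0 - arm):(c0 + arm), c0] <- 1
  m
}

# Rows realised from i.i.d. exponential gaps (ceiling-discretised so the
# run-length histogram is exactly geometric with the same rate).
make_exp_gap_matrix <- function(nrow = 200, ncol = 2000, mean_gap = 15) {
  m <- matrix(0, nrow, ncol)
  for (r in seq_len(nrow)) {
    pos <- 1
    while (pos <= ncol) {
      m[r, pos] <- 1
      pos <- pos + 1 + ceiling(stats::rexp(1, 1 / mean_gap))
    }
  }
  m
}

# Render Gaussian spots at given (x, y) pixel positions into a matrix.
render_spots <- function(nr, nc, x, y, sigma = 1.2) {
  m <- matrix(0, nr, nc)
  w <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    rr <- max(1, round(y[i]) - w):min(nr, round(y[i]) + w)
    cc <- max(1, round(x[i]) - w):min(nc, round(x[i]) + w)
    m[rr, cc] <- m[rr, cc] + exp(-outer((rr - y[i])^2, (cc - x[i])^2, "+") /
                                   (2 * sigma^2))
  }
  m
}

# Random derivative-like series for oracle-equivalence scans: a mix of pure
# noise, noisy sigmoid slopes, and flat series with spikes.
random_deriv_series <- function() {
  n <- sample(10:60, 1)
  kind <- sample(3, 1)
  if (kind == 1) {
    stats::rnorm(n)
  } else if (kind == 2) {
    tm <- stats::runif(1, 2, n - 2)
    tau <- stats::runif(1, 0.5, 5)
    exp(-((seq_len(n) - tm) / tau)^2) + stats::rnorm(n, 0, 0.2)
  } else {
    s <- rep(stats::rnorm(1), n)
    s[sample(n, 2)] <- stats::rnorm(2, 0, 5)
    s
  }
}
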