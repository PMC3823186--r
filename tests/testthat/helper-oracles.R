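# Independent oracles used across the suite.  These are deliberately written
# as literal, brute-force implementations (explicit loops, textbook formulas)
# so that agreement with the package is a genuine cross-check, not a
# tautology.

# per-window max-minus-min by exhaustive scan, O(n * w)
oracle_window_ranges <- function(axes, w) {
  n <- nrow(axes)
  np <- n - w + 1L
  rng <- matrix(NA_real_, np, 3L)
  for (p in seq_len(np)) {
    for (a in 1:3) {
      seg <- axes[p:(p + w - 1L), a]
      rng[p, a] <- max(seg) - min(seg)
    }
  }
  rng
}

# Literal reading of the detection rule: a movement is a maximal run of
# window positions whose range exceeds the threshold on at least one axis,
# accepted only if the q window positions immediately before and after all
# have ranges below the threshold on every axis.
oracle_detect <- function(axes, w, q, thr) {
  np <- nrow(axes) - w + 1L
  if (np < 1L) return(data.frame(first = integer(0), last = integer(0)))
  rng <- oracle_window_ranges(axes, w)
  events <- list()
  p <- 1L
  while (p <= np) {
    if (any(rng[p, ] > thr)) {
      l <- p
      while (l < np && any(rng[l + 1L, ] > thr)) l <- l + 1L
      ok <- (p - q >= 1L) && (l + q <= np)
      if (ok) {
        for (j in (p - q):(p - 1L)) {
          if (!all(rng[j, ] < thr)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        for (j in (l + 1L):(l + q)) {
          if (!all(rng[j, ] < thr)) { ok <- FALSE; break }
        }
      }
      if (ok) events[[length(events) + 1L]] <- c(first = p, last = l)
      p <- l + 1L
    } else {
      p <- p + 1L
    }
  }
  if (!length(events)) return(data.frame(first = integer(0), last = integer(0)))
  as.data.frame(do.call(rbind, events))
}

# Random trace mixing quiet noise, borderline and clear bursts, so that the
# threshold, run-merging and quiescence logic all get exercised.
random_test_trace <- function(sr = 100) {
  dur <- runif(1, 2, 8)
  n <- as.integer(round(dur * sr))
  noise_sd <- runif(1, 0.005, 0.1)
  axes <- matrix(rnorm(n * 3L, sd = noise_sd), ncol = 3L)
  axes <- sweep(axes, 2L, runif(3, -10, 10), "+")
  n_burst <- sample(0:4, 1L)
  for (b in seq_len(n_burst)) {
    amp <- runif(1, 0.05, 0.6)
    dur_b <- as.integer(round(runif(1, 0.1, 0.6) * sr))
    s0 <- sample.int(max(1L, n - dur_b), 1L)
    a <- sample.int(3L, 1L)
    axes[s0:(s0 + dur_b - 1L), a] <-
      axes[s0:(s0 + dur_b - 1L), a] + (amp / 2) * sin(2 * pi * seq(0, 1, length.out = dur_b))
  }
  accel_trace(axes[, 1L], axes[, 2L], axes[, 3L], sr, "intact")
}

# ---- textbook statistical formulas -----------------------------------------

oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_one_sample_t <- function(x) {
  t <- mean(x) / (sd(x) / sqrt(length(x)))
  list(t = t, df = length(x) - 1, p = 2 * pt(-abs(t), length(x) - 1))
}

# U as the direct count of pairs where a beats b (ties count 1/2); exact
# two-sided p by complete enumeration of group assignments.
oracle_mann_whitney <- function(a, b) {
  U <- 0
  for (x in a) for (y in b) U <- U + (x > y) + 0.5 * (x == y)
  pooled <- c(a, b)
  n1 <- length(a)
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2L, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    u <- 0
    for (x in aa) for (y in bb) u <- u + (x > y) + 0.5 * (x == y)
    u
  })
  p_lo <- mean(us <= U); p_hi <- mean(us >= U)
  list(U = U, p = min(1, 2 * min(p_lo, p_hi)))
}

# Balanced mixed-design (one between factor, two-level within factor)
# sums-of-squares decomposition done long-hand.
oracle_mixed_anova_F <- function(values, group, subject, limb) {
  grand <- mean(values)
  a <- length(unique(group)); b <- length(unique(limb))
  N <- length(unique(subject))
  n <- N / a                                   # per-group size (balanced)
  subj_mean <- tapply(values, subject, mean)
  subj_group <- tapply(group, subject, function(g) g[1])
  grp_mean <- tapply(values, group, mean)
  limb_mean <- tapply(values, limb, mean)
  cell_mean <- tapply(values, list(group, limb), mean)

  ss_between_subj <- b * sum((subj_mean - grand)^2)
  ss_group <- n * b * sum((grp_mean - grand)^2)
  ss_limb <- n * a * sum((limb_mean - grand)^2)
  ss_int <- 0
  for (g in rownames(cell_mean)) for (l in colnames(cell_mean)) {
    ss_int <- ss_int + n * (cell_mean[g, l] - grp_mean[g] - limb_mean[l] + grand)^2
  }
  ss_total <- sum((values - grand)^2)
  ss_err_within <- ss_total - ss_between_subj - ss_limb - ss_int
  df_int <- (a - 1) * (b - 1)
  df_err <- (N - a) * (b - 1)
  Fval <- unname((ss_int / df_int) / (ss_err_within / df_err))
  list(F = Fval, df = c(df_int, df_err), p = pf(Fval, df_int, df_err, lower.tail = FALSE))
}

# Group F from explicit residual sums of squares of nested least-squares
# fits, solved through the normal equations (no lm()).
oracle_nested_F <- function(y, group, covs) {
  g <- as.numeric(factor(group)) - 1
  X_full <- cbind(1, g, covs)
  X_red <- cbind(1, covs)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss_f <- rss(X_full); rss_r <- rss(X_red)
  df2 <- length(y) - ncol(X_full)
  Fval <- (rss_r - rss_f) / (rss_f / df2)
  list(F = Fval, df = c(1, df2), p = pf(Fval, 1, df2, lower.tail = FALSE))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2, p = 2 * pt(-abs(t), n - 2))
}

# partial r by explicit two-stage simple/multiple regression residuals
oracle_partial <- function(x, y, z) {
  z <- as.matrix(z)
  D <- cbind(1, z)
  beta_x <- solve(t(D) %*% D, t(D) %*% x)
  beta_y <- solve(t(D) %*% D, t(D) %*% y)
  rx <- x - D %*% beta_x
  ry <- y - D %*% beta_y
  r <- oracle_pearson(as.numeric(rx), as.numeric(ry))$r
  df <- length(x) - 2 - ncol(z)
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p_two = 2 * pt(-abs(t), df), p_less = pt(t, df))
}

oracle_fisher_z <- function(r1, n1, r2, n2) {
  z <- (0.5 * log((1 + r1) / (1 - r1)) - 0.5 * log((1 + r2) / (1 - r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Minimal high-SNR simulation parameters reused by recovery tests: clear
# bursts, near-noiseless baseline, events well separated.
high_snr_params <- function(seed, duration_s = 300) {
  accel_sim_params(duration_s = duration_s, rate_intact = 6, rate_residual = 2,
                   coupled_rate = 1, burst_amp = 0.5, noise_sd = 0.02,
                   seed = seed)
}
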