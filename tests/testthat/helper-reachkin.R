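# Shared fixtures and independent oracles, all built in code.

# Analytic single-kernel trial: one 0.3 m minimum-jerk reach along x,
# 1 s long, starting at 0.5 s, sampled at 100 Hz over 2 s.
analytic_trial <- function(displacement = c(0.3, 0, 0), start = 0.5,
                           duration = 1, sample_rate = 100, t_end = 2) {
  t <- seq(0, t_end, by = 1 / sample_rate)
  k <- submovement_kernel(start, duration, displacement)
  tr <- render_submovements(list(k), t)
  list(t = t, kernel = k, traj = tr,
       rec = trial_recording("ORACLE", "TD", 1L, sample_rate, t,
                             pos = tr$pos, acc = tr$acc,
                             trigger_time = 0, end_time = t_end))
}

# Brute-force sign-change scan: the independent oracle for zero crossings.
brute_sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

# Hand-coded one-way ANOVA from sums of squares.
oracle_anova <- function(groups) {
  y <- unlist(groups)
  ns <- lengths(groups)
  gm <- mean(y)
  ssb <- sum(ns * (sapply(groups, mean) - gm)^2)
  ssw <- sum(sapply(groups, function(v) sum((v - mean(v))^2)))
  dfb <- length(groups) - 1
  dfw <- length(y) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# Welch two-sample t from the textbook formula.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tt <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# Pearson r from the covariance formula and its t-transform p-value.
oracle_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# Step-up Benjamini-Hochberg by direct scan.
oracle_bh <- function(p, q) {
  m <- length(p)
  if (m == 0L) return(logical(0L))
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  flags <- logical(m)
  if (length(k) > 0L) flags[o[seq_len(max(k))]] <- TRUE
  flags
}

# Two Gaussian clouds separated by `sep` sd along every feature.
gaussian_clouds <- function(seed, n_per_class = 200, sep = 4,
                            features = classifier_config()$feature_set) {
  set.seed(seed)
  p <- length(features)
  X <- rbind(matrix(stats::rnorm(n_per_class * p), n_per_class, p),
             matrix(stats::rnorm(n_per_class * p, mean = sep), n_per_class, p))
  colnames(X) <- features
  list(X = X, y = rep(c(0, 1), each = n_per_class))
}

cohort_feature_table <- function(spec) {
  co <- simulate_cohort(spec)
  extract_cohort_features(co$trials, co$manifest)
}
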