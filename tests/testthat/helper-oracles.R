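# Independent oracles used to freeze expected values: brute-force
# enumeration and numerical integration, deliberately avoiding the code
# paths they check.

# all valid window start indices by direct enumeration
enumerate_window_starts <- function(stream_length, window, hop) {
  starts <- integer(0)
  s <- 0L
  while (s + window <= stream_length) {
    starts <- c(starts, s)
    s <- s + hop
  }
  starts
}

# two-sided t-test p-value by numerical integration of the t density
p_from_t_integration <- function(t, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t), Inf)$value
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mann_whitney_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2L, u_stat)
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns
wilcoxon_exact_p <- function(z) {
  z <- z[z != 0]
  n <- length(z)
  stopifnot(n > 0, !anyDuplicated(abs(z)))
  r <- rank(abs(z))
  v_obs <- sum(r[z > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  all_v <- as.vector(signs %*% r)
  min(1, 2 * min(mean(all_v <= v_obs), mean(all_v >= v_obs)))
}

# a minimal valid stream of a given length for windowing tests
constant_stream <- function(n, rate = 21) {
  sensor_stream(data.frame(
    t = if (n > 0) (seq_len(n) - 1) / rate else numeric(0),
    flex_middle = rep(2048L, n), flex_thumb = rep(1024L, n),
    ax = rep(0, n), ay = rep(0, n), az = rep(9.81, n),
    gx = rep(0, n), gy = rep(0, n), gz = rep(0, n)),
    sampling_rate = rate)
}

# small two-exercise dataset shared across classifier tests
small_dataset <- function(seed = 1, n_per_class = 4, noise_sd = 0.35) {
  models <- lapply(exercise_catalog()[1:2], exercise_signal_model,
                   noise_sd = noise_sd)
  build_dataset(models, n_per_class = n_per_class, duration_seconds = 6,
                seed = seed)
}
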