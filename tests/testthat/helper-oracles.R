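# Independent oracles used across the suite.

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
enumerate_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Mann-Whitney p by enumeration of all C(n+m, n) rank splits
enumerate_rank_sum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  rr <- rank(seq_len(n + m))  # pooled ranks are 1..n+m for distinct data
  w_all <- apply(splits, 2, function(idx) sum(rr[idx])) - n * (n + 1) / 2
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force duration rule: check every 3-bin window start explicitly
brute_force_duration <- function(post_rates, baseline, bin_width) {
  n <- length(post_rates)
  means <- vapply(seq_len(n - 2), function(s) mean(post_rates[s:(s + 2)]), 0)
  hit <- which(means <= baseline)
  if (length(hit) == 0) return(list(duration = n * bin_width, capped = TRUE))
  list(duration = (hit[1] - 1) * bin_width, capped = FALSE)
}

# event train at given times with safe default amplitudes
train_at <- function(times, amp = -20, source = "truth") {
  event_train(sort(times), rep(amp, length(times)), source = source)
}

# ground-truth train with amplitude magnitudes resampled to >= floor_pA
truncate_truth_amplitudes <- function(gt, cfg, floor_pA) {
  a <- abs(gt$amplitude_pA)
  bad <- which(a < floor_pA)
  while (length(bad) > 0) {
    a[bad] <- epsctools:::sample_epsc_amplitudes(length(bad), cfg)
    bad <- bad[a[bad] < floor_pA]
  }
  gt$amplitude_pA <- -a
  gt
}
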