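test_that("histogram bin arithmetic and averaging behave as defined", {
  # 10 events inside one 0.1 s bin -> 100 events/s in that bin
  tr <- train_at(2.2 + seq(0.001, 0.099, length.out = 10))
  h <- bin_events(tr, burst_end = 2.2, t_max = 3)
  i0 <- which(abs(h$bin_edges[-length(h$bin_edges)] - 2.2) < 1e-9)
  expect_equal(h$rates[i0], 100)
  expect_equal(sum(h$rates), 100)

  # averaging three identical trains changes nothing
  h3 <- bin_events(list(tr, tr, tr), burst_end = 2.2, t_max = 3)
  expect_equal(h3$rates, h$rates)

  # counts 1, 2, 3 in a bin across three trains -> (1+2+3)/3/0.1 = 20
  t1 <- train_at(2.25); t2 <- train_at(c(2.24, 2.26)); t3 <- train_at(c(2.22, 2.25, 2.28))
  hm <- bin_events(list(t1, t2, t3), burst_end = 2.2, t_max = 3)
  i0 <- which(abs(hm$bin_edges[-length(hm$bin_edges)] - 2.2) < 1e-9)
  expect_equal(hm$rates[i0], 20)

  # grid is anchored at burst end
  expect_true(any(abs(hm$bin_edges - 2.2) < 1e-12))
  expect_error(bin_events(list(), 2.2, t_max = 3), "at least one")
})

test_that("baseline rate is events per second per trace", {
  expect_equal(baseline_rate(train_at(numeric(0), numeric(0)), c(0, 2)), 0)
  tr <- train_at(seq(0.1, 4.9, length.out = 5))
  expect_equal(baseline_rate(list(tr, tr, tr), c(0, 5)), 1.0)
  expect_error(baseline_rate(tr, c(2, 2)), "positive length")

  # Poisson recovery: lambda = 10
  cfg <- sim_config(baseline_rate = 10, elevation_amplitude = 0,
                    trace_duration = 10)
  set.seed(61)
  est <- replicate(200, baseline_rate(sample_event_times(cfg), c(0, 2)))
  se <- sqrt(10 / (2 * 200))
  expect_lt(abs(mean(est) - 10), 3 * se)
})

test_that("duration rule matches the hand-computed staircase example", {
  # one train, counts per 0.1 s bin: 5,4,3,2,2,1,1,1 then silence;
  # baseline 10 events/s = 1 count/bin; triplet means 40,30,23.3,16.7,
  # 13.3,10,... -> first triplet <= baseline starts at bin 6 -> 0.5 s
  counts <- c(5, 4, 3, 2, 2, 1, 1, 1)
  times <- unlist(lapply(seq_along(counts), function(b)
    2.2 + (b - 1) * 0.1 + seq_len(counts[b]) * 0.01))
  h <- bin_events(train_at(times), burst_end = 2.2, t_max = 4)
  res <- duration_of_increase(h, baseline = 10)
  expect_equal(res$duration, 0.5)
  expect_false(res$capped)

  # immediately at/below baseline -> duration 0
  h0 <- bin_events(train_at(2.25), burst_end = 2.2, t_max = 4)
  expect_equal(duration_of_increase(h0, baseline = 50)$duration, 0)

  # never returns -> capped at the post-burst extent
  times_hi <- 2.2 + seq(0.005, 1.795, by = 0.045)
  hc <- bin_events(train_at(times_hi), burst_end = 2.2, t_max = 4)
  resc <- duration_of_increase(hc, baseline = 0)
  expect_true(resc$capped)
  expect_equal(resc$duration, 1.8)

  expect_error(
    duration_of_increase(bin_events(train_at(2.25), 2.2, t_max = 2.45),
                         baseline = 1), "3 post-burst bins")
})

test_that("duration rule equals the brute-force triplet scan on random inputs", {
  set.seed(71)
  for (i in 1:100) {
    nb <- sample(5:60, 1)
    counts <- rpois(nb, lambda = runif(1, 0, 8))
    times <- unlist(lapply(seq_len(nb), function(b) {
      k <- counts[b]
      if (k == 0) return(numeric(0))
      2.2 + (b - 1) * 0.1 + seq_len(k) * (0.1 / (k + 1))
    }))
    h <- bin_events(train_at(times), burst_end = 2.2,
                    t_max = 2.2 + nb * 0.1)
    base <- runif(1, 0, 60)
    got <- duration_of_increase(h, base)
    want <- brute_force_duration(h$rates[h$bin_edges[-length(h$bin_edges)]
                                         >= 2.2 - 1e-9], base, 0.1)
    expect_identical(got$duration, want$duration)
    expect_identical(got$capped, want$capped)
  }
})

test_that("sliding and disjoint triplet conventions differ as documented", {
  counts <- c(5, 5, 5, 0, 0, 0, 5, 5, 5, 0, 0, 0)
  times <- unlist(lapply(seq_along(counts), function(b)
    2.2 + (b - 1) * 0.1 + seq_len(max(counts[b], 0)) * 0.01))
  h <- bin_events(train_at(times), burst_end = 2.2, t_max = 3.4)
  s <- duration_of_increase(h, baseline = 20, mode = "sliding")
  d <- duration_of_increase(h, baseline = 20, mode = "disjoint")
  expect_equal(s$duration, 0.2)   # first qualifying triplet is bins 3-5
  expect_equal(d$duration, 0.3)   # disjoint stepping only tries bins 4-6
  e <- duration_of_increase(h, baseline = 20, endpoint = "end")
  expect_equal(e$duration, s$duration + 0.3)
})

test_that("post-burst 1-s frequency is counted in the right window", {
  tr <- train_at(2.2 + seq(0.01, 0.99, length.out = 30))
  expect_equal(post_burst_rate(tr, 2.2, t_max = 4), 30)
  expect_equal(post_burst_rate(train_at(numeric(0), numeric(0)), 2.2,
                               t_max = 4), 0)
  expect_error(post_burst_rate(tr, 2.2, t_max = 2.5), "insufficient")
  # events during the burst itself do not count
  tr2 <- train_at(c(2.05, 2.1, 2.5))
  expect_equal(post_burst_rate(tr2, 2.2, t_max = 4), 1)
})

test_that("percent reduction is per neuron, then averaged", {
  expect_equal(as.numeric(percent_reduction(2.6, 0.9)), 65.38462,
               tolerance = 1e-6)
  expect_equal(as.numeric(percent_reduction(3, 3)), 0)
  # mean of per-neuron ratios differs from ratio of means
  red <- percent_reduction(c(2, 4), c(1, 1))
  expect_equal(mean(red), 62.5)
  expect_false(isTRUE(all.equal(mean(red),
                                100 * (1 - sum(c(1, 1)) / sum(c(2, 4))))))
  # non-positive control excluded with flag
  red2 <- percent_reduction(c(0, 2), c(1, 1))
  expect_true(is.na(red2[1]))
  expect_identical(attr(red2, "excluded"), c(TRUE, FALSE))
})

test_that("measured duration grows with the elevation time constant", {
  set.seed(81)
  means <- vapply(c(0.5, 1, 2), function(tau) {
    cfg <- sim_config(elevation_tau = tau, trace_duration = 14)
    coh <- generate_cohort(50, cfg, NULL, render = FALSE)
    m <- quantify_cohort(coh, use_truth = TRUE)
    mean(m$value[m$metric == "duration_s"])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("truth-fed post-burst rate matches the rate-model expectation", {
  cfg <- sim_config()
  expected <- cfg$baseline_rate +
    cfg$elevation_amplitude * cfg$elevation_tau *
      (1 - exp(-1 / cfg$elevation_tau))
  set.seed(91)
  # no per-neuron random effects so the closed form applies exactly
  rates <- replicate(80, {
    trains <- replicate(3, sample_event_times(cfg), simplify = FALSE)
    post_burst_rate(trains, 2.2, t_max = 10)
  })
  se <- sqrt(expected / (3 * 80))
  expect_lt(abs(mean(rates) - expected), 3 * se)
})
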