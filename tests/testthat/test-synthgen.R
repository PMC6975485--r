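test_that("event counts follow the inhomogeneous Poisson rate integral", {
  # constant rate: lambda = 10/s over 10 s, mean count 100
  cfg <- sim_config(baseline_rate = 10, elevation_amplitude = 0,
                    elevation_tau = 1, trace_duration = 10)
  set.seed(101)
  counts <- replicate(1000, nrow(sample_event_times(cfg)))
  se <- sqrt(100 / 1000)
  expect_lt(abs(mean(counts) - 100), 3 * se)

  # burst-added events: expected extra count = A * tau * (1 - exp(-(T-tb)/tau))
  cfg2 <- sim_config(baseline_rate = 0, elevation_amplitude = 20,
                     elevation_tau = 1, trace_duration = 12,
                     burst_start = 1)
  expected <- 20 * 1 * (1 - exp(-(12 - 1.2) / 1))
  set.seed(102)
  extra <- replicate(500, nrow(sample_event_times(cfg2)))
  se2 <- sqrt(expected / 500)
  expect_lt(abs(mean(extra) - expected), 3 * se2)
})

test_that("zero rates give an empty train and all invariants hold", {
  cfg <- sim_config(baseline_rate = 0, elevation_amplitude = 0, seed = 3)
  gt <- sample_event_times(cfg)
  expect_s3_class(gt, "ground_truth")
  expect_equal(nrow(gt), 0)

  cfg2 <- sim_config(seed = 5)
  gt2 <- sample_event_times(cfg2)
  expect_true(all(diff(gt2$time_s) > 0))
  expect_true(all(gt2$time_s >= 0 & gt2$time_s <= cfg2$trace_duration))
  expect_true(all(gt2$amplitude_pA < 0))
  # truncation floor: no magnitude below 1.5 * noise_sd
  expect_true(all(abs(gt2$amplitude_pA) >= 1.5 * cfg2$noise_sd))
})

test_that("drug effects scale the elevation and are validated", {
  expect_error(drug_effect("X", rate_scale = 1.2), "rate_scale")
  cfg <- sim_config(baseline_rate = 0, elevation_amplitude = 40,
                    elevation_tau = 1, trace_duration = 12)
  eff <- drug_effect("NAS", rate_scale = 0.5, tau_scale = 0.5)
  set.seed(7)
  n_drug <- mean(replicate(400, nrow(sample_event_times(cfg, eff))))
  expected <- 20 * 0.5 * (1 - exp(-10.8 / 0.5))
  expect_lt(abs(n_drug - expected), 3 * sqrt(expected / 400))
})

test_that("same seed reproduces traces and truths; different seeds differ", {
  cfg <- sim_config(trace_duration = 4, seed = 11)
  gt1 <- sample_event_times(cfg)
  gt2 <- sample_event_times(cfg)
  expect_identical(gt1, gt2)
  tr1 <- render_trace(gt1, cfg)
  tr2 <- render_trace(gt1, cfg)
  expect_identical(tr1$samples, tr2$samples)
  gt3 <- sample_event_times(cfg, seed = 12)
  expect_false(identical(gt1$time_s, gt3$time_s))
})

test_that("rendered kernels are peak-normalized and reconstructable", {
  cfg <- sim_config(noise_sd = 0, artifact_amplitude = 0,
                    trace_duration = 4, burst_start = 1)
  one <- event_train(2.0, -20, source = "truth")
  class(one) <- c("ground_truth", class(one))
  tr <- render_trace(one, cfg)
  expect_lt(abs(min(tr$samples) - (-20)) / 20, 0.01)

  # empty truth, no noise: flat zero everywhere (no artifact rendered)
  empty <- sample_event_times(sim_config(baseline_rate = 0,
                                         elevation_amplitude = 0,
                                         noise_sd = 0, seed = 1))
  tr0 <- render_trace(empty, cfg)
  expect_true(all(tr0$samples == 0))

  # subtracting independently computed kernels recovers a flat baseline
  gt <- sample_event_times(sim_config(seed = 21, noise_sd = 0,
                                      trace_duration = 4))
  cfg0 <- sim_config(noise_sd = 0, artifact_amplitude = 0,
                     trace_duration = 4)
  trk <- render_trace(gt, cfg0)
  tt <- trace_times(trk)
  t_pk <- with(cfg0, tau_rise * tau_decay / (tau_decay - tau_rise) *
                 log(tau_decay / tau_rise))
  pk <- with(cfg0, exp(-t_pk / tau_decay) - exp(-t_pk / tau_rise))
  recon <- numeric(length(tt))
  for (j in seq_len(nrow(gt))) {
    u <- tt - (gt$time_s[j] - t_pk)
    on <- u >= 0
    recon[on] <- recon[on] + gt$amplitude_pA[j] *
      (exp(-u[on] / cfg0$tau_decay) - exp(-u[on] / cfg0$tau_rise)) / pk
  }
  expect_lt(max(abs(trk$samples - recon)), 1e-9)
})

test_that("rendered noise has the configured SD", {
  cfg <- sim_config(baseline_rate = 0, elevation_amplitude = 0,
                    noise_sd = 2, artifact_amplitude = 0, seed = 31)
  tr <- render_trace(sample_event_times(cfg), cfg)
  expect_lt(abs(stats::sd(tr$samples) - 2) / 2, 0.05)
})

test_that("puff responses follow the driving-force model", {
  # holding at reversal: no deflection
  p0 <- generate_puff_response(300, 1, holding = -10, reversal = -10)
  expect_equal(max(abs(p0$trace$samples)), 0)

  # ohmic: responses at +40 / -60 mV from reversal have ratio -2/3
  pp <- generate_puff_response(300, 1, holding = 40, reversal = 0)
  pm <- generate_puff_response(300, 1, holding = -60, reversal = 0)
  expect_equal(puff_peak(pp) / puff_peak(pm), -2 / 3, tolerance = 1e-12)

  # rectification parameter propagates to the RI exactly
  pr <- generate_puff_response(300, 1, holding = 40, reversal = 0,
                               rectification = 0.5)
  ri <- rectification_index(puff_peak(pr), puff_peak(pm))
  expect_equal(ri$RI, 0.5, tolerance = 1e-12)
  expect_identical(ri$classification, "inward")
})

test_that("cohorts have the paired structure and known truth", {
  cfg <- sim_config(trace_duration = 5)
  eff <- drug_effect("NAS", 0.6, 0.5)
  coh <- generate_cohort(8, cfg, eff, traces_per_neuron = 3, seed = 41)
  expect_length(coh, 8)
  for (rec in coh) {
    expect_setequal(names(rec$conditions), c("control", "NAS"))
    for (cond in rec$conditions) {
      expect_length(cond$traces, 3)
      expect_length(cond$truths, 3)
    }
  }
  coh2 <- generate_cohort(8, cfg, eff, traces_per_neuron = 3, seed = 41)
  expect_identical(coh[[3]]$conditions$control$truths,
                   coh2[[3]]$conditions$control$truths)
})

test_that("a null drug effect leaves control and drug exchangeable", {
  cfg <- sim_config()
  veh <- drug_effect("VEH", 1, 1)
  set.seed(51)
  n_sig <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    coh <- generate_cohort(8, cfg, veh, render = FALSE)
    m <- quantify_cohort(coh, use_truth = TRUE)
    dc <- m$value[m$metric == "duration_s" & m$condition == "control"]
    dd <- m$value[m$metric == "duration_s" & m$condition == "VEH"]
    p <- tryCatch(run_test("paired_t", dc, dd)$p, error = function(e) 1)
    if (p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / reps, 0.10)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(trace_duration = 1, burst_start = 2), "exceed")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(tau_rise = 0.01, tau_decay = 0.005), "tau_decay")
  expect_error(sim_config(elevation_tau = 0), "elevation_tau")
})
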