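test_that("RI arithmetic and classification follow the conductance ratio", {
  # ohmic conductance g = 5 nS: +200 pA at +40, -300 pA at -60 -> RI 1
  r <- rectification_index(200, -300)
  expect_equal(r$RI, 1.0)
  expect_identical(r$classification, "outward")

  r2 <- rectification_index(100, -300)
  expect_equal(r2$RI, 0.5)
  expect_identical(r2$classification, "inward")

  expect_identical(rectification_index(0.67 * 200, -300)$classification,
                   "inward")
  expect_identical(rectification_index(1.28 * 200, -300)$classification,
                   "outward")
  expect_error(rectification_index(100, 0), "non-zero")
})

test_that("ohmic puff responses give RI exactly 1 across g and reversal", {
  for (g in c(0.5, 2, 5, 20)) {
    for (rev in c(-20, -7, 0, 13, 20)) {
      pp <- generate_puff_response(60 * g, 0.8, holding = rev + 40,
                                   reversal = rev)
      pm <- generate_puff_response(60 * g, 0.8, holding = rev - 60,
                                   reversal = rev)
      ri <- rectification_from_puffs(pp, pm)
      expect_equal(ri$RI, 1.0, tolerance = 1e-12)
    }
  }
})

test_that("reversal potential interpolation brackets the zero crossing", {
  expect_equal(find_reversal(c(-300, 200), c(-60, 40)), 0)
  expect_equal(find_reversal(c(-150, 0, 80), c(-30, 0, 20)), 0)
  expect_equal(find_reversal(c(-100, 100), c(-10, 30)), 10)
  expect_error(find_reversal(c(-100, -50), c(-60, 40)), "bracket")
})

test_that("NMDA/AMPA ratio uses baseline-subtracted peak magnitudes", {
  nmda <- generate_puff_response(58.5, 1.5, holding = 40, reversal = 0,
                                 agonist = "NMDA")
  ampa <- generate_puff_response(6000 / 70, 0.5, holding = -70,
                                 reversal = 0, agonist = "KA")
  expect_equal(abs(puff_peak(nmda)), 39, tolerance = 1e-9)
  expect_equal(abs(puff_peak(ampa)), 100, tolerance = 1e-9)
  expect_equal(nmda_ampa_ratio(nmda, ampa), 0.39, tolerance = 1e-9)

  # scale invariance: doubling both peaks leaves the ratio unchanged
  nmda2 <- generate_puff_response(117, 1.5, holding = 40, agonist = "NMDA")
  ampa2 <- generate_puff_response(12000 / 70, 0.5, holding = -70)
  expect_equal(nmda_ampa_ratio(nmda2, ampa2), 0.39, tolerance = 1e-9)

  # equal magnitudes -> 1
  nmda3 <- generate_puff_response(150, 1, holding = 40, agonist = "NMDA")
  ampa3 <- generate_puff_response(6000 / 70, 1, holding = -70)
  expect_equal(nmda_ampa_ratio(nmda3, ampa3), 1.0, tolerance = 1e-9)

  expect_error(nmda_ampa_ratio(ampa, nmda), "\\+40")
})

test_that("charge transfer integrates 10 s of baseline-subtracted current", {
  # rectangle: constant 10 pA for >= 10 s, C = 50 pF -> 100 pC, 2 pC/pF
  fs <- 1000
  x <- c(numeric(fs), rep(10, 11 * fs))
  rect <- list(trace = epsc_trace(x, fs), puff_time = 1)
  ct <- charge_transfer(rect, capacitance_pF = 50)
  expect_equal(ct$charge_pC, 100, tolerance = 1e-3)
  expect_equal(ct$charge_per_pF, 2, tolerance = 1e-3)

  # zero current -> zero charge
  flat <- list(trace = epsc_trace(numeric(12 * fs), fs), puff_time = 0.5)
  expect_equal(charge_transfer(flat, 50)$charge_pC, 0)

  # monoexponential peak 100 pA, tau 1 s: closed form A*tau*(1-exp(-10))
  pr <- generate_puff_response(150, 1, holding = 40, reversal = 0)
  expect_equal(abs(puff_peak(pr)), 100, tolerance = 1e-9)
  want <- 100 * 1 * (1 - exp(-10))
  got <- charge_transfer(pr, 50)$charge_pC
  expect_lt(abs(got - want) / want, 0.01)

  expect_error(charge_transfer(rect, 0), "capacitance")
  short <- list(trace = epsc_trace(numeric(5 * fs), fs), puff_time = 1)
  expect_error(charge_transfer(short, 50), "shorter")
})

test_that("charge transfer is additive and offset-invariant after subtraction", {
  pr <- generate_puff_response(150, 1, holding = 40, reversal = 0)
  full <- charge_transfer(pr, 1, window = 10)$charge_pC
  first <- charge_transfer(pr, 1, window = 5)$charge_pC
  # remaining sub-interval integrated independently (baseline is 0 here)
  tt <- trace_times(pr$trace)
  sel <- tt >= pr$puff_time + 5 & tt <= pr$puff_time + 10
  y <- pr$trace$samples[sel]
  second <- sum((y[-1] + y[-length(y)]) / 2) / pr$trace$sampling_rate
  expect_equal(full, first + abs(second), tolerance = 1e-9)

  off <- pr
  off$trace$samples <- off$trace$samples + 35
  expect_equal(charge_transfer(off, 1)$charge_pC, full, tolerance = 1e-9)
})

test_that("input capacitance is recovered within 2% across the RC grid", {
  for (C in c(20, 50, 100, 200)) {
    for (Rs in c(5, 20)) {
      sr <- simulate_capacitance_step(C, Rs, dV_mV = 10)
      est <- input_capacitance(sr)
      expect_lt(abs(est - C) / C, 0.02)
    }
  }
  # linearity: doubling C doubles the estimate
  e1 <- input_capacitance(simulate_capacitance_step(80, 10))
  e2 <- input_capacitance(simulate_capacitance_step(160, 10))
  expect_equal(e2 / e1, 2, tolerance = 0.01)
  # zero transient flagged
  flat <- list(trace = epsc_trace(numeric(5000), 1e5), step_onset = 0.01,
               step_duration = 0.03, dV = 10)
  expect_warning(c0 <- input_capacitance(flat), "transient")
  expect_equal(c0, 0)
})

test_that("series-resistance QC applies the 20% discard rule", {
  mk <- function(rs) simulate_capacitance_step(100, rs, dV_mV = -10)
  qc0 <- series_resistance_qc(lapply(c(10, 10, 10), mk))
  expect_true(qc0$pass)
  expect_equal(qc0$max_change_fraction, 0)
  expect_equal(qc0$rs_mohm, rep(10, 3), tolerance = 1e-9)

  expect_false(series_resistance_qc(lapply(c(10, 13), mk))$pass)   # 30%
  expect_true(series_resistance_qc(lapply(c(10, 11.9), mk))$pass)  # 19%
  expect_true(series_resistance_qc(lapply(c(10, 12), mk))$pass)    # 20% inclusive
  expect_error(series_resistance_qc(list(mk(10))), "at least 2")
})
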