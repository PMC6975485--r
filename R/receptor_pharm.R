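#' Peak of a puff-evoked agonist response
#'
#' Baseline (mean of the pre-puff segment) is subtracted and the extremum
#' of the response within `window` seconds of puff onset is returned,
#' signed (inward negative).
#'
#' @param puff A `puff_response` from [generate_puff_response()] or a
#'   compatible list with `trace` and `puff_time`.
#' @param window Peak-search window after puff onset, s (default 2).
#' @return Peak current, pA (signed).
#' @export
puff_peak <- function(puff, window = 2) {
  tr <- puff$trace
  tt <- trace_times(tr)
  pre <- tr$samples[tt < puff$puff_time]
  base <- if (length(pre) > 0) mean(pre) else 0
  seg <- tr$samples[tt >= puff$puff_time &
                      tt <= puff$puff_time + window] - base
  if (length(seg) == 0) stop("no samples in the peak-search window")
  seg[which.max(abs(seg))]
}

#' Rectification index of kainate-evoked currents
#'
#' `RI = (|I_+40| / 40) / (|I_-60| / 60)`: the ratio of conductance at
#' +40 mV to conductance at -60 mV relative to the reversal potential,
#' computed from magnitudes so that an ohmic conductance yields exactly 1.
#' `RI < 1` classifies the response as inwardly rectifying (the
#' Ca2+-permeable AMPA receptor phenotype); `RI >= 1` as outwardly
#' rectifying.
#'
#' @param I_plus40 Response amplitude at +40 mV from reversal, pA.
#' @param I_minus60 Response amplitude at -60 mV from reversal, pA
#'   (non-zero).
#' @return A `rectification_result`: list with `I_plus40`, `I_minus60`,
#'   `RI`, `classification` (`"inward"` or `"outward"`).
#' @examples
#' rectification_index(200, -300)$RI    # ohmic: 1
#' rectification_index(100, -300)$RI    # 0.5 -> inward
#' @export
rectification_index <- function(I_plus40, I_minus60) {
  if (I_minus60 == 0) stop("I_minus60 must be non-zero")
  ri <- (abs(I_plus40) / 40) / (abs(I_minus60) / 60)
  structure(list(I_plus40 = I_plus40, I_minus60 = I_minus60, RI = ri,
                 classification = if (ri < 1) "inward" else "outward"),
            class = "rectification_result")
}

#' @rdname rectification_index
#' @param puff_plus40,puff_minus60 `puff_response`s recorded at +40 and
#'   -60 mV from reversal; peaks are extracted with [puff_peak()].
#' @export
rectification_from_puffs <- function(puff_plus40, puff_minus60) {
  rectification_index(puff_peak(puff_plus40), puff_peak(puff_minus60))
}

#' Reversal potential by linear interpolation of peak responses
#'
#' The holding potential at which the agonist evokes no current deflection,
#' found by interpolating the peak-vs-holding relation to its zero
#' crossing.  The responses must bracket zero.
#'
#' @param peaks Peak currents, pA (signed), at each holding potential.
#' @param holdings Holding potentials, mV.
#' @return Reversal potential, mV.
#' @examples
#' find_reversal(c(-300, 200), c(-60, 40))
#' @export
find_reversal <- function(peaks, holdings) {
  if (length(peaks) != length(holdings) || length(peaks) < 2)
    stop("need peaks and holdings of equal length >= 2")
  ord <- order(holdings)
  peaks <- peaks[ord]; holdings <- holdings[ord]
  if (any(peaks == 0)) return(holdings[which(peaks == 0)[1]])
  s <- sign(peaks)
  cross <- which(s[-1] != s[-length(s)])
  if (length(cross) == 0)
    stop("responses do not bracket zero; no reversal in range")
  i <- cross[1]
  holdings[i] + (0 - peaks[i]) * (holdings[i + 1] - holdings[i]) /
    (peaks[i + 1] - peaks[i])
}

#' NMDA/AMPA ratio
#'
#' Ratio of the peak NMDA-evoked current at +40 mV to the peak
#' kainate-evoked (AMPA) current at -70 mV, both measured from the
#' pre-puff baseline.  Holding potentials are validated from the response
#' metadata (1 mV tolerance).
#'
#' @param nmda A `puff_response` recorded at +40 mV (agonist `"NMDA"`).
#' @param ampa A `puff_response` recorded at -70 mV (agonist `"KA"`).
#' @return Dimensionless ratio `|peak NMDA| / |peak AMPA|`.
#' @export
nmda_ampa_ratio <- function(nmda, ampa) {
  if (abs(nmda$holding_potential - 40) > 1)
    stop("NMDA response must be recorded at +40 mV")
  if (abs(ampa$holding_potential - (-70)) > 1)
    stop("AMPA response must be recorded at -70 mV")
  pn <- puff_peak(nmda)
  pa <- puff_peak(ampa)
  if (pa == 0) stop("zero AMPA peak")
  abs(pn) / abs(pa)
}

#' Charge transfer of an agonist-evoked current
#'
#' Trapezoidal integral of the baseline-subtracted current over the 10 s
#' following puff onset, reported as a magnitude in pC and normalized by
#' the input capacitance (pC/pF).
#'
#' @param puff A `puff_response`.
#' @param capacitance_pF Input capacitance, pF (> 0).
#' @param window Integration window, s (default 10); the trace must cover
#'   it.
#' @return List with `charge_pC` and `charge_per_pF`.
#' @examples
#' pr <- generate_puff_response(100, 1, holding = 40, reversal = 0)
#' charge_transfer(pr, capacitance_pF = 50)
#' @export
charge_transfer <- function(puff, capacitance_pF, window = 10) {
  if (capacitance_pF <= 0) stop("capacitance must be > 0")
  tr <- puff$trace
  tt <- trace_times(tr)
  if (max(tt) < puff$puff_time + window)
    stop("trace shorter than the integration window after the puff")
  pre <- tr$samples[tt < puff$puff_time]
  base <- if (length(pre) > 0) mean(pre) else 0
  sel <- tt >= puff$puff_time & tt <= puff$puff_time + window
  y <- tr$samples[sel] - base
  dt <- 1 / tr$sampling_rate
  q <- abs(sum((y[-1] + y[-length(y)]) / 2) * dt)  # pA * s = pC
  list(charge_pC = q, charge_per_pF = q / capacitance_pF)
}

#' Input capacitance from a voltage-step transient
#'
#' The capacitive charge is the time integral of the step-onset transient
#' above the steady-state current; dividing by the membrane voltage change
#' gives the capacitance (Q = C dV).  The steady-state current is the mean
#' over the last 20% of the pulse; the membrane voltage change is corrected
#' for the drop across the series resistance
#' (`dV_m = dV (1 - I_ss / I_peak)`), which reduces to `dV` for a pure
#' series-RC cell.
#'
#' @param step A `step_response` from [simulate_capacitance_step()] (or a
#'   list with `trace`, `step_onset`, `step_duration`, `dV`).
#' @return Capacitance, pF.  A zero transient returns 0 with a warning.
#' @examples
#' input_capacitance(simulate_capacitance_step(100, 10))
#' @export
input_capacitance <- function(step) {
  tr <- step$trace
  y <- pulse_samples(tr, step$step_onset, step$step_duration)
  n <- length(y)
  ss_sel <- seq(max(1, floor(0.8 * n)), n)
  if (length(ss_sel) < 3) stop("pulse too short to estimate steady state")
  i_ss <- mean(y[ss_sel])
  i_peak <- y[which.max(abs(y))]
  if (abs(i_peak) <= abs(i_ss) * (1 + 1e-9) || i_peak == 0) {
    warning("no capacitive transient above steady state; returning 0")
    return(0)
  }
  trans <- y - i_ss
  dt <- 1 / tr$sampling_rate
  q <- sum((trans[-1] + trans[-n]) / 2) * dt  # pA*s = pC
  dv_m <- step$dV * (1 - i_ss / i_peak)
  if (dv_m == 0) stop("no steady state reached; cannot correct dV")
  abs(q) * 1000 / abs(dv_m)  # pC / mV -> pF
}

# integer-indexed pulse window (robust to floating-point edge times)
pulse_samples <- function(trace, onset, duration) {
  fs <- trace$sampling_rate
  i_on <- round((onset - trace$t0) * fs) + 1L
  i_off <- i_on + round(duration * fs) - 1L
  i_on <- max(1L, i_on)
  i_off <- min(length(trace$samples), i_off)
  if (i_off < i_on) stop("no samples inside the voltage pulse")
  trace$samples[i_on:i_off]
}

#' Series-resistance quality control across sweeps
#'
#' Series resistance per sweep is `dV / I_peak` of the test-pulse
#' transient.  A recording passes when the largest relative change from
#' the first sweep does not exceed 20% (a change strictly above 20%
#' discards the data).
#'
#' @param test_pulses List of `step_response`s (>= 2), one per sweep.
#' @return A `series_resistance_qc`: list with `rs_mohm` (per sweep),
#'   `max_change_fraction`, `pass`.
#' @examples
#' sweeps <- lapply(c(10, 11), simulate_capacitance_step,
#'                  capacitance_pF = 100, dV_mV = -10)
#' series_resistance_qc(sweeps)$pass
#' @export
series_resistance_qc <- function(test_pulses) {
  if (length(test_pulses) < 2) stop("need at least 2 test-pulse sweeps")
  rs <- vapply(test_pulses, function(step) {
    y <- pulse_samples(step$trace, step$step_onset, step$step_duration)
    i_peak <- y[which.max(abs(y))]
    if (i_peak == 0) stop("absent test-pulse transient")
    1000 * abs(step$dV) / abs(i_peak)  # mV / pA -> GOhm; *1000 -> MOhm
  }, 0)
  max_change <- max(abs(rs - rs[1]) / rs[1])
  structure(list(rs_mohm = rs, max_change_fraction = max_change,
                 pass = max_change <= 0.20),
            class = "series_resistance_qc")
}
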