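#' Sample synthetic EPSC event times from the inhomogeneous Poisson model
#'
#' Events are drawn from the rate
#' \eqn{\lambda(t) = r_0} for `t < burst_end` and
#' \eqn{\lambda(t) = r_0 + A' e^{-(t-burst\_end)/\tau'}} afterwards, where
#' `A' = elevation_amplitude * rate_scale` and
#' `tau' = elevation_tau * tau_scale` of the optional drug effect.  The
#' expected number of burst-added events is
#' \eqn{A'\tau'(1 - e^{-(T - burst\_end)/\tau'})}.  Amplitude magnitudes are
#' log-normal (configured mean/SD) truncated below at `1.5 * noise_sd` so
#' that some true events lie under the 3-SD detection threshold; they are
#' stored negative (inward).
#'
#' @param config A [sim_config()].
#' @param effect Optional [drug_effect()]; `NULL` means control.
#' @param seed Optional seed overriding `config$seed`.
#' @return A `ground_truth` object: an [event_train()] with
#'   `source = "truth"` and strictly increasing times.
#' @examples
#' gt <- sample_event_times(sim_config(seed = 1))
#' head(gt)
#' @export
sample_event_times <- function(config, effect = NULL, seed = NULL) {
  validate_sim_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  T <- config$trace_duration
  burst_end <- config$burst_start + config$burst_duration
  rs <- if (is.null(effect)) 1 else effect$rate_scale
  ts <- if (is.null(effect)) 1 else effect$tau_scale
  A <- config$elevation_amplitude * rs
  tau <- config$elevation_tau * ts

  n0 <- stats::rpois(1, config$baseline_rate * T)
  t_base <- stats::runif(n0, 0, T)

  t_elev <- numeric(0)
  if (A > 0 && tau > 0) {
    frac <- 1 - exp(-(T - burst_end) / tau)
    n1 <- stats::rpois(1, A * tau * frac)
    u <- stats::runif(n1)
    t_elev <- burst_end - tau * log(1 - u * frac)
  }
  times <- sort(c(t_base, t_elev))
  times <- times[!duplicated(times)]
  amps <- -sample_epsc_amplitudes(length(times), config)
  out <- event_train(times, amps, source = "truth")
  class(out) <- c("ground_truth", class(out))
  out
}

# truncated log-normal amplitude magnitudes (pA)
sample_epsc_amplitudes <- function(n, config) {
  if (n == 0) return(numeric(0))
  m <- config$epsc_amplitude_mean
  s <- config$epsc_amplitude_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  lower <- 1.5 * config$noise_sd
  out <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(out < lower)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    out[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1
  }
  if (length(bad) > 0) out[bad] <- lower
  out
}

# biexponential kernel sampled from onset, normalized to unit peak
epsc_kernel <- function(n_samples, sampling_rate, tau_rise, tau_decay) {
  u <- (seq_len(n_samples) - 1) / sampling_rate
  k <- exp(-u / tau_decay) - exp(-u / tau_rise)
  t_pk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  peak <- exp(-t_pk / tau_decay) - exp(-t_pk / tau_rise)
  list(kernel = k / peak, t_peak = t_pk)
}

#' Render a synthetic voltage-clamp trace from ground-truth events
#'
#' The trace is Gaussian baseline noise plus one peak-normalized
#' biexponential kernel per event (so each kernel's minimum equals the
#' event's amplitude) plus biphasic stimulus artifacts at the pulse times of
#' the burst window.  Event times are peak times; each kernel's onset is
#' shifted earlier by the kernel's rise-to-peak delay.
#'
#' @param truth A `ground_truth` event train (see [sample_event_times()]).
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed` (noise only).
#' @param condition,neuron_id,trace_index Metadata passed to the trace.
#' @return An [epsc_trace()] with the burst window recorded in metadata.
#' @examples
#' cfg <- sim_config(trace_duration = 4, seed = 2)
#' tr <- render_trace(sample_event_times(cfg), cfg)
#' @export
render_trace <- function(truth, config, seed = NULL,
                         condition = "control", neuron_id = NA_character_,
                         trace_index = NA_integer_) {
  validate_sim_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  n <- round(config$trace_duration * fs)
  x <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd)
       else numeric(n)

  if (nrow(truth) > 0) {
    tau_r <- config$tau_rise; tau_d <- config$tau_decay
    t_pk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
    peak <- exp(-t_pk / tau_d) - exp(-t_pk / tau_r)
    # support to 30 decay constants: truncation residual ~ exp(-30) of the
    # peak, negligible against pA-scale signals
    klen <- max(2L, ceiling(30 * tau_d * fs))
    for (j in seq_len(nrow(truth))) {
      onset <- truth$time_s[j] - t_pk
      i0 <- max(1L, floor(onset * fs) + 1L)
      idx <- i0:min(n, i0 + klen)
      u <- (idx - 1) / fs - onset  # kernel evaluated at true sample times
      pos <- u >= 0
      x[idx[pos]] <- x[idx[pos]] + truth$amplitude_pA[j] *
        (exp(-u[pos] / tau_d) - exp(-u[pos] / tau_r)) / peak
    }
  }

  burst_window <- c(config$burst_start,
                    config$burst_start + config$burst_duration)
  pulses <- stimulus_pulse_times(burst_window, config$pulse_count)
  for (p in pulses) {
    i1 <- round(p * fs) + 1L
    if (i1 >= 1L && i1 <= n) x[i1] <- x[i1] + config$artifact_amplitude
    if (i1 + 1L >= 1L && i1 + 1L <= n)
      x[i1 + 1L] <- x[i1 + 1L] - config$artifact_amplitude
  }

  epsc_trace(x, sampling_rate = fs, t0 = 0,
             holding_potential = config$holding_potential,
             burst_window = burst_window, condition = condition,
             neuron_id = neuron_id, trace_index = trace_index)
}

#' Stimulus pulse times and artifact blanking windows
#'
#' Pulses are evenly spaced across the burst window (20 pulses over 0.2 s =
#' 100 Hz).  The blanking window around each pulse is
#' `[pulse - 0.5 ms, pulse + 2 ms]`; detected peaks inside it are discarded.
#'
#' @param burst_window `c(start, end)`, s.
#' @param pulse_count Number of pulses.
#' @return `stimulus_pulse_times`: numeric vector of pulse onsets;
#'   `stimulus_blank_windows`: two-column matrix of blank intervals.
#' @export
stimulus_pulse_times <- function(burst_window, pulse_count = 20) {
  burst_window[1] +
    (seq_len(pulse_count) - 1) * diff(burst_window) / pulse_count
}

#' @rdname stimulus_pulse_times
#' @param pre_s,post_s Blank extent before and after each pulse, s.  The
#'   pre-pulse extent covers the symmetric (acausal) ringing that a
#'   zero-phase filter spreads ahead of the artifact.
#' @export
stimulus_blank_windows <- function(burst_window, pulse_count = 20,
                                   pre_s = 1.5e-3, post_s = 2e-3) {
  p <- stimulus_pulse_times(burst_window, pulse_count)
  cbind(start = p - pre_s, end = p + post_s)
}

#' Generate an agonist puff response at a stated holding potential
#'
#' The peak current follows a driving-force model
#' \eqn{I = g (V_h - V_{rev})}, attenuated by the `rectification` factor for
#' depolarized potentials (`V_h > V_rev`), and decays monoexponentially.
#' The conductance is parameterized by `peak`, the response magnitude at a
#' -60 mV driving force (so `g = peak/60` nS); an ohmic cell has
#' `rectification = 1`, a Ca2+-permeable AMPA receptor phenotype has
#' `rectification < 1`.
#'
#' @param peak Response magnitude at a -60 mV driving force, pA.
#' @param decay_tau Monoexponential decay time constant, s.
#' @param holding Holding potential, mV.
#' @param reversal Reversal potential, mV.
#' @param rectification Multiplier on the outward limb, dimensionless.
#' @param noise_sd Gaussian noise SD, pA.
#' @param seed Optional seed.
#' @param agonist `"KA"` or `"NMDA"`.
#' @param sampling_rate Hz.
#' @param pre_s,post_s Baseline and post-puff durations, s.
#' @return A `puff_response`: list with `trace`, `agonist`,
#'   `holding_potential`, `puff_time`.
#' @examples
#' pr <- generate_puff_response(300, 1, holding = -60, reversal = 0)
#' min(pr$trace$samples)
#' @export
generate_puff_response <- function(peak, decay_tau, holding, reversal = 0,
                                   rectification = 1, noise_sd = 0,
                                   seed = NULL, agonist = c("KA", "NMDA"),
                                   sampling_rate = 5000, pre_s = 0.5,
                                   post_s = 12) {
  agonist <- match.arg(agonist)
  if (decay_tau <= 0) stop("decay_tau must be > 0")
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  dV <- holding - reversal
  scale <- if (dV > 0) rectification else 1
  i_peak <- (peak / 60) * dV * scale
  u <- (seq_len(n_post) - 1) / fs
  x <- c(numeric(n_pre), i_peak * exp(-u / decay_tau))
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  tr <- epsc_trace(x, sampling_rate = fs, t0 = 0,
                   holding_potential = holding, condition = agonist)
  structure(list(trace = tr, agonist = agonist,
                 holding_potential = holding, puff_time = pre_s),
            class = "puff_response")
}

#' Generate a cohort of paired control/drug neuron recordings
#'
#' Each neuron gets a multiplicative log-normal random effect on the
#' elevation amplitude and time constant (shared between its control and
#' drug conditions, making the design paired), then `traces_per_neuron`
#' traces per condition are simulated with independent Poisson event
#' realizations.  Ground truth is retained alongside every trace.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param config A [sim_config()].
#' @param effect A [drug_effect()] for the drug condition; `NULL` simulates
#'   a control-only cohort.
#' @param traces_per_neuron Traces per neuron and condition (default 3).
#' @param seed Seed for the whole cohort.
#' @param nucleus `"PHN"` or `"INC"` label attached to every neuron.
#' @param re_sdlog_amp,re_sdlog_tau SD (log scale) of the per-neuron random
#'   effects on elevation amplitude and tau.
#' @param render If `FALSE`, only ground-truth event trains are generated
#'   (no current traces); useful for large truth-fed calibration runs.
#' @return List of `neuron_record` objects, each with `neuron_id`,
#'   `nucleus`, and `conditions`, a named list (`control`, drug label) of
#'   `list(traces = <list of epsc_trace>, truths = <list of ground_truth>)`.
#' @examples
#' coh <- generate_cohort(2, sim_config(trace_duration = 5),
#'                        drug_effect("NAS", 0.7, 0.4), seed = 1)
#' names(coh[[1]]$conditions)
#' @export
generate_cohort <- function(n_neurons, config, effect = NULL,
                            traces_per_neuron = 3, seed = NULL,
                            nucleus = "PHN", re_sdlog_amp = 0.2,
                            re_sdlog_tau = 0.25, render = TRUE) {
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  conditions <- list(control = NULL)
  if (!is.null(effect)) conditions[[effect$label]] <- effect
  lapply(seq_len(n_neurons), function(i) {
    m_amp <- stats::rlnorm(1, 0, re_sdlog_amp)
    m_tau <- stats::rlnorm(1, 0, re_sdlog_tau)
    cfg_i <- config
    cfg_i$elevation_amplitude <- config$elevation_amplitude * m_amp
    cfg_i$elevation_tau <- config$elevation_tau * m_tau
    cfg_i$seed <- NULL
    conds <- lapply(names(conditions), function(lab) {
      eff <- conditions[[lab]]
      reps <- lapply(seq_len(traces_per_neuron), function(k) {
        gt <- sample_event_times(cfg_i, effect = eff)
        tr <- if (render)
          render_trace(gt, cfg_i, condition = lab,
                       neuron_id = sprintf("%s_%02d", nucleus, i),
                       trace_index = k)
        list(trace = tr, truth = gt)
      })
      list(traces = if (render) lapply(reps, `[[`, "trace") else NULL,
           truths = lapply(reps, `[[`, "truth"))
    })
    names(conds) <- names(conditions)
    structure(list(neuron_id = sprintf("%s_%02d", nucleus, i),
                   nucleus = nucleus, conditions = conds,
                   config = cfg_i,
                   random_effects = c(amp = m_amp, tau = m_tau)),
              class = "neuron_record")
  })
}

#' Simulate the current response to a voltage step across a series-RC cell
#'
#' A step of `dV_mV` across a pipette series resistance in series with the
#' cell capacitance produces a transient `I(t) = (dV/Rs) exp(-t/(Rs C))`
#' whose area equals `C * dV` exactly; an equal and opposite transient
#' occurs at step offset.  Used to validate [input_capacitance()] and
#' [series_resistance_qc()].  Sampled fast (default 100 kHz) so that the
#' transient of a small cell with a low-resistance pipette is resolved.
#'
#' @param capacitance_pF Cell capacitance, pF.
#' @param rs_mohm Series resistance, MOhm.
#' @param dV_mV Step amplitude, mV (may be negative).
#' @param sampling_rate Hz.
#' @param pre_s,pulse_s,post_s Baseline, pulse, and tail durations, s.
#' @param noise_sd Gaussian noise SD, pA.
#' @param seed Optional seed.
#' @return A `step_response`: list with `trace`, `step_onset`,
#'   `step_duration`, `dV`.
#' @examples
#' sr <- simulate_capacitance_step(100, 10)
#' input_capacitance(sr)
#' @export
simulate_capacitance_step <- function(capacitance_pF, rs_mohm, dV_mV = 10,
                                      sampling_rate = 1e5, pre_s = 0.02,
                                      pulse_s = 0.1, post_s = 0.02,
                                      noise_sd = 0, seed = NULL) {
  if (capacitance_pF < 0 || rs_mohm <= 0)
    stop("capacitance must be >= 0 and rs > 0")
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate
  tau <- rs_mohm * capacitance_pF * 1e-6   # MOhm * pF -> s
  i0 <- dV_mV / rs_mohm * 1000             # mV / MOhm -> pA
  n_pre <- round(pre_s * fs)
  n_pulse <- round(pulse_s * fs)
  n_post <- round(post_s * fs)
  u <- (seq_len(n_pulse) - 1) / fs
  v <- (seq_len(n_post) - 1) / fs
  on_tr <- if (tau > 0) i0 * exp(-u / tau) else c(i0, numeric(n_pulse - 1))
  off_tr <- if (tau > 0) -i0 * exp(-v / tau) else c(-i0, numeric(n_post - 1))
  x <- c(numeric(n_pre), on_tr, off_tr)
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  tr <- epsc_trace(x, sampling_rate = fs, t0 = 0)
  structure(list(trace = tr, step_onset = pre_s, step_duration = pulse_s,
                 dV = dV_mV),
            class = "step_response")
}
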