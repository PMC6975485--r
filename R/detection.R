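#' Zero-phase low-pass Butterworth filter
#'
#' Applies the squared magnitude response of an order-`order` Butterworth
#' low-pass (the response of a forward-backward filter pass) in the
#' frequency domain, giving exactly zero phase shift so detected peak times
#' are not displaced.  Mirrors the 1 kHz acquisition filter of the
#' recording chain.
#'
#' @param x Numeric signal.
#' @param sampling_rate Hz.
#' @param cutoff Cutoff frequency, Hz; if `>= sampling_rate/2` the signal is
#'   returned unchanged.
#' @param order Filter order (of the one-way filter; the zero-phase
#'   response applies it twice).
#' @return Filtered numeric vector of the same length.
#' @export
lowpass_zero_phase <- function(x, sampling_rate, cutoff = 1000, order = 4) {
  n <- length(x)
  if (n < 4 || cutoff >= sampling_rate / 2) return(x)
  nh <- n %/% 2
  f_pos <- (0:nh) * sampling_rate / n
  Hh <- 1 / (1 + (f_pos / cutoff)^(2 * order))
  H <- c(Hh, Hh[seq(n - nh, 2)])  # hermitian mirror for negative freqs
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Estimate baseline noise SD from the pre-burst segment
#'
#' The detection threshold is three times the SD of the baseline noise
#' before burst stimulation.  The `raw` method is the sample SD of the
#' window; the `robust` method uses 1.4826 x the median absolute deviation,
#' which resists inflation by spontaneous EPSCs present in the baseline.
#'
#' @param trace An [epsc_trace()].
#' @param window `c(start, end)` in s; defaults to everything from the
#'   trace start to the burst onset.  Must precede the burst onset and span
#'   at least 0.5 s.
#' @param method `"robust"` (default) or `"raw"`.
#' @return A `noise_estimate`: list with `sd` (pA), `window`, `method`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' tr <- render_trace(sample_event_times(cfg), cfg)
#' estimate_baseline_sd(tr)$sd
#' @export
estimate_baseline_sd <- function(trace, window = NULL,
                                 method = c("robust", "raw")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "epsc_trace"))
  ext <- trace_extent(trace)
  if (is.null(window)) {
    if (is.null(trace$burst_window))
      stop("no burst window in metadata; supply `window`")
    window <- c(ext[1], trace$burst_window[1])
  }
  if (window[1] < ext[1] || window[2] > ext[2] || window[1] >= window[2])
    stop("window outside trace extent")
  if (!is.null(trace$burst_window) && window[2] > trace$burst_window[1])
    stop("noise window must precede burst onset")
  if (diff(window) < 0.5)
    stop("noise window must span at least 0.5 s")
  tt <- trace_times(trace)
  x <- trace$samples[tt >= window[1] & tt < window[2]]
  sd_hat <- if (method == "robust") stats::mad(x, constant = 1.4826)
            else stats::sd(x)
  structure(list(sd = sd_hat, window = window, method = method),
            class = "noise_estimate")
}

#' Detect spontaneous EPSCs by the 3-SD threshold criterion
#'
#' The trace is low-pass filtered at 1 kHz with a zero-phase Butterworth
#' response, a running local baseline is taken as the median of a 10 ms
#' window preceding each sample, and local minima whose depth below that
#' baseline exceeds `threshold_k` times the baseline-noise SD (strict
#' inequality) are kept as EPSC peaks.  Peaks inside stimulus-artifact
#' blanking windows are discarded, and peaks closer than `min_separation`
#' are merged to the larger one.  Amplitudes are peak minus local baseline
#' (negative), which makes detection invariant to a constant holding-current
#' offset.
#'
#' @param trace An [epsc_trace()].
#' @param noise A `noise_estimate` from [estimate_baseline_sd()], or a bare
#'   number (pA).
#' @param threshold_k Threshold in units of noise SD (default 3).
#' @param min_separation Minimum peak separation, s (default 2 ms; below
#'   this, overlapping events merge to the larger peak).
#' @param blank_windows Two-column matrix of intervals to exclude; by
#'   default derived from the trace's burst window via
#'   [stimulus_blank_windows()].  Overlapping windows are merged.
#' @param pulse_count Pulses assumed when deriving default blanks.
#' @param baseline_span Length of the local-baseline median window, s.
#' @param prominence_span Length of the pre-peak window (on the scale of
#'   the EPSC rise time) from whose maximum the peak must additionally
#'   drop by the threshold; rejects ripples on the decay of a preceding
#'   event.
#' @param filter_cutoff Low-pass cutoff, Hz; `Inf` disables filtering.
#' @return An [event_train()] with `source = "detected"`.
#' @examples
#' cfg <- sim_config(seed = 4)
#' tr <- render_trace(sample_event_times(cfg), cfg)
#' ev <- detect_epscs(tr, estimate_baseline_sd(tr))
#' nrow(ev)
#' @export
detect_epscs <- function(trace, noise, threshold_k = 3,
                         min_separation = 0.002, blank_windows = NULL,
                         pulse_count = 20, baseline_span = 0.010,
                         prominence_span = 0.0015, filter_cutoff = 1000) {
  stopifnot(inherits(trace, "epsc_trace"))
  sd_n <- if (inherits(noise, "noise_estimate")) noise$sd else as.numeric(noise)
  if (sd_n < 0) stop("noise sd must be >= 0")
  if (sd_n == 0 && stats::sd(trace$samples) > 0)
    warning("noise sd is 0 for a non-flat trace; every local minimum ",
            "below baseline will be reported")
  fs <- trace$sampling_rate
  x <- lowpass_zero_phase(trace$samples, fs, cutoff = filter_cutoff)
  n <- length(x)
  if (n < 3) return(event_train(source = "detected"))

  # running local baseline: median over `baseline_span`, evaluated just
  # before each candidate peak (window centre shifted back by roughly the
  # half-window plus a 2 ms guard so the event's own rise is excluded)
  k <- max(3L, round(baseline_span * fs))
  if (k %% 2 == 0) k <- k + 1L
  base <- stats::runmed(x, k, endrule = "keep")
  lag <- as.integer(round((baseline_span / 2 + 0.002) * fs))
  lag2 <- lag + k  # one further window back, clear of any immediately
                   # preceding event that contaminates the first window

  d <- diff(x)
  cand <- which(d[-1] > 0 & d[-(n - 1)] <= 0) + 1L
  if (length(cand) == 0) return(event_train(source = "detected"))
  bidx <- pmax(1L, cand - lag)
  bidx2 <- pmax(1L, cand - lag2)
  # peak located on the filtered trace; amplitude read from the unfiltered
  # samples at that time (the low-pass attenuates the sharp peak itself)
  amp <- trace$samples[cand] - pmax(base[bidx], base[bidx2])
  keep <- amp < -(threshold_k * sd_n)
  cand <- cand[keep]; amp <- amp[keep]
  if (length(cand) == 0) return(event_train(source = "detected"))
  # the peak must also stand out from the immediately preceding signal
  # (a window on the scale of the EPSC rise); this rejects sub-threshold
  # ripples riding on the decay of a previous event, whose running-baseline
  # depth would otherwise re-trigger
  w <- max(2L, as.integer(round(prominence_span * fs)))
  prom <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    x[i] - max(x[max(1L, i - w):max(1L, i - 1L)])
  }, 0)
  keep <- prom < -(threshold_k * sd_n)
  cand <- cand[keep]; amp <- amp[keep]
  if (length(cand) == 0) return(event_train(source = "detected"))
  tt <- trace$t0 + (cand - 1) / fs

  if (is.null(blank_windows) && !is.null(trace$burst_window))
    blank_windows <- stimulus_blank_windows(trace$burst_window, pulse_count)
  if (!is.null(blank_windows) && nrow(blank_windows) > 0) {
    bw <- normalize_windows(blank_windows)
    inside <- rep(FALSE, length(tt))
    for (r in seq_len(nrow(bw)))
      inside <- inside | (tt >= bw[r, 1] & tt <= bw[r, 2])
    tt <- tt[!inside]; amp <- amp[!inside]
  }
  if (length(tt) == 0) return(event_train(source = "detected"))

  # merge peaks closer than min_separation, keeping the deeper one
  ord <- order(tt)
  tt <- tt[ord]; amp <- amp[ord]
  repeat {
    gap <- diff(tt)
    j <- which(gap < min_separation)
    if (length(j) == 0) break
    j <- j[1]
    drop <- if (amp[j] <= amp[j + 1]) j + 1L else j
    tt <- tt[-drop]; amp <- amp[-drop]
  }
  event_train(tt, amp, source = "detected")
}

# sort and merge overlapping [start, end] rows
normalize_windows <- function(w) {
  w <- w[order(w[, 1]), , drop = FALSE]
  out <- w[1, , drop = FALSE]
  for (r in seq_len(nrow(w))[-1]) {
    last <- nrow(out)
    if (w[r, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], w[r, 2])
    } else {
      out <- rbind(out, w[r, , drop = FALSE])
    }
  }
  out
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching by absolute time difference: candidate pairs
#' within `tolerance` are taken closest-first.  Recall is matched/truth;
#' precision is matched/detected.  With no detections precision is reported
#' as 1 by convention (flagged via `precision_defined = FALSE`).
#'
#' @param detected An [event_train()] (`source = "detected"`).
#' @param truth A `ground_truth` event train.
#' @param tolerance Matching tolerance, s (> 0).
#' @return List with `recall`, `precision`, `n_matched`, `time_errors`
#'   (signed detected - truth, s) and `precision_defined`.
#' @examples
#' gt <- event_train(c(1, 2), c(-20, -20), source = "truth")
#' det <- event_train(c(1.001, 2.0005), c(-19, -21), source = "detected")
#' match_to_truth(det, gt, tolerance = 0.002)$recall
#' @export
match_to_truth <- function(detected, truth, tolerance = 0.002) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  nd <- nrow(detected); nt <- nrow(truth)
  if (nt == 0) {
    return(list(recall = NA_real_,
                precision = if (nd == 0) 1 else 0,
                n_matched = 0L, time_errors = numeric(0),
                precision_defined = nd > 0))
  }
  if (nd == 0) {
    return(list(recall = 0, precision = 1, n_matched = 0L,
                time_errors = numeric(0), precision_defined = FALSE))
  }
  dt <- abs(outer(detected$time_s, truth$time_s, "-"))
  pairs <- which(dt <= tolerance, arr.ind = TRUE)
  n_matched <- 0L
  errors <- numeric(0)
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(dt[pairs]), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE
        n_matched <- n_matched + 1L
        errors <- c(errors, detected$time_s[i] - truth$time_s[j])
      }
    }
  }
  list(recall = n_matched / nt, precision = n_matched / nd,
       n_matched = n_matched, time_errors = errors,
       precision_defined = TRUE)
}
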