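#' Peristimulus EPSC frequency histogram
#'
#' Counts events per bin averaged across traces and divided by the bin
#' width, giving events/s.  The bin grid is anchored at the end of burst
#' stimulation so that the first post-burst bin starts exactly at
#' `burst_end`; bins extend back toward `t_min` and forward to `t_max`.
#'
#' @param trains A single [event_train()] or a list of them (one per
#'   trace).
#' @param burst_end End of burst stimulation, s.
#' @param bin_width Bin width, s (default 0.1, i.e. 100 ms).
#' @param t_min,t_max Extent of the histogram, s; `t_max` is required (use
#'   the trace duration).
#' @return A `frequency_histogram`: list with `bin_edges`, `rates`
#'   (events/s), `bin_width`, `burst_end`, `n_traces`.
#' @examples
#' tr <- event_train(c(2.25, 2.26, 2.33), rep(-20, 3), source = "truth")
#' h <- bin_events(tr, burst_end = 2.2, t_max = 3)
#' h$rates
#' @export
bin_events <- function(trains, burst_end, bin_width = 0.1, t_min = 0,
                       t_max) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  if (length(trains) == 0) stop("need at least one event train")
  if (bin_width <= 0) stop("bin_width must be > 0")
  n_pre <- max(0L, floor((burst_end - t_min) / bin_width + 1e-9))
  n_post <- floor((t_max - burst_end) / bin_width + 1e-9)
  if (n_post < 1) stop("no complete post-burst bin fits in [burst_end, t_max]")
  edges <- burst_end + bin_width * seq(-n_pre, n_post)
  counts <- rep(0, length(edges) - 1)
  for (tr in trains) {
    h <- graphics::hist(tr$time_s[tr$time_s >= edges[1] &
                                    tr$time_s < edges[length(edges)]],
                        breaks = edges, plot = FALSE, right = FALSE)
    counts <- counts + h$counts
  }
  structure(list(bin_edges = edges,
                 rates = counts / length(trains) / bin_width,
                 bin_width = bin_width, burst_end = burst_end,
                 n_traces = length(trains)),
            class = "frequency_histogram")
}

#' Average baseline EPSC frequency before burst stimulation
#'
#' @param trains A single [event_train()] or list of them.
#' @param pre_window `c(start, end)` of the baseline window, s (must have
#'   positive length, typically everything before the burst).
#' @return Events/s: total events in the window divided by window length
#'   times the number of traces.
#' @examples
#' tr <- event_train(c(0.5, 1.1, 1.9), rep(-15, 3), source = "truth")
#' baseline_rate(tr, c(0, 2))
#' @export
baseline_rate <- function(trains, pre_window) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  if (length(trains) == 0) stop("need at least one event train")
  if (diff(pre_window) <= 0) stop("pre_window must have positive length")
  total <- sum(vapply(trains, function(tr)
    sum(tr$time_s >= pre_window[1] & tr$time_s < pre_window[2]), 0))
  total / (diff(pre_window) * length(trains))
}

#' Duration of increased EPSC frequency
#'
#' Scans the post-burst histogram with a sliding window of three adjacent
#' bins (300 ms at the default 100 ms bin width), stepping one bin at a
#' time.  The duration runs from the end of burst stimulation to the start
#' of the first triplet whose mean rate is equal to or smaller than the
#' baseline frequency.  If no triplet qualifies, the duration equals the
#' available post-burst extent and `capped` is `TRUE`.
#'
#' The sliding window with a start-of-triplet endpoint gives 0.1 s
#' resolution; a disjoint-triplet alternative (`mode = "disjoint"`) and an
#' end-of-triplet endpoint (`endpoint = "end"`) are provided as documented
#' conventions.
#'
#' @param hist A `frequency_histogram` from [bin_events()] (grid anchored
#'   at burst end).
#' @param baseline Baseline frequency, events/s.
#' @param mode `"sliding"` (default) or `"disjoint"` triplet stepping.
#' @param endpoint `"start"` (default) or `"end"`: which edge of the
#'   qualifying triplet terminates the duration.
#' @return List with `duration` (s) and `capped` (logical).
#' @examples
#' tr <- event_train(2.2 + c(0.01, 0.02, 0.15), rep(-20, 3),
#'                   source = "truth")
#' h <- bin_events(tr, burst_end = 2.2, t_max = 4)
#' duration_of_increase(h, baseline = 5)
#' @export
duration_of_increase <- function(hist, baseline,
                                 mode = c("sliding", "disjoint"),
                                 endpoint = c("start", "end")) {
  mode <- match.arg(mode)
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(hist, "frequency_histogram"))
  post <- hist$rates[hist$bin_edges[-length(hist$bin_edges)] >=
                       hist$burst_end - 1e-9]
  if (length(post) < 3) stop("need at least 3 post-burst bins")
  starts <- if (mode == "sliding") seq_len(length(post) - 2)
            else seq(1, length(post) - 2, by = 3)
  for (s in starts) {
    if (mean(post[s:(s + 2)]) <= baseline) {
      off <- if (endpoint == "start") s - 1 else s + 2
      return(list(duration = off * hist$bin_width, capped = FALSE))
    }
  }
  list(duration = length(post) * hist$bin_width, capped = TRUE)
}

#' EPSC frequency in the first second after burst stimulation
#'
#' @param trains A single [event_train()] or list of them.
#' @param burst_end End of burst stimulation, s.
#' @param window Measurement window length, s (default 1).
#' @param t_max Trace extent, s; an error is raised when less than `window`
#'   of recording follows the burst.
#' @return Events/s averaged across traces.
#' @examples
#' tr <- event_train(2.2 + (1:30) / 31, rep(-20, 30), source = "truth")
#' post_burst_rate(tr, burst_end = 2.2, t_max = 4)
#' @export
post_burst_rate <- function(trains, burst_end, window = 1, t_max = NULL) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  if (length(trains) == 0) stop("need at least one event train")
  if (!is.null(t_max) && t_max < burst_end + window)
    stop("insufficient trace after burst for the measurement window")
  total <- sum(vapply(trains, function(tr)
    sum(tr$time_s >= burst_end & tr$time_s < burst_end + window), 0))
  total / (window * length(trains))
}

#' Per-neuron percent reduction of a metric by a drug
#'
#' `100 * (control - drug) / control`, computed for each neuron separately;
#' cohort summaries must average these per-neuron values (mean of ratios,
#' not ratio of means).  Neurons with `control <= 0` are returned as `NA`
#' with an `excluded` attribute.
#'
#' @param control,drug Numeric vectors of per-neuron metric values.
#' @return Numeric vector of percent reductions with attribute `excluded`
#'   (logical vector).
#' @examples
#' percent_reduction(c(2, 4), c(1, 1))          # 50, 75; mean 62.5
#' mean(percent_reduction(c(2, 4), c(1, 1)))
#' @export
percent_reduction <- function(control, drug) {
  if (length(control) != length(drug))
    stop("control and drug must have equal length")
  excluded <- !(control > 0)
  out <- ifelse(excluded, NA_real_, 100 * (control - drug) / control)
  attr(out, "excluded") <- excluded
  out
}

#' Sustained-response summary for one neuron and condition
#'
#' Combines [baseline_rate()], [bin_events()], [duration_of_increase()] and
#' [post_burst_rate()] on the (typically three) event trains of one neuron:
#' the histogram is averaged across the trains before the duration rule is
#' applied.
#'
#' @param trains List of [event_train()]s.
#' @param burst_window `c(start, end)` of the burst, s.
#' @param t_max Trace extent, s.
#' @param bin_width Histogram bin width, s.
#' @param pre_window Baseline window; defaults to `c(0, burst_start)`.
#' @param ... Passed to [duration_of_increase()].
#' @return List with `baseline_rate`, `duration`, `capped`,
#'   `post_burst_rate_1s`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' gts <- replicate(3, sample_event_times(cfg), simplify = FALSE)
#' sustained_response(gts, c(2, 2.2), t_max = 10)
#' @export
sustained_response <- function(trains, burst_window, t_max,
                               bin_width = 0.1, pre_window = NULL, ...) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  if (is.null(pre_window)) pre_window <- c(0, burst_window[1])
  base <- baseline_rate(trains, pre_window)
  h <- bin_events(trains, burst_end = burst_window[2],
                  bin_width = bin_width, t_min = pre_window[1],
                  t_max = t_max)
  dur <- duration_of_increase(h, base, ...)
  list(baseline_rate = base, duration = dur$duration,
       capped = dur$capped,
       post_burst_rate_1s = post_burst_rate(trains, burst_window[2],
                                            t_max = t_max))
}

#' Quantify a simulated cohort into a metric table
#'
#' Runs the full per-neuron pipeline on the output of [generate_cohort()]:
#' EPSC detection on each trace (or ground truth directly when
#' `use_truth = TRUE`), then the sustained-response metrics per condition.
#'
#' @param records List of `neuron_record`s from [generate_cohort()].
#' @param use_truth Bypass the detector and feed ground-truth events.
#' @param threshold_k,min_separation Passed to [detect_epscs()].
#' @return A [metric_table()] with metrics `duration_s`, `post_rate_1s`,
#'   `baseline_rate`.
#' @examples
#' coh <- generate_cohort(2, sim_config(trace_duration = 6), seed = 1)
#' quantify_cohort(coh, use_truth = TRUE)
#' @export
quantify_cohort <- function(records, use_truth = FALSE, threshold_k = 3,
                            min_separation = 0.003) {
  rows <- list()
  for (rec in records) {
    for (lab in names(rec$conditions)) {
      cond <- rec$conditions[[lab]]
      trains <- if (use_truth) {
        cond$truths
      } else {
        if (is.null(cond$traces))
          stop("cohort was generated without traces; use use_truth = TRUE")
        lapply(cond$traces, function(tr) {
          ns <- estimate_baseline_sd(tr)
          detect_epscs(tr, ns, threshold_k = threshold_k,
                       min_separation = min_separation)
        })
      }
      if (!is.null(cond$traces)) {
        tr1 <- cond$traces[[1]]
        bw <- tr1$burst_window
        tmax <- trace_extent(tr1)[2]
      } else {
        cfg <- rec$config
        bw <- c(cfg$burst_start, cfg$burst_start + cfg$burst_duration)
        tmax <- cfg$trace_duration
      }
      res <- sustained_response(trains, bw, t_max = tmax)
      rows[[length(rows) + 1]] <- data.frame(
        neuron_id = rec$neuron_id, nucleus = rec$nucleus, condition = lab,
        metric = c("duration_s", "post_rate_1s", "baseline_rate"),
        value = c(res$duration, res$post_burst_rate_1s,
                  res$baseline_rate),
        units = c("s", "events/s", "events/s"),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  metric_table(df$neuron_id, df$nucleus, df$condition, df$metric,
               df$value, df$units)
}

#' Append per-neuron percent-reduction metrics to a metric table
#'
#' For each neuron with both a `control` and a `drug` value of `metric`,
#' adds a row `<metric>_reduction_pct` under condition `drug`.
#'
#' @param metrics A [metric_table()].
#' @param drug Drug condition label present in `metrics`.
#' @param metric_names Metrics to reduce.
#' @return The augmented [metric_table()].
#' @export
add_reduction_metrics <- function(metrics, drug,
                                  metric_names = c("duration_s",
                                                   "post_rate_1s")) {
  out <- as.data.frame(metrics)
  for (m in metric_names) {
    ctl <- metrics[metrics$condition == "control" & metrics$metric == m, ]
    drg <- metrics[metrics$condition == drug & metrics$metric == m, ]
    ids <- intersect(ctl$neuron_id, drg$neuron_id)
    if (length(ids) == 0) next
    cv <- ctl$value[match(ids, ctl$neuron_id)]
    dv <- drg$value[match(ids, drg$neuron_id)]
    red <- percent_reduction(cv, dv)
    out <- rbind(out, data.frame(
      neuron_id = ids, nucleus = ctl$nucleus[match(ids, ctl$neuron_id)],
      condition = drug, metric = paste0(m, "_reduction_pct"),
      value = as.numeric(red), units = "%", stringsAsFactors = FALSE))
  }
  metric_table(out$neuron_id, out$nucleus, out$condition, out$metric,
               out$value, out$units)
}
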