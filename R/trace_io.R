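#' Construct a voltage-clamp current trace
#'
#' A uniformly sampled current recording with acquisition metadata.  The
#' fixed conventions of the package apply: time in seconds, current in pA,
#' potentials in mV, inward current negative.
#'
#' @param samples Numeric vector of current samples, pA.
#' @param sampling_rate Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @param holding_potential Holding potential, mV.
#' @param burst_window Optional `c(start, end)` of the burst stimulus, s.
#' @param condition Condition label (e.g. `"control"`, `"NAS"`).
#' @param neuron_id Neuron identifier.
#' @param trace_index Index of the trace within the neuron (1..3 typically).
#' @return An object of class `epsc_trace`.
#' @examples
#' tr <- epsc_trace(rnorm(1000), sampling_rate = 1000)
#' trace_times(tr)[1:3]
#' @export
epsc_trace <- function(samples, sampling_rate, t0 = 0,
                       holding_potential = NA_real_, burst_window = NULL,
                       condition = NA_character_, neuron_id = NA_character_,
                       trace_index = NA_integer_) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  samples <- as.numeric(samples)
  tr <- structure(
    list(samples = samples, sampling_rate = sampling_rate, t0 = t0,
         holding_potential = holding_potential, burst_window = burst_window,
         condition = condition, neuron_id = neuron_id,
         trace_index = trace_index),
    class = "epsc_trace"
  )
  if (!is.null(burst_window)) {
    ext <- trace_extent(tr)
    if (length(burst_window) != 2 || burst_window[1] >= burst_window[2])
      stop("burst_window must be c(start, end) with start < end")
    if (burst_window[1] < ext[1] || burst_window[2] > ext[2])
      stop("burst_window lies outside the trace extent")
  }
  tr
}

#' @rdname epsc_trace
#' @param trace An `epsc_trace`.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' @rdname epsc_trace
#' @export
trace_extent <- function(trace) {
  c(trace$t0, trace$t0 + (length(trace$samples) - 1) / trace$sampling_rate)
}

#' @export
print.epsc_trace <- function(x, ...) {
  ext <- trace_extent(x)
  cat(sprintf(
    "<epsc_trace> %d samples @ %g Hz, t = [%.4g, %.4g] s, hold %g mV\n",
    length(x$samples), x$sampling_rate, ext[1], ext[2],
    x$holding_potential))
  if (!is.null(x$burst_window))
    cat(sprintf("  burst window [%g, %g] s; condition %s\n",
                x$burst_window[1], x$burst_window[2], x$condition))
  invisible(x)
}

#' Construct an EPSC event train
#'
#' Detected or ground-truth EPSC peak times with amplitudes (negative,
#' relative to local baseline).
#'
#' @param times Sorted event peak times, s.
#' @param amplitudes Event amplitudes, pA (negative).
#' @param source `"detected"` or `"truth"`.
#' @return Object of class `event_train` (a data frame).
#' @examples
#' event_train(c(0.1, 0.5), c(-20, -15), source = "truth")
#' @export
event_train <- function(times = numeric(), amplitudes = numeric(),
                        source = c("detected", "truth")) {
  source <- match.arg(source)
  if (length(times) != length(amplitudes))
    stop("times and amplitudes must have equal length")
  if (is.unsorted(times, strictly = FALSE))
    stop("event times must be sorted")
  if (any(amplitudes >= 0))
    stop("EPSC amplitudes must be negative (inward)")
  out <- data.frame(time_s = as.numeric(times),
                    amplitude_pA = as.numeric(amplitudes))
  attr(out, "source") <- source
  class(out) <- c("event_train", "data.frame")
  out
}

#' Write / read a trace as delimited text with a metadata sidecar
#'
#' The trace is stored as two tab-separated columns (`time_s`,
#' `current_pA`); acquisition metadata (sampling rate, holding potential,
#' burst window, condition, neuron id) goes to a YAML sidecar so the files
#' stay diff-able and self-describing.
#'
#' @param trace An [epsc_trace()].
#' @param path Path of the trace data file.
#' @param metadata_path Path of the YAML sidecar (default `path` + `.yml`).
#' @return `write_trace` returns `path` invisibly; `read_trace` returns an
#'   [epsc_trace()].  `read_trace` validates that any time column present is
#'   uniform and consistent with the declared sampling rate to one part in
#'   1e6.
#' @examples
#' tr <- epsc_trace(rnorm(100), 1000)
#' f <- tempfile(fileext = ".tsv")
#' write_trace(tr, f)
#' tr2 <- read_trace(f)
#' stopifnot(identical(tr$samples, tr2$samples))
#' @export
write_trace <- function(trace, path, metadata_path = paste0(path, ".yml")) {
  stopifnot(inherits(trace, "epsc_trace"))
  df <- data.frame(time_s = trace_times(trace),
                   current_pA = trace$samples)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    sampling_rate = trace$sampling_rate,
    t0 = trace$t0,
    holding_potential = trace$holding_potential,
    burst_window = if (is.null(trace$burst_window)) NULL
                   else as.numeric(trace$burst_window),
    condition = trace$condition,
    neuron_id = trace$neuron_id,
    trace_index = trace$trace_index
  )
  yaml::write_yaml(meta, metadata_path, precision = 17)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, metadata_path = paste0(path, ".yml")) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata sidecar not found: ", metadata_path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "current_pA") %in% names(df)))
    stop("trace file must have columns time_s, current_pA: ", path)
  meta <- yaml::read_yaml(metadata_path)
  fs <- meta$sampling_rate
  if (is.null(fs) || fs <= 0) stop("metadata missing valid sampling_rate")
  n <- nrow(df)
  if (n > 1) {
    expected <- df$time_s[1] + (seq_len(n) - 1) / fs
    tol <- max(1e-6 * max(abs(expected)), 1e-12)
    bad <- which(abs(df$time_s - expected) > tol)
    if (length(bad) > 0)
      stop(sprintf(
        "time column inconsistent with sampling rate at data line %d",
        bad[1]))
  }
  epsc_trace(df$current_pA, sampling_rate = fs, t0 = df$time_s[1],
             holding_potential = meta$holding_potential %||% NA_real_,
             burst_window = if (is.null(meta$burst_window)) NULL
                            else as.numeric(meta$burst_window),
             condition = meta$condition %||% NA_character_,
             neuron_id = meta$neuron_id %||% NA_character_,
             trace_index = meta$trace_index %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read EPSC event lists as CSV
#'
#' Columns `time_s`, `amplitude_pA`; order and digits are preserved on a
#' round trip.  Reading rejects unsorted times.
#'
#' @param events An [event_train()].
#' @param path CSV path.
#' @return `read_events` returns an [event_train()].
#' @examples
#' ev <- event_train(c(0.1, 0.2), c(-12, -30), source = "truth")
#' f <- tempfile(fileext = ".csv")
#' write_events(ev, f)
#' read_events(f)
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_train"))
  df <- as.data.frame(events)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param source Source tag to attach on read.
#' @export
read_events <- function(path, source = c("detected", "truth")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) return(event_train(source = source))
  if (!all(c("time_s", "amplitude_pA") %in% names(df)))
    stop("event file must have columns time_s, amplitude_pA: ", path)
  event_train(df$time_s, df$amplitude_pA, source = source)
}

#' Write / read a simulation configuration as YAML
#'
#' All pipeline defaults are overridable from a plain-text config file;
#' unknown keys are rejected.
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `read_sim_config` returns a validated [sim_config()].
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_sim_config(sim_config(noise_sd = 3), f)
#' read_sim_config(f)$noise_sd
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path,
                   precision = 17)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Assemble per-neuron metric rows
#'
#' One row per (neuron, condition, metric); the long format consumed by
#' [build_report()].
#'
#' @param neuron_id,nucleus,condition,metric,value,units Vectors, recycled
#'   to a common length.  `nucleus` must be `"PHN"` or `"INC"`.
#' @return A data frame of class `metric_table`.
#' @export
metric_table <- function(neuron_id, nucleus, condition, metric, value,
                         units) {
  df <- data.frame(neuron_id = neuron_id, nucleus = nucleus,
                   condition = condition, metric = metric,
                   value = as.numeric(value), units = units,
                   stringsAsFactors = FALSE)
  if (!all(df$nucleus %in% c("PHN", "INC")))
    stop("nucleus must be PHN or INC")
  key <- paste(df$neuron_id, df$condition, df$metric)
  if (anyDuplicated(key))
    stop("duplicate (neuron, condition, metric) rows")
  class(df) <- c("metric_table", "data.frame")
  df
}
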