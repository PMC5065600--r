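# Activation detection: each peak in the current trace is one activation of
# the electrosurgical device. Detection is a plain amplitude threshold on
# the raw current (the simulator guarantees >= 6 sigma separation between
# baseline noise and the activation amplitude), followed by a fixed
# post-pass order: threshold runs -> merge close events -> drop short events.

#' Detect device activations in a current trace
#'
#' An event is a maximal run of samples with `current >= threshold`;
#' `start_s` is the first supra-threshold timestamp and `end_s` the last
#' supra-threshold timestamp plus one median sampling interval (so an
#' isolated supra-threshold sample still has nonzero duration). Events
#' separated by less than `merge_gap_s` are then merged, and events shorter
#' than `min_event_duration_s` after merging are dropped.
#'
#' Negative or non-finite current samples are clamped to 0 with a warning
#' (sensor artifact policy).
#'
#' @param trace data.frame with columns `t_s` (strictly increasing seconds)
#'   and `current` (current units).
#' @param config a [detector_config()].
#' @return data.frame of sorted, non-overlapping events with columns
#'   `start_s`, `end_s`; zero rows if nothing crosses the threshold.
#' @export
detect_activations <- function(trace, config = detector_config()) {
  trace <- validate_trace(trace)
  t <- trace$t_s
  x <- trace$current
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(t) == 0) return(empty)

  med_dt <- if (length(t) >= 2) stats::median(diff(t)) else 0
  supra <- x >= config$threshold
  if (!any(supra)) return(empty)

  r <- rle(supra)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values
  starts <- t[run_start[keep]]
  ends <- t[run_end[keep]] + med_dt

  ev <- merge_events(data.frame(start_s = starts, end_s = ends),
                     config$merge_gap_s)
  ev <- ev[ev$end_s - ev$start_s >= config$min_event_duration_s, ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

merge_events <- function(ev, merge_gap_s) {
  n <- nrow(ev)
  if (n <= 1 || merge_gap_s <= 0) return(ev)
  group <- cumsum(c(1, as.integer(
    ev$start_s[-1] - ev$end_s[-n] >= merge_gap_s)))
  data.frame(
    start_s = tapply(ev$start_s, group, min),
    end_s = tapply(ev$end_s, group, max),
    row.names = NULL)
}

validate_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("t_s", "current") %in% names(trace)))
    stop("format error: trace must be a data.frame with columns t_s, current",
         call. = FALSE)
  if (nrow(trace) > 1 && any(diff(trace$t_s) <= 0))
    stop("format error: trace timestamps must be strictly increasing",
         call. = FALSE)
  bad <- !is.finite(trace$current) | trace$current < 0
  if (any(bad)) {
    warning(sum(bad), " negative/non-finite current sample(s) clamped to 0")
    trace$current[bad] <- 0
  }
  trace
}

#' Detect activations in the observed prefix of a trace
#'
#' Real-time variant: equivalent to [detect_activations()] applied to the
#' sub-trace with `t_s <= t_now_s`; an event still open at `t_now_s` is
#' truncated there. Predictions made during a procedure may only use this.
#'
#' @inheritParams detect_activations
#' @param t_now_s current time in seconds since first incision (>= 0).
#' @return data.frame of events, as [detect_activations()].
#' @export
detect_prefix <- function(trace, config = detector_config(), t_now_s) {
  if (!is.numeric(t_now_s) || length(t_now_s) != 1 || t_now_s < 0)
    stop("argument error: t_now_s must be a single number >= 0",
         call. = FALSE)
  trace <- validate_trace(trace)
  sub <- trace[trace$t_s <= t_now_s, , drop = FALSE]
  ev <- detect_activations(sub, config)
  if (nrow(ev) > 0) {
    ev$end_s <- pmin(ev$end_s, t_now_s)
    ev <- ev[ev$end_s > ev$start_s, , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}
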