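# Fixed 9-feature summary of the activation pattern observed up to a
# decision time. Captures what distinguishes slow from fast operators --
# burst durations and inter-burst intervals -- plus elapsed-pattern context.
# Elapsed time itself is NOT a feature: each decision time has its own
# classifier, so it would be constant within one training set.

#' Names of the activation-pattern features, in order
#' @return character vector of length 9.
#' @export
feature_names <- function() {
  c("n_events", "total_active_s", "mean_event_dur_s", "sd_event_dur_s",
    "mean_gap_s", "sd_gap_s", "time_since_last_end_s", "first_event_start_s",
    "recent_active_fraction")
}

#' Extract the activation-pattern feature vector at a decision time
#'
#' Pure deterministic function of the detected events and the decision
#' time. Gap statistics are over the pauses between consecutive events
#' (`start[i+1] - end[i]`). `recent_active_fraction` is the active time in
#' the trailing 5-min (300 s) window divided by 300 s. Sentinels keep the
#' vector finite without imputation: undefined means/SDs are 0, and with no
#' events both `time_since_last_end_s` and `first_event_start_s` equal
#' `t_now_s`.
#'
#' @param events data.frame of activation events (`start_s`, `end_s`), all
#'   ending at or before `t_now_s`.
#' @param t_now_s decision time in seconds (> 0).
#' @param recent_window_s trailing window length for
#'   `recent_active_fraction`; default 300 s matches the protocol's 5-min
#'   decision cadence.
#' @return named numeric vector, names as [feature_names()].
#' @export
extract_features <- function(events, t_now_s, recent_window_s = 300) {
  if (!is.numeric(t_now_s) || length(t_now_s) != 1 || t_now_s <= 0)
    stop("argument error: t_now_s must be a single number > 0", call. = FALSE)
  if (nrow(events) > 0) {
    if (any(events$end_s > t_now_s + 1e-9))
      stop("argument error: event ends after t_now_s", call. = FALSE)
    events <- events[order(events$start_s), , drop = FALSE]
  }

  n <- nrow(events)
  if (n == 0) {
    fv <- c(0, 0, 0, 0, 0, 0, t_now_s, t_now_s, 0)
    names(fv) <- feature_names()
    return(fv)
  }

  dur <- events$end_s - events$start_s
  gaps <- if (n >= 2) events$start_s[-1] - events$end_s[-n] else numeric(0)

  win_lo <- t_now_s - recent_window_s
  recent <- sum(pmax(0, pmin(events$end_s, t_now_s) -
                       pmax(events$start_s, win_lo)))

  fv <- c(n,
          sum(dur),
          mean(dur),
          if (n >= 2) stats::sd(dur) else 0,
          if (length(gaps)) mean(gaps) else 0,
          if (length(gaps) >= 2) stats::sd(gaps) else 0,
          t_now_s - events$end_s[n],
          events$start_s[1],
          min(1, recent / recent_window_s))
  names(fv) <- feature_names()
  fv
}
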