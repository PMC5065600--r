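# The sequential advice loop: starting 15 min after incision and every
# 5 min thereafter, ask the horizon classifier whether the remaining
# duration exceeds the 25-min preparation lead time. Stop and advise at the
# first "no"; if every prediction up to the 45-min cap says "longer", emit
# a forced (capped) advice at the cap -- downstream scheduling always needs
# a preparation trigger. Decision times are a grid anchored at the first
# incision, not wall-clock polling, so replay is exactly reproducible.

#' Run the advice protocol over a procedure trace
#'
#' Iterates the decision grid; at each time `t` it computes
#' [detect_prefix()] on the trace, extracts features, and asks the bank via
#' [predict_longer()]. Degenerate cases: a trace that ends before the first
#' decision time yields advice at trace end with an empty trail (the next
#' patient's preparation is already late); a trace that ends between grid
#' times while the bank still says "longer" also yields advice at trace
#' end. No sample after the advice time is ever read (prefix causality).
#'
#' @param bank a `classifier_bank` or [oracle_bank()]; its grid and lead
#'   time must match `protocol`.
#' @param trace data.frame `t_s`, `current` covering the procedure so far.
#' @param protocol a [protocol_config()].
#' @param detector a [detector_config()].
#' @param procedure_id optional label copied into the result.
#' @return an `advice_result`: list with `procedure_id`, `advice_time_s`,
#'   `capped`, and `decision_trail` (data.frame `decision_time_s`,
#'   `predicted_longer`, `decision_value`).
#' @export
run_protocol <- function(bank, trace, protocol = protocol_config(),
                         detector = detector_config(),
                         procedure_id = NA_character_) {
  grid <- decision_grid(protocol)
  if (length(bank$decision_times_s) != length(grid) ||
      any(abs(bank$decision_times_s - grid) > 1e-9) ||
      abs(bank$lead_time_s - protocol$lead_time_s) > 1e-9)
    stop("configuration error: bank decision grid/lead time does not match ",
         "the protocol", call. = FALSE)

  trace <- validate_trace(trace)
  trace_end <- if (nrow(trace)) max(trace$t_s) else 0
  trail <- data.frame(decision_time_s = numeric(0),
                      predicted_longer = logical(0),
                      decision_value = numeric(0))

  if (trace_end < protocol$first_decision_s) {
    return(advice_result(procedure_id, trace_end, capped = FALSE, trail))
  }

  for (t in grid) {
    if (t > trace_end) {
      # procedure ended between grid times with the bank still saying longer
      return(advice_result(procedure_id, trace_end, capped = FALSE, trail))
    }
    ev <- detect_prefix(trace, detector, t)
    dv <- decision_value(bank, ev, t)
    longer <- dv > 0
    trail <- rbind(trail, data.frame(decision_time_s = t,
                                     predicted_longer = longer,
                                     decision_value = dv))
    if (!longer) {
      return(advice_result(procedure_id, t, capped = FALSE, trail))
    }
  }
  advice_result(procedure_id, protocol$cap_s, capped = TRUE, trail)
}

advice_result <- function(procedure_id, advice_time_s, capped, trail) {
  res <- list(procedure_id = as.character(procedure_id),
              advice_time_s = advice_time_s,
              capped = capped,
              decision_trail = trail)
  class(res) <- "advice_result"
  res
}

#' Replay a recorded procedure through the protocol
#'
#' Offline stand-in for the live sensor/server loop: identical result to
#' [run_protocol()] on `record$trace`, with one structured JSON log line
#' per decision (decision time, feature vector, decision value, prediction)
#' written to `log_path` when given.
#'
#' @param record a `procedure_record`.
#' @inheritParams run_protocol
#' @param log_path optional path for a JSON-lines decision log.
#' @return an `advice_result`.
#' @export
replay_stream <- function(record, bank, protocol = protocol_config(),
                          detector = detector_config(), log_path = NULL) {
  res <- run_protocol(bank, record$trace, protocol, detector,
                      procedure_id = record$procedure_id)
  if (!is.null(log_path)) {
    lines <- vapply(seq_len(nrow(res$decision_trail)), function(i) {
      t <- res$decision_trail$decision_time_s[i]
      ev <- detect_prefix(record$trace, detector, t)
      jsonlite::toJSON(list(
        procedure_id = record$procedure_id,
        decision_time_s = t,
        features = as.list(extract_features(ev, t)),
        decision_value = res$decision_trail$decision_value[i],
        predicted_longer = res$decision_trail$predicted_longer[i]),
        auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, log_path)
  }
  res
}
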