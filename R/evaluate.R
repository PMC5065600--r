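# Timing-error evaluation: the ideal moment to start preparing the next
# patient is `lead_time` before the last suture (clamped at 0 for very
# short procedures). Errors are signed minutes, positive = advice later
# than ideal, matching the above/below-the-line reading of a timing plot.
# Advice within the 10-min margin of the ideal is acceptable.

#' Score advice times against ground truth
#'
#' Matches advices to truths by `procedure_id` and computes per-procedure
#' signed timing errors (`advice - ideal`, ideal = `max(0, total_duration -
#' lead_time)`), the overall mean absolute error in minutes, the MAE
#' stratified to procedures longer than 40 min, and
#' too-early/acceptable/too-late band counts at the protocol margin.
#'
#' @param advices list of `advice_result`s.
#' @param truths list of `procedure_record`s, matched one-to-one by id.
#' @param protocol a [protocol_config()] (lead time and margin).
#' @param long_threshold_s stratification boundary for the long-procedure
#'   MAE; default 2400 s (40 min).
#' @return an `evaluation_report`: list with `n`, `mae_min`,
#'   `mae_min_over_40`, `band_counts` (named too_early/acceptable/
#'   too_late), `per_procedure` (data.frame), and `baseline_mae_min`
#'   (`NA` until filled by the caller).
#' @export
score_advice <- function(advices, truths, protocol = protocol_config(),
                         long_threshold_s = 2400) {
  if (length(advices) == 0 || length(truths) == 0)
    stop("argument error: advices and truths must be non-empty",
         call. = FALSE)
  aid <- vapply(advices, `[[`, character(1), "procedure_id")
  tid <- vapply(truths, `[[`, character(1), "procedure_id")
  unmatched <- c(setdiff(aid, tid), setdiff(tid, aid))
  if (length(unmatched) || anyDuplicated(aid) || anyDuplicated(tid))
    stop("data error: unmatched or duplicated procedure ids: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)

  truths <- truths[match(aid, tid)]
  duration_s <- vapply(truths, `[[`, numeric(1), "total_duration_s")
  advice_s <- vapply(advices, `[[`, numeric(1), "advice_time_s")
  ideal_s <- pmax(0, duration_s - protocol$lead_time_s)
  error_s <- advice_s - ideal_s
  band <- ifelse(error_s > protocol$margin_s, "too_late",
                 ifelse(error_s < -protocol$margin_s, "too_early",
                        "acceptable"))

  per <- data.frame(procedure_id = aid,
                    total_duration_s = duration_s,
                    ideal_time_s = ideal_s,
                    advice_time_s = advice_s,
                    error_s = error_s,
                    band = band,
                    stringsAsFactors = FALSE)
  long <- duration_s > long_threshold_s

  rep <- list(n = length(advices),
              mae_min = mean(abs(error_s)) / 60,
              mae_min_over_40 = if (any(long))
                mean(abs(error_s[long])) / 60 else NA_real_,
              band_counts = c(too_early = sum(band == "too_early"),
                              acceptable = sum(band == "acceptable"),
                              too_late = sum(band == "too_late")),
              per_procedure = per,
              baseline_mae_min = NA_real_)
  class(rep) <- "evaluation_report"
  rep
}

#' Fixed-booked-duration baseline scheduler
#'
#' Comparator emulating a scheduler who trusts the booked duration: every
#' procedure gets advice at `assumed_duration_s - lead_time_s` (clamped at
#' 0), regardless of the signal. This is an offline stand-in comparator,
#' not the live operating-room staff judgement.
#'
#' @param truths list of `procedure_record`s.
#' @param assumed_duration_s the booked duration; must exceed the lead
#'   time.
#' @param protocol a [protocol_config()].
#' @return list of `advice_result`s with empty trails.
#' @export
baseline_fixed_lead <- function(truths, assumed_duration_s,
                                protocol = protocol_config()) {
  if (!is.numeric(assumed_duration_s) || length(assumed_duration_s) != 1 ||
      assumed_duration_s <= protocol$lead_time_s)
    stop("argument error: assumed_duration_s must exceed the lead time",
         call. = FALSE)
  t_adv <- max(0, assumed_duration_s - protocol$lead_time_s)
  lapply(truths, function(rec) {
    advice_result(rec$procedure_id, t_adv, capped = FALSE,
                  data.frame(decision_time_s = numeric(0),
                             predicted_longer = logical(0),
                             decision_value = numeric(0)))
  })
}
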