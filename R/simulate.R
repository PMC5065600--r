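# Synthetic electrosurgical procedure generator.
#
# Draw order within one seeded procedure is a stable contract (tests replay
# it): profile index, access minutes, closure minutes, workload seconds,
# then alternating burst/gap draws, then (only if a trace is built)
# timestamp jitter and per-sample noise.

BURST_GAMMA_SHAPE <- 2  # shape of the Gamma burst-duration law

#' Derive a per-procedure seed from a cohort seed and index
#'
#' Stable integer hash so a cohort can be extended without reshuffling the
#' seeds of existing procedures. Always in `[1, 2^31 - 2]`.
#'
#' @param seed cohort seed (integer).
#' @param index 1-based procedure index.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  h <- (((seed %% m) * 48271) %% m + (index %% m) * 16807) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Simulate one laparoscopic procedure
#'
#' Generates a phase-structured current trace and its ground truth: a silent
#' access phase, a dissection phase of alternating electrosurgical bursts
#' (Gamma durations, effective mean `burst_duration_mean_s * speed`) and
#' pauses (Exponential, effective mean `burst_gap_mean_s / speed`) that
#' stops once cumulative burst time reaches the sampled workload, and a
#' silent closure phase ending at the last suture. Total duration is the
#' sum of the three phase durations. Identical `(config, procedure_id,
#' seed)` yields a bit-identical record.
#'
#' @param config a [sim_config()].
#' @param procedure_id label for the procedure.
#' @param seed integer seed for this procedure.
#' @param include_trace if `FALSE`, skip synthesis of the sampled current
#'   trace (durations and ground-truth events are unaffected); useful for
#'   large Monte-Carlo studies of durations only.
#' @return a `procedure_record`: list with `procedure_id`, `trace`
#'   (data.frame `t_s`, `current`), `total_duration_s`, `true_events`
#'   (data.frame `start_s`, `end_s`), `phase_durations_s` (named access/
#'   dissection/closure), `profile`, `seed`.
#' @export
simulate_procedure <- function(config, procedure_id, seed,
                               include_trace = TRUE) {
  validate_sim_config(config)
  seed <- as.integer(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  w <- vapply(config$profiles, `[[`, numeric(1), "weight")
  pidx <- sample.int(length(config$profiles), 1, prob = w / sum(w))
  profile <- config$profiles[[pidx]]

  access_s <- 60 * stats::rlnorm(1, config$access_phase_lognormal[1],
                                 config$access_phase_lognormal[2])
  closure_s <- 60 * stats::rlnorm(1, config$closure_phase_lognormal[1],
                                  config$closure_phase_lognormal[2])
  workload_s <- max(stats::rnorm(1, config$dissection_workload_mean_s,
                                 config$dissection_workload_sd_s), 30)

  eff_burst <- profile$burst_duration_mean_s * profile$speed
  eff_gap <- profile$burst_gap_mean_s / profile$speed

  bursts <- numeric(0)
  gaps <- numeric(0)
  cum <- 0
  repeat {
    b <- stats::rgamma(1, shape = BURST_GAMMA_SHAPE,
                       scale = eff_burst / BURST_GAMMA_SHAPE)
    bursts <- c(bursts, b)
    cum <- cum + b
    if (cum >= workload_s) break
    gaps <- c(gaps, stats::rexp(1, rate = 1 / eff_gap))
  }

  starts <- access_s + cumsum(c(0, bursts[-length(bursts)] + gaps))
  ends <- starts + bursts
  dissection_s <- ends[length(ends)] - access_s
  total_s <- access_s + dissection_s + closure_s
  true_events <- data.frame(start_s = starts, end_s = ends)

  trace <- NULL
  if (include_trace) {
    trace <- synthesize_trace(total_s, true_events, config)
  }

  rec <- list(procedure_id = as.character(procedure_id),
              trace = trace,
              total_duration_s = total_s,
              true_events = true_events,
              phase_durations_s = c(access = access_s,
                                    dissection = dissection_s,
                                    closure = closure_s),
              profile = profile,
              seed = seed)
  class(rec) <- "procedure_record"
  rec
}

# Sample the current signal over [0, total_s]: jittered ~10 Hz timestamps,
# folded-normal baseline noise outside bursts, amplitude + noise inside.
synthesize_trace <- function(total_s, events, config) {
  dt <- 1 / config$sample_rate_hz
  n <- floor(total_s / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  if (config$timing_jitter_sd_s > 0) {
    t <- t + stats::rnorm(n, 0, config$timing_jitter_sd_s)
  }
  t[1] <- 0
  t <- pmin(pmax(t, 0), total_s)
  t <- enforce_increasing(t)

  inside <- in_event(t, events)
  current <- numeric(n)
  n_in <- sum(inside)
  if (n_in > 0) {
    current[inside] <- config$activation_amplitude +
      stats::rnorm(n_in, 0, config$activation_noise_sd)
  }
  if (n_in < n) {
    current[!inside] <- abs(stats::rnorm(n - n_in, 0, config$baseline_noise_sd))
  }
  current <- pmax(current, 0)
  data.frame(t_s = t, current = current)
}

# TRUE for points lying in [start, end) of any event (events sorted,
# non-overlapping).
in_event <- function(t, events) {
  if (nrow(events) == 0) return(rep(FALSE, length(t)))
  b <- as.vector(rbind(events$start_s, events$end_s))
  findInterval(t, b) %% 2L == 1L
}

enforce_increasing <- function(t) {
  eps <- 1e-9
  for (i in seq_along(t)[-1]) {
    if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + eps
  }
  t
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a cohort of procedures
#'
#' Per-procedure seeds are derived deterministically from the cohort seed
#' with [derive_seed()], so a cohort is extendable without reshuffling, and
#' each procedure draws its surgeon profile by the configured weights.
#'
#' @param config a [sim_config()].
#' @param n number of procedures (>= 1).
#' @param seed cohort seed.
#' @param id_prefix prefix of generated procedure ids.
#' @inheritParams simulate_procedure
#' @return list of `procedure_record`s with distinct ids.
#' @export
simulate_cohort <- function(config, n, seed, id_prefix = "proc",
                            include_trace = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("argument error: n must be a positive integer", call. = FALSE)
  lapply(seq_len(n), function(i) {
    simulate_procedure(config,
                       procedure_id = sprintf("%s_%03d", id_prefix, i),
                       seed = derive_seed(seed, i),
                       include_trace = include_trace)
  })
}
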