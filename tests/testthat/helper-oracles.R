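# Independent oracles used across the suite. These deliberately use naive
# per-sample / per-event loops, not the package's vectorised paths.

# Brute-force threshold-scan detector: walk the samples one by one, close a
# run at the first sub-threshold sample, then apply the same post-pass
# order as the detector contract (merge close events, drop short events).
oracle_detect <- function(trace, config) {
  t <- trace$t_s
  x <- trace$current
  n <- length(t)
  med_dt <- if (n >= 2) stats::median(diff(t)) else 0
  starts <- ends <- numeric(0)
  cur_start <- NA_real_
  last_supra <- NA_real_
  for (i in seq_len(n)) {
    if (x[i] >= config$threshold) {
      if (is.na(cur_start)) cur_start <- t[i]
      last_supra <- t[i]
    } else if (!is.na(cur_start)) {
      starts <- c(starts, cur_start)
      ends <- c(ends, last_supra + med_dt)
      cur_start <- NA_real_
    }
  }
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start)
    ends <- c(ends, last_supra + med_dt)
  }
  # merge events separated by < merge_gap_s
  if (length(starts) > 1 && config$merge_gap_s > 0) {
    ms <- starts[1]; me <- ends[1]
    out_s <- out_e <- numeric(0)
    for (i in 2:length(starts)) {
      if (starts[i] - me < config$merge_gap_s) {
        me <- max(me, ends[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
    out_s <- c(out_s, ms); out_e <- c(out_e, me)
    starts <- out_s; ends <- out_e
  }
  keep <- (ends - starts) >= config$min_event_duration_s
  data.frame(start_s = starts[keep], end_s = ends[keep])
}

# Random short trace with supra-threshold bursts, for oracle-equivalence
# sweeps. Returns the trace only; the detector settings are drawn by the
# caller.
random_trace <- function(span_s = stats::runif(1, 20, 120),
                         rate_hz = stats::runif(1, 8, 12)) {
  t <- seq(0, span_s, by = 1 / rate_hz)
  x <- abs(stats::rnorm(length(t), 0, 0.25))
  k <- sample(0:6, 1)
  for (j in seq_len(k)) {
    s <- stats::runif(1, 0, span_s)
    d <- stats::runif(1, 0.05, 4)
    x[t >= s & t < s + d] <- 1.2 + stats::rnorm(sum(t >= s & t < s + d), 0, 0.1)
  }
  data.frame(t_s = t, current = pmax(x, 0))
}

# Independent replay of the generator's seeded draw order (profile index,
# access, closure, workload, alternating burst/gap) computing the total
# duration and ground-truth events without building a trace.
oracle_simulate_duration <- function(config, seed) {
  set.seed(as.integer(seed))
  w <- vapply(config$profiles, function(p) p$weight, numeric(1))
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
  pos <- access_s
  cum <- 0
  starts <- ends <- numeric(0)
  repeat {
    b <- stats::rgamma(1, shape = 2, scale = eff_burst / 2)
    starts <- c(starts, pos)
    ends <- c(ends, pos + b)
    pos <- pos + b
    cum <- cum + b
    if (cum >= workload_s) break
    g <- stats::rexp(1, rate = 1 / eff_gap)
    pos <- pos + g
  }
  list(total_s = access_s + (pos - access_s) + closure_s,
       access_s = access_s, closure_s = closure_s,
       dissection_s = pos - access_s,
       events = data.frame(start_s = starts, end_s = ends),
       profile = profile)
}

# Closed-form advice time of the oracle-driven protocol for a procedure of
# duration D: first grid time t with D - t <= lead, else the cap (or trace
# end when the procedure is over before the first decision).
closed_form_advice <- function(duration_s, protocol) {
  grid <- decision_grid(protocol)
  if (duration_s < protocol$first_decision_s) return(duration_s)
  hit <- grid[duration_s - grid <= protocol$lead_time_s & grid <= duration_s]
  if (length(hit)) hit[1] else {
    feasible <- grid[grid <= duration_s]
    if (length(feasible) == length(grid)) protocol$cap_s else duration_s
  }
}

# A small fast-running simulator configuration for tests that only need
# structure, not the default study conditions.
tiny_sim_config <- function(...) {
  sim_config(access_phase_lognormal = c(log(2), 0.2),
             closure_phase_lognormal = c(log(2), 0.2),
             dissection_workload_mean_s = 60,
             dissection_workload_sd_s = 15,
             ...)
}

# Two widely separated single-profile configs whose durations fall on
# opposite sides of the 40-min boundary by construction: used to build
# linearly separable training cohorts.
fast_short_config <- function() {
  sim_config(access_phase_lognormal = c(log(4), 0.1),
             closure_phase_lognormal = c(log(4), 0.1),
             dissection_workload_mean_s = 300,
             dissection_workload_sd_s = 30,
             profiles = list(surgeon_profile("fast", speed = 2.0)))
}

slow_long_config <- function() {
  sim_config(access_phase_lognormal = c(log(10), 0.1),
             closure_phase_lognormal = c(log(15), 0.1),
             dissection_workload_mean_s = 900,
             dissection_workload_sd_s = 60,
             profiles = list(surgeon_profile("slow", speed = 0.5)))
}
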