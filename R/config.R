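#' Surgeon activation profile
#'
#' Describes how one surgeon (or one class of surgeons) uses the
#' electrosurgical device during the dissection phase. `speed` is a
#' dimensionless work-rate multiplier relative to a reference experienced
#' surgeon (1.0). The effective mean burst duration scales *proportionally*
#' with speed and the effective mean inter-burst gap scales *inversely* with
#' speed, so a slow surgeon (trainee) produces shorter activations separated
#' by longer pauses -- the pattern a duration classifier can exploit.
#'
#' @param name label for the profile.
#' @param speed positive work-rate multiplier; 1.0 = reference surgeon.
#' @param burst_duration_mean_s base mean activation-burst duration in
#'   seconds at speed 1; effective mean is `burst_duration_mean_s * speed`.
#' @param burst_gap_mean_s base mean gap between bursts in seconds at
#'   speed 1; effective mean is `burst_gap_mean_s / speed`.
#' @param weight sampling weight used when a cohort draws profiles.
#' @return an object of class `surgeon_profile`.
#' @export
surgeon_profile <- function(name, speed = 1.0,
                            burst_duration_mean_s = 4.0,
                            burst_gap_mean_s = 8.0,
                            weight = 1.0) {
  p <- list(name = as.character(name), speed = speed,
            burst_duration_mean_s = burst_duration_mean_s,
            burst_gap_mean_s = burst_gap_mean_s, weight = weight)
  class(p) <- "surgeon_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  for (f in c("speed", "burst_duration_mean_s", "burst_gap_mean_s", "weight")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("config error: surgeon_profile field '", f,
           "' must be a single positive finite number", call. = FALSE)
    }
  }
  invisible(p)
}

#' Simulation configuration
#'
#' Parameters of the synthetic procedure generator. A procedure is modelled
#' as three consecutive phases: access (port placement, silent), dissection
#' (gallbladder removed from the liver bed; all electrosurgical bursts live
#' here), and closure (suturing, silent). Phase durations for access and
#' closure are lognormal in minutes; the dissection phase runs alternating
#' Gamma-distributed bursts and Exponential gaps until a sampled cumulative
#' active-time workload is met. Defaults target a cohort mean total duration
#' of about 60 min with SD about 20 min so that the 40-min short/long split
#' is non-trivial.
#'
#' @param sample_rate_hz nominal sampling rate of the current sensor (Hz).
#' @param access_phase_lognormal `c(mu, sigma)` of log-minutes for the
#'   access phase duration.
#' @param closure_phase_lognormal `c(mu, sigma)` of log-minutes for the
#'   closure phase duration.
#' @param dissection_workload_mean_s mean required cumulative active
#'   (burst) time in seconds.
#' @param dissection_workload_sd_s SD of the workload draw (seconds).
#' @param baseline_noise_sd sensor noise SD outside bursts (current units).
#' @param activation_amplitude current level during a burst (current units);
#'   must exceed `6 * baseline_noise_sd` so bursts are detectable by
#'   construction at the default threshold.
#' @param activation_noise_sd noise SD added on top of the amplitude.
#' @param profiles list of [surgeon_profile()] objects; their `weight`
#'   fields are normalised to sampling probabilities.
#' @param timing_jitter_sd_s Gaussian SD of per-sample timestamp jitter
#'   (seconds), modelling the "approximately 10 Hz" logger.
#' @param seed default integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(sample_rate_hz = 10,
                       access_phase_lognormal = c(log(8), 0.40),
                       closure_phase_lognormal = c(log(14), 0.40),
                       dissection_workload_mean_s = 620,
                       dissection_workload_sd_s = 200,
                       baseline_noise_sd = 0.05,
                       activation_amplitude = 1.0,
                       activation_noise_sd = 0.1,
                       profiles = default_profiles(),
                       timing_jitter_sd_s = 0.01,
                       seed = 1L) {
  cfg <- list(sample_rate_hz = sample_rate_hz,
              access_phase_lognormal = access_phase_lognormal,
              closure_phase_lognormal = closure_phase_lognormal,
              dissection_workload_mean_s = dissection_workload_mean_s,
              dissection_workload_sd_s = dissection_workload_sd_s,
              baseline_noise_sd = baseline_noise_sd,
              activation_amplitude = activation_amplitude,
              activation_noise_sd = activation_noise_sd,
              profiles = profiles,
              timing_jitter_sd_s = timing_jitter_sd_s,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_profiles <- function() {
  list(surgeon_profile("attending_fast", speed = 1.2, weight = 0.35),
       surgeon_profile("attending", speed = 1.0, weight = 0.35),
       surgeon_profile("trainee", speed = 0.7, weight = 0.30))
}

validate_sim_config <- function(cfg) {
  pos_scalar <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config error: sim_config field '", f,
           "' must be a single positive finite number", call. = FALSE)
  }
  for (f in c("sample_rate_hz", "dissection_workload_mean_s",
              "baseline_noise_sd", "activation_amplitude",
              "activation_noise_sd"))
    pos_scalar(f)
  for (f in c("dissection_workload_sd_s", "timing_jitter_sd_s")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("config error: sim_config field '", f,
           "' must be a single non-negative finite number", call. = FALSE)
  }
  for (f in c("access_phase_lognormal", "closure_phase_lognormal")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || v[2] < 0)
      stop("config error: sim_config field '", f,
           "' must be c(mu, sigma) with sigma >= 0", call. = FALSE)
  }
  if (!length(cfg$profiles))
    stop("config error: sim_config field 'profiles' must be non-empty",
         call. = FALSE)
  lapply(cfg$profiles, validate_profile)
  if (cfg$activation_amplitude <= cfg$baseline_noise_sd * 6)
    stop("config error: sim_config field 'activation_amplitude' must exceed ",
         "6 * baseline_noise_sd for bursts to be detectable", call. = FALSE)
  invisible(cfg)
}

#' Activation detector configuration
#'
#' @param threshold current level at or above which a sample counts as part
#'   of an activation. Default is half the default simulator amplitude.
#' @param min_event_duration_s events shorter than this after merging are
#'   dropped (seconds).
#' @param merge_gap_s events separated by less than this are merged
#'   (seconds); separates blend-mode stutter from distinct activations.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(threshold = 0.5,
                            min_event_duration_s = 0.2,
                            merge_gap_s = 0.3) {
  cfg <- list(threshold = threshold,
              min_event_duration_s = min_event_duration_s,
              merge_gap_s = merge_gap_s)
  class(cfg) <- "detector_config"
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("config error: detector_config field 'threshold' must be > 0",
         call. = FALSE)
  for (f in c("min_event_duration_s", "merge_gap_s")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop("config error: detector_config field '", f, "' must be >= 0",
           call. = FALSE)
  }
  cfg
}

#' Advice protocol configuration
#'
#' Constants of the sequential advice loop: preparation of the next patient
#' should ideally start `lead_time_s` (default 25 min) before the last
#' suture; advice within `margin_s` (10 min) of that moment counts as
#' acceptable; the first prediction is made `first_decision_s` (15 min)
#' after incision, repeated every `decision_interval_s` (5 min) until either
#' a "prepare now" prediction or the `cap_s` (45 min) cap.
#'
#' @param lead_time_s preparation lead time, seconds.
#' @param margin_s acceptable-timing margin, seconds.
#' @param first_decision_s first decision time after incision, seconds.
#' @param decision_interval_s re-prediction interval, seconds.
#' @param cap_s hard stop of the decision loop, seconds after incision.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(lead_time_s = 1500,
                            margin_s = 600,
                            first_decision_s = 900,
                            decision_interval_s = 300,
                            cap_s = 2700) {
  cfg <- list(lead_time_s = lead_time_s, margin_s = margin_s,
              first_decision_s = first_decision_s,
              decision_interval_s = decision_interval_s, cap_s = cap_s)
  class(cfg) <- "protocol_config"
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("config error: protocol_config field '", f,
           "' must be a single non-negative finite number", call. = FALSE)
  }
  if (cfg$decision_interval_s <= 0)
    stop("config error: protocol_config field 'decision_interval_s' must be > 0",
         call. = FALSE)
  if (cfg$first_decision_s > cfg$cap_s)
    stop("config error: protocol_config field 'first_decision_s' must not ",
         "exceed 'cap_s'", call. = FALSE)
  k <- (cfg$cap_s - cfg$first_decision_s) / cfg$decision_interval_s
  if (abs(k - round(k)) > 1e-9)
    stop("config error: (cap_s - first_decision_s) must be an integer ",
         "multiple of decision_interval_s", call. = FALSE)
  cfg
}

#' Decision-time grid of a protocol
#'
#' @param protocol a [protocol_config()].
#' @return numeric vector of decision times in seconds
#'   (15, 20, ..., 45 min at the defaults).
#' @export
decision_grid <- function(protocol) {
  seq(protocol$first_decision_s, protocol$cap_s,
      by = protocol$decision_interval_s)
}
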