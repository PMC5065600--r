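# File formats and pipeline plumbing. Everything on disk is plain text:
# trace CSV (header `t_s,current`, 6-decimal floats, seconds since first
# incision), per-procedure metadata JSON, ground-truth events JSON lines,
# a cohort manifest JSON, a YAML run configuration, and the model JSON.
# Time unit is seconds everywhere except report summary fields suffixed
# `_min`.

#' Write / read a current trace CSV
#'
#' @param trace data.frame `t_s`, `current`.
#' @param path CSV path; header `t_s,current`, 6-decimal floats.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns the validated trace (negative/non-finite currents clamped to
#'   0 with a warning).
#' @export
write_trace_csv <- function(trace, path) {
  lines <- c("t_s,current",
             sprintf("%.6f,%.6f", trace$t_s, trace$current))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("t_s", "current") %in% names(df)))
    stop("format error: trace CSV must have columns t_s, current",
         call. = FALSE)
  validate_trace(df)
}

#' Write / read activation events as JSON lines
#'
#' @param events data.frame `start_s`, `end_s`.
#' @param path JSONL path, one `{"start_s":..,"end_s":..}` object per line.
#' @return `write_events_jsonl` returns `path` invisibly;
#'   `read_events_jsonl` the events data.frame.
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(start_s = events$start_s[i],
                          end_s = events$end_s[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  do.call(rbind, lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(start_s = x$start_s, end_s = x$end_s)
  }))
}

#' Write a simulated cohort to a directory
#'
#' Layout: one `<id>.csv` trace, one `<id>.json` metadata file
#' (`procedure_id`, `total_duration_s`, `phase_durations_s`, `profile`,
#' `seed`) and one `<id>.events.jsonl` ground-truth file per procedure,
#' plus `manifest.json` recording the ids, cohort seed and a hash of the
#' generating configuration.
#'
#' @param cohort list of `procedure_record`s with traces.
#' @param dir output directory (created if missing).
#' @param config the [sim_config()] that generated the cohort.
#' @param seed the cohort seed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) {
    base <- file.path(dir, rec$procedure_id)
    write_trace_csv(rec$trace, paste0(base, ".csv"))
    write_events_jsonl(rec$true_events, paste0(base, ".events.jsonl"))
    meta <- list(procedure_id = rec$procedure_id,
                 total_duration_s = rec$total_duration_s,
                 phase_durations_s = as.list(rec$phase_durations_s),
                 profile = unclass(rec$profile),
                 seed = rec$seed)
    jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  manifest <- list(
    n = length(cohort),
    procedure_ids = vapply(cohort, `[[`, character(1), "procedure_id"),
    cohort_seed = seed,
    config_hash = if (is.null(config)) NA else config_hash(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return list of `procedure_record`s.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop("I/O error: no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lapply(manifest$procedure_ids, function(id) {
    base <- file.path(dir, id)
    meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
    prof <- meta$profile
    rec <- list(procedure_id = meta$procedure_id,
                trace = read_trace_csv(paste0(base, ".csv")),
                total_duration_s = meta$total_duration_s,
                true_events = read_events_jsonl(paste0(base, ".events.jsonl")),
                phase_durations_s = unlist(meta$phase_durations_s),
                profile = surgeon_profile(prof$name, prof$speed,
                                          prof$burst_duration_mean_s,
                                          prof$burst_gap_mean_s, prof$weight),
                seed = meta$seed)
    class(rec) <- "procedure_record"
    rec
  })
}

# Stable short hash of a configuration (for manifests / logs).
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
             collapse = "\n")
  # FNV-1a over the printed representation; no external digest dependency.
  # The xor operand is a single byte, so only the low byte of the state
  # is xored (keeps the state in doubles, clear of bitwXor's 32-bit cap).
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Read / write the run configuration YAML
#'
#' One YAML document with `sim`, `detector`, `protocol` and `classifier`
#' blocks; omitted fields take the package defaults. Profiles are listed
#' under `sim$profiles` with their name, speed, burst parameters and
#' weight.
#'
#' @param path YAML file path.
#' @return a list with validated `sim` ([sim_config()]), `detector`
#'   ([detector_config()]), `protocol` ([protocol_config()]) and
#'   `classifier` (list with `cost`) components.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

#' @rdname read_run_config
#' @param config a run configuration as returned by `default_run_config()`.
#' @export
write_run_config <- function(config, path) {
  out <- list(sim = unclass_profiles(config$sim),
              detector = unclass(config$detector),
              protocol = unclass(config$protocol),
              classifier = config$classifier)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(sim = sim_config(), detector = detector_config(),
       protocol = protocol_config(), classifier = list(cost = 1.0))
}

build_run_config <- function(raw) {
  if (is.null(raw)) raw <- list()
  simr <- raw$sim
  if (!is.null(simr$profiles)) {
    simr$profiles <- lapply(simr$profiles, function(p) {
      do.call(surgeon_profile, p)
    })
  }
  cfg <- list(
    sim = do.call(sim_config, simr %||% list()),
    detector = do.call(detector_config, raw$detector %||% list()),
    protocol = do.call(protocol_config, raw$protocol %||% list()),
    classifier = utils::modifyList(list(cost = 1.0),
                                   raw$classifier %||% list()))
  cfg
}

unclass_profiles <- function(sim) {
  sim <- unclass(sim)
  sim$profiles <- lapply(sim$profiles, unclass)
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an advice result / evaluation report as JSON
#'
#' @param x an `advice_result` or `evaluation_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  out <- unclass(x)
  if (!is.null(out$per_procedure)) {
    out$band_counts <- as.list(out$band_counts)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
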