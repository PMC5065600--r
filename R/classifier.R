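# Per-decision-time binary classifiers: at grid time t, decide whether the
# procedure will run longer than t + lead time (equivalently, remaining
# duration > 25 min at the defaults). One independent linear-kernel SVM per
# decision time; features are z-scored with statistics stored at training
# time, and the fitted maximum-margin hyperplane is reduced to an explicit
# weight vector + bias so predictions are auditable dot products and the
# whole bank serializes losslessly to JSON.

FEATURE_SCHEMA_VERSION <- "1"

#' Train a bank of horizon classifiers
#'
#' For each decision time `t` on the protocol grid, the training rows are
#' the cohort members still ongoing at `t` (`total_duration_s > t`), the
#' label is `"longer"` when `total_duration_s > t + lead_time_s`, and the
#' features come from [detect_prefix()] + [extract_features()] at `t`.
#' Features are z-scored with the training means/SDs (zero-variance
#' features get SD 1, which makes their scaled column constant and their
#' fitted weight 0); a linear-kernel soft-margin SVM is fitted.
#'
#' By default classes are unweighted. The advice loop stops at the first
#' "prepare now" prediction, so false "shorter" calls compound across the
#' seven decision times; an unweighted fit respects the class prior (most
#' procedures still ongoing at an early decision time are "longer") and
#' biases residual errors toward late advice on short procedures -- the
#' same direction the live clinical system erred. `class_weights =
#' "inverse"` restores inverse-frequency weighting for users who prefer
#' balanced recall per horizon.
#'
#' @param cohort list of `procedure_record`s (>= 10).
#' @param protocol a [protocol_config()]; fixes the decision grid and the
#'   lead time.
#' @param detector a [detector_config()] used for prefix detection, stored
#'   in the bank so replay uses the same detector.
#' @param cost SVM regularization constant C.
#' @param class_weights `"none"` (default) or `"inverse"`
#'   (inverse-frequency).
#' @return an object of class `classifier_bank`.
#' @export
train_bank <- function(cohort, protocol = protocol_config(),
                       detector = detector_config(), cost = 1.0,
                       class_weights = c("none", "inverse")) {
  class_weights <- match.arg(class_weights)
  if (length(cohort) < 10)
    stop("training error: cohort must contain at least 10 procedures",
         call. = FALSE)
  grid <- decision_grid(protocol)
  durations <- vapply(cohort, `[[`, numeric(1), "total_duration_s")

  classifiers <- lapply(grid, function(t) {
    eligible <- which(durations > t)
    longer <- durations[eligible] > t + protocol$lead_time_s
    if (length(eligible) == 0 || all(longer) || !any(longer))
      stop("training error: only one class present at decision time ",
           t, " s (", t / 60, " min)", call. = FALSE)
    X <- t(vapply(cohort[eligible], function(rec) {
      ev <- detect_prefix(rec$trace, detector, t)
      extract_features(ev, t)
    }, numeric(length(feature_names()))))
    fit_horizon(X, longer, decision_time_s = t,
                duration_threshold_s = t + protocol$lead_time_s,
                cost = cost, class_weights = class_weights)
  })
  names(classifiers) <- paste0("t", grid)

  bank <- list(lead_time_s = protocol$lead_time_s,
               decision_times_s = grid,
               classifiers = classifiers,
               detector_config = unclass(detector),
               feature_schema_version = FEATURE_SCHEMA_VERSION)
  class(bank) <- "classifier_bank"
  bank
}

# Fit one horizon: z-score, linear SVM, extract hyperplane oriented so
# positive decision value = longer.
fit_horizon <- function(X, longer, decision_time_s, duration_threshold_s,
                        cost, class_weights = "none") {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  y <- factor(ifelse(longer, "longer", "shorter"),
              levels = c("longer", "shorter"))
  cw <- if (class_weights == "inverse") {
    tab <- length(y) / (2 * table(y))
    stats::setNames(as.numeric(tab), names(tab))
  } else NULL
  fit <- e1071::svm(Z, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm's decision value is positive for the first factor level of the
  # training labels; flip if it fitted the opposite orientation.
  dv <- attr(stats::predict(fit, Z, decision.values = TRUE),
             "decision.values")
  if (colnames(dv)[1] == "shorter/longer") {
    w <- -w
    b <- -b
  }

  list(decision_time_s = decision_time_s,
       duration_threshold_s = duration_threshold_s,
       feature_means = stats::setNames(as.numeric(mu), feature_names()),
       feature_sds = stats::setNames(as.numeric(sdv), feature_names()),
       weights = stats::setNames(w, feature_names()),
       bias = b,
       training_n = nrow(X),
       positive_label = "longer")
}

#' Predict whether the procedure will run longer than the horizon
#'
#' Dispatches on the bank type: a trained [train_bank()] bank evaluates the
#' stored linear decision function on the z-scored feature vector at
#' `t_now_s`; an [oracle_bank()] answers from ground truth. A decision
#' value of exactly 0 returns `FALSE` ("prepare now"): erring toward
#' advising is the conservative tie-break, since an OR team waiting for a
#' patient is worse than a patient waiting for the OR.
#'
#' @param bank a `classifier_bank` or `oracle_bank`.
#' @param events detected activation events up to `t_now_s`.
#' @param t_now_s decision time; must lie on the bank's decision grid.
#' @return logical: `TRUE` if remaining duration is predicted to exceed the
#'   lead time.
#' @export
predict_longer <- function(bank, events, t_now_s) {
  UseMethod("predict_longer")
}

#' @export
predict_longer.classifier_bank <- function(bank, events, t_now_s) {
  decision_value(bank, events, t_now_s) > 0
}

#' @export
predict_longer.oracle_bank <- function(bank, events, t_now_s) {
  decision_value(bank, events, t_now_s) > 0
}

# Signed decision value at a grid time (positive = longer); shared by
# prediction and the replay decision log.
decision_value <- function(bank, events, t_now_s) {
  UseMethod("decision_value")
}

#' @export
decision_value.classifier_bank <- function(bank, events, t_now_s) {
  clf <- bank_classifier_at(bank, t_now_s)
  fv <- extract_features(events, t_now_s)
  z <- (fv - clf$feature_means) / clf$feature_sds
  sum(clf$weights * z) + clf$bias
}

#' @export
decision_value.oracle_bank <- function(bank, events, t_now_s) {
  if (!any(abs(bank$decision_times_s - t_now_s) < 1e-9))
    stop("argument error: t_now_s = ", t_now_s,
         " is not on the bank's decision grid", call. = FALSE)
  (bank$total_duration_s - t_now_s) - bank$lead_time_s
}

bank_classifier_at <- function(bank, t_now_s) {
  i <- which(abs(bank$decision_times_s - t_now_s) < 1e-9)
  if (length(i) != 1)
    stop("argument error: t_now_s = ", t_now_s,
         " is not on the bank's decision grid", call. = FALSE)
  bank$classifiers[[i]]
}

#' Ground-truth oracle bank
#'
#' Implements the same interface as a trained bank but answers from the
#' true total duration: "longer" iff remaining duration strictly exceeds
#' the lead time. Used to characterise the protocol itself, independent of
#' classifier quality (an `oracle_bank(Inf, ...)` is an always-"longer"
#' stub, useful to exercise the 45-min cap).
#'
#' @param total_duration_s the procedure's true total duration in seconds.
#' @param protocol a [protocol_config()].
#' @return an object of class `oracle_bank`.
#' @export
oracle_bank <- function(total_duration_s, protocol = protocol_config()) {
  b <- list(lead_time_s = protocol$lead_time_s,
            decision_times_s = decision_grid(protocol),
            total_duration_s = total_duration_s)
  class(b) <- "oracle_bank"
  b
}

#' Save / load a classifier bank as JSON
#'
#' The model file is a single JSON document holding the grid, lead time,
#' per-horizon normalization statistics and hyperplanes, the detector
#' configuration, and the feature schema version (checked on load).
#'
#' @param bank a `classifier_bank`.
#' @param path file path of the model JSON.
#' @return `save_bank` returns `path` invisibly; `load_bank` returns the
#'   bank.
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "classifier_bank"))
  jsonlite::write_json(unclass(bank), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(raw$feature_schema_version),
                 FEATURE_SCHEMA_VERSION))
    stop("version error: model file has feature schema version '",
         raw$feature_schema_version, "', this package expects '",
         FEATURE_SCHEMA_VERSION, "'", call. = FALSE)
  raw$classifiers <- lapply(raw$classifiers, function(clf) {
    for (f in c("feature_means", "feature_sds", "weights")) {
      v <- as.numeric(unlist(clf[[f]]))
      if (length(v) != length(feature_names()))
        stop("version error: model file stores ", length(v),
             " features, this package expects ", length(feature_names()),
             call. = FALSE)
      clf[[f]] <- stats::setNames(v, feature_names())
    }
    clf
  })
  dc <- raw$detector_config
  raw$detector_config <- unclass(detector_config(
    threshold = dc$threshold,
    min_event_duration_s = dc$min_event_duration_s,
    merge_gap_s = dc$merge_gap_s))
  class(raw) <- "classifier_bank"
  raw
}

#' Detector configuration stored in a bank
#' @param bank a `classifier_bank`.
#' @return a [detector_config()].
#' @export
bank_detector <- function(bank) {
  dc <- bank$detector_config
  detector_config(threshold = dc$threshold,
                  min_event_duration_s = dc$min_event_duration_s,
                  merge_gap_s = dc$merge_gap_s)
}
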