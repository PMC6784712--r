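# Per-night AHI protocol: whole-night estimation for nights recorded
# concurrently with a gold standard (clinician-invalidated spans excised),
# windowed estimation with rolling-median outlier rejection for unattended
# load-cell-only nights, and max-rule aggregation across a subject's nights.

night_estimate <- function(rec, ahi, censored, severity, n_used, n_rejected) {
  structure(
    list(subject = rec$subject_id, night = rec$night, setting = rec$setting,
         ahi = ahi, censored = censored, severity = severity,
         n_windows_used = n_used, n_windows_rejected = n_rejected),
    class = "night_estimate"
  )
}

#' @export
print.night_estimate <- function(x, ...) {
  cat(sprintf("<night_estimate> subject %s night %d (%s): AHI %s, %s\n",
              x$subject, x$night, x$setting,
              if (x$censored) "<5" else sprintf("%.2f", x$ahi),
              as.character(x$severity)))
  if (x$n_windows_used + x$n_windows_rejected > 1L)
    cat(sprintf("  windows used %d, rejected %d\n", x$n_windows_used,
                x$n_windows_rejected))
  invisible(x)
}

#' Whole-night AHI estimate
#'
#' Estimates a single AHI for the night from the entire valid signal:
#' preprocess (invalid spans excised), extract the six spectral features,
#' and apply the two-stage classifier once. Used for nights recorded
#' concurrently with a gold-standard study.
#'
#' @param rec an [lc_recording()].
#' @param model trained pipeline ([osa_fit()] or [osa_model()] with a tree).
#' @param min_duration_s minimum valid signal duration (default 150 s, the
#'   spectral-resolution floor).
#' @inheritParams preprocess_recording
#' @return a `night_estimate`: censored `"<5"` when the study is graded
#'   normal, otherwise a numeric AHI and its severity.
#' @export
whole_night_ahi <- function(rec, model, low_hz = 0.05, high_hz = 5,
                            min_duration_s = 150) {
  stopifnot(inherits(rec, "lc_recording"))
  valid_s <- recording_duration_h(rec, valid_only = TRUE) * 3600
  if (valid_s < min_duration_s)
    stop_lcosa(sprintf(
      "only %.0f s of valid signal: insufficient data for an AHI estimate",
      valid_s), "lcosa_insufficient_data_error")
  x <- study_features(rec, low_hz, high_hz)
  p <- predict_study(x, model)
  night_estimate(rec, ahi = p$ahi, censored = p$censored,
                 severity = p$severity, n_used = 1L, n_rejected = 0L)
}

#' Windowed AHI series over a night
#'
#' Slides a window (default 3 h, in line with the 2-4 h minimum recording
#' recommended for sleep apnea testing) across the recording in steps of
#' `step_h` and applies the two-stage classifier to each segment. A trailing
#' partial window is dropped. Windows graded normal carry the censoring
#' imputation value `censor_value` (default 2.5 events/h, the midpoint of
#' the normal range) so that the series is numeric throughout.
#'
#' @param rec an [lc_recording()].
#' @param model trained pipeline.
#' @param window_h window length in hours (default 3).
#' @param step_h step between window starts in hours (default 1).
#' @param censor_value numeric stand-in for windows graded normal.
#' @inheritParams preprocess_recording
#' @return object of class `ahi_series`: data frame with `start_s`, `end_s`,
#'   `ahi` (imputed where censored), `category`, plus attributes `window_h`,
#'   `step_h`, `censor_value` and provenance.
#' @export
windowed_ahi <- function(rec, model, window_h = 3, step_h = 1,
                         censor_value = 2.5, low_hz = 0.05, high_hz = 5) {
  stopifnot(inherits(rec, "lc_recording"))
  if (!is_scalar_number(window_h) || window_h <= 0 ||
      !is_scalar_number(step_h) || step_h <= 0)
    stop_lcosa("window_h and step_h must be positive", "lcosa_parameter_error")
  fs <- rec$sample_rate_hz
  n <- length(rec$channels[[1L]])
  win_n <- round(window_h * 3600 * fs)
  step_n <- round(step_h * 3600 * fs)
  if (n < win_n)
    stop_lcosa(sprintf("recording of %.2f h is shorter than one %g h window",
                       n / fs / 3600, window_h),
               "lcosa_insufficient_data_error")
  starts <- seq(1L, n - win_n + 1L, by = step_n)
  rows <- lapply(starts, function(s0) {
    idx <- s0:(s0 + win_n - 1L)
    sub <- lc_recording(lapply(rec$channels, function(ch) ch[idx]),
                        sample_rate_hz = fs, subject_id = rec$subject_id,
                        night = rec$night, setting = rec$setting,
                        valid_mask = rec$valid_mask[idx])
    x <- study_features(sub, low_hz, high_hz)
    p <- predict_study(x, model)
    data.frame(start_s = (s0 - 1L) / fs,
               end_s = (s0 - 1L + win_n) / fs,
               ahi = if (p$censored) censor_value else p$ahi,
               category = p$category)
  })
  out <- do.call(rbind, rows)
  attr(out, "window_h") <- window_h
  attr(out, "step_h") <- step_h
  attr(out, "censor_value") <- censor_value
  attr(out, "provenance") <- list(subject = rec$subject_id,
                                  night = rec$night, setting = rec$setting)
  class(out) <- c("ahi_series", "data.frame")
  out
}

#' Rolling-median outlier rejection for a windowed AHI series
#'
#' Window estimates deviating from the rolling median of the time-ordered
#' series by more than `threshold` events/h usually flag noisy segments
#' (movement, sensor artifacts) and are removed. If every estimate would be
#' removed, the single value nearest the global median is kept so a night
#' always retains at least one estimate.
#'
#' @param series an `ahi_series` from [windowed_ahi()], or a plain numeric
#'   vector of estimates.
#' @param median_window span of the rolling median in estimates (odd;
#'   default 5).
#' @param threshold maximum absolute deviation from the rolling median
#'   (events/h, default 10).
#' @return the series with outlying rows dropped; attribute `n_rejected`
#'   records how many were removed.
#' @export
reject_outliers <- function(series, median_window = 5, threshold = 10) {
  vals <- if (is.data.frame(series)) series$ahi else as.numeric(series)
  n <- length(vals)
  if (n == 0L)
    stop_lcosa("empty AHI series", "lcosa_data_error")
  k <- min(median_window, n)
  if (k %% 2L == 0L) k <- k - 1L
  med <- if (k >= 3L) runmed(vals, k, endrule = "median") else vals
  keep <- abs(vals - med) <= threshold
  if (!any(keep)) keep[which.min(abs(vals - median(vals)))] <- TRUE
  out <- if (is.data.frame(series)) {
    res <- series[keep, , drop = FALSE]
    for (a in c("window_h", "step_h", "censor_value", "provenance"))
      attr(res, a) <- attr(series, a)
    class(res) <- class(series)
    res
  } else vals[keep]
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Night-level estimate from a filtered AHI series
#'
#' The night's AHI is the arithmetic mean of the surviving window estimates.
#' The night is graded by majority vote of the surviving windows' two-stage
#' categories: a normal-majority night is censored `"<5"`; otherwise the
#' mean (clamped from below at 5 events/h, consistent with the abnormal
#' grade) is reported with its severity.
#'
#' @param filtered an `ahi_series`, normally after [reject_outliers()].
#' @param rec optional [lc_recording()] supplying provenance; defaults to
#'   the provenance carried by the series.
#' @return a `night_estimate`.
#' @export
night_from_series <- function(filtered, rec = NULL) {
  stopifnot(inherits(filtered, "ahi_series"))
  if (nrow(filtered) == 0L)
    stop_lcosa("no surviving window estimates", "lcosa_data_error")
  n_rej <- attr(filtered, "n_rejected")
  if (is.null(n_rej)) n_rej <- 0L
  prov <- attr(filtered, "provenance")
  if (is.null(rec)) {
    rec <- list(subject_id = prov$subject, night = prov$night,
                setting = prov$setting)
  }
  normal_vote <- mean(filtered$category == "normal") > 0.5
  if (normal_vote) {
    night_estimate(rec, ahi = NA_real_, censored = TRUE,
                   severity = factor("normal", levels = severity_levels),
                   n_used = nrow(filtered), n_rejected = n_rej)
  } else {
    ahi <- max(5, mean(filtered$ahi))
    night_estimate(rec, ahi = ahi, censored = FALSE,
                   severity = severity_from_ahi(ahi),
                   n_used = nrow(filtered), n_rejected = n_rej)
  }
}

#' Windowed night protocol in one call
#'
#' [windowed_ahi()], [reject_outliers()] and [night_from_series()] chained:
#' the per-night procedure for unattended load-cell-only home nights.
#'
#' @inheritParams windowed_ahi
#' @inheritParams reject_outliers
#' @return a `night_estimate`.
#' @export
windowed_night_ahi <- function(rec, model, window_h = 3, step_h = 1,
                               median_window = 5, threshold = 10,
                               censor_value = 2.5) {
  series <- windowed_ahi(rec, model, window_h = window_h, step_h = step_h,
                         censor_value = censor_value)
  night_from_series(reject_outliers(series, median_window, threshold),
                    rec = rec)
}

#' Aggregate a subject's nights into a final diagnosis
#'
#' OSA has high night-to-night variability, and clinical practice errs
#' toward the more severe estimate, so the subject's final AHI is the
#' highest estimate across nights. The final AHI is censored `"<5"` only if
#' every night is censored; final severity follows [severity_from_ahi()].
#'
#' @param nights list of `night_estimate` objects (>= 1) for one subject.
#' @return object of class `subject_diagnosis`: `subject`, `nights`,
#'   `final_ahi` (`NA` when censored), `final_censored`, `final_severity`.
#' @export
aggregate_subject <- function(nights) {
  if (inherits(nights, "night_estimate")) nights <- list(nights)
  if (length(nights) == 0L)
    stop_lcosa("need at least one night estimate", "lcosa_data_error")
  stopifnot(all(vapply(nights, inherits, logical(1), "night_estimate")))
  subject <- unique(vapply(nights, `[[`, character(1), "subject"))
  if (length(subject) != 1L)
    stop_lcosa("nights belong to different subjects", "lcosa_data_error")
  vals <- vapply(nights, `[[`, numeric(1), "ahi")
  cens <- vapply(nights, `[[`, logical(1), "censored")
  if (all(cens)) {
    final_ahi <- NA_real_
    final_censored <- TRUE
    final_severity <- factor("normal", levels = severity_levels)
  } else {
    final_ahi <- max(vals[!cens])
    final_censored <- FALSE
    final_severity <- severity_from_ahi(final_ahi)
  }
  structure(
    list(subject = subject, nights = nights, final_ahi = final_ahi,
         final_censored = final_censored, final_severity = final_severity),
    class = "subject_diagnosis"
  )
}

#' @export
print.subject_diagnosis <- function(x, ...) {
  cat(sprintf("<subject_diagnosis> subject %s over %d night(s): AHI %s, %s\n",
              x$subject, length(x$nights),
              if (x$final_censored) "<5" else sprintf("%.2f", x$final_ahi),
              as.character(x$final_severity)))
  invisible(x)
}

#' Serialize night estimates to a per-night results table
#'
#' @param nights list of `night_estimate` objects.
#' @return data frame with one row per night: subject, night, setting,
#'   ahi (string, `"<5"` where censored), severity, windows used/rejected.
#' @export
night_results_table <- function(nights) {
  if (inherits(nights, "night_estimate")) nights <- list(nights)
  do.call(rbind, lapply(nights, function(ne) data.frame(
    subject = ne$subject, night = ne$night, setting = ne$setting,
    ahi = if (ne$censored) "<5" else sprintf("%.2f", ne$ahi),
    severity = as.character(ne$severity),
    windows_used = ne$n_windows_used,
    windows_rejected = ne$n_windows_rejected,
    stringsAsFactors = FALSE
  )))
}
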