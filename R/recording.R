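#' Construct a load-cell recording
#'
#' A load-cell (LC) recording holds the four synchronized pressure channels
#' captured by the sensor subassemblies under the mattress (two under the
#' shoulders, two under the hips), together with the sampling rate and study
#' metadata. Channel units are arbitrary sensor units: the preprocessing
#' pipeline standardizes the composite signal, so absolute gain never matters.
#'
#' @param channels list of exactly 4 equal-length numeric vectors.
#' @param sample_rate_hz sampling rate in Hz (default 250, the acquisition
#'   rate of the device).
#' @param subject_id subject identifier (coerced to character).
#' @param night night index (positive integer).
#' @param setting one of `"clinic_psg"` (in-clinic polysomnography night),
#'   `"home_hsat"` (home night with concurrent home-sleep-apnea-test sensors)
#'   or `"home_lc_only"` (home night with load cells only).
#' @param start_time optional `POSIXct` start time; when absent, time is
#'   sample index over `sample_rate_hz`.
#' @param valid_mask optional logical vector (one flag per sample), `FALSE`
#'   marking clinician-invalidated spans to be excised before analysis.
#'
#' @return An object of class `lc_recording`.
#' @seealso [read_lc_csv()], [preprocess_recording()], [simulate_recording()]
#' @export
#' @examples
#' rec <- lc_recording(replicate(4, sin(seq_len(500) / 10), simplify = FALSE),
#'                     sample_rate_hz = 250, subject_id = "s1")
#' rec
lc_recording <- function(channels, sample_rate_hz = 250, subject_id = "unknown",
                         night = 1L, setting = c("clinic_psg", "home_hsat",
                                                 "home_lc_only"),
                         start_time = NULL, valid_mask = NULL) {
  setting <- match.arg(setting)
  if (!is.list(channels) || length(channels) != 4L)
    stop_lcosa("an LC recording requires exactly 4 channels",
               "lcosa_format_error")
  n <- unique(lengths(channels))
  if (length(n) != 1L)
    stop_lcosa("all 4 channels must have the same length", "lcosa_data_error")
  if (n < 1L)
    stop_lcosa("channels must contain at least one sample", "lcosa_data_error")
  if (!all(vapply(channels, is.numeric, logical(1))))
    stop_lcosa("channels must be numeric", "lcosa_format_error")
  if (!is_scalar_number(sample_rate_hz) || sample_rate_hz <= 0)
    stop_lcosa("sample_rate_hz must be a positive number",
               "lcosa_parameter_error")
  if (!is.null(valid_mask)) {
    if (!is.logical(valid_mask) || length(valid_mask) != n)
      stop_lcosa("valid_mask must be a logical vector of channel length",
                 "lcosa_format_error")
  }
  night <- as.integer(night)
  if (is.na(night) || night < 1L)
    stop_lcosa("night must be a positive integer", "lcosa_parameter_error")
  structure(
    list(subject_id = as.character(subject_id), night = night,
         setting = setting, sample_rate_hz = as.numeric(sample_rate_hz),
         channels = lapply(channels, as.numeric), start_time = start_time,
         valid_mask = valid_mask),
    class = "lc_recording"
  )
}

#' @export
print.lc_recording <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cat(sprintf("<lc_recording> subject %s, night %d, %s\n",
              x$subject_id, x$night, x$setting))
  cat(sprintf("  4 channels x %d samples @ %g Hz (%.2f h)\n",
              n, x$sample_rate_hz, n / x$sample_rate_hz / 3600))
  if (!is.null(x$valid_mask))
    cat(sprintf("  valid samples: %d of %d\n", sum(x$valid_mask), n))
  invisible(x)
}

#' Duration of a recording in hours
#'
#' @param rec an [lc_recording()].
#' @param valid_only if `TRUE` count only samples flagged valid.
#' @return duration in hours.
#' @export
recording_duration_h <- function(rec, valid_only = FALSE) {
  stopifnot(inherits(rec, "lc_recording"))
  n <- if (valid_only && !is.null(rec$valid_mask)) sum(rec$valid_mask)
       else length(rec$channels[[1L]])
  n / rec$sample_rate_hz / 3600
}

#' Read a load-cell recording from CSV
#'
#' Expects a header row naming one timestamp column (seconds) followed by the
#' four sensor columns, i.e. `t_s, lc1, lc2, lc3, lc4`. The sampling rate is
#' taken from an optional `# sample_rate_hz: <value>` comment line, and
#' otherwise inferred from the median timestamp increment.
#'
#' @param path path to the CSV file.
#' @param subject_id,night,setting study metadata attached to the recording.
#' @return An [lc_recording()].
#' @export
read_lc_csv <- function(path, subject_id = "unknown", night = 1L,
                        setting = "clinic_psg") {
  if (!file.exists(path))
    stop_lcosa(sprintf("file not found: %s", path), "lcosa_io_error")
  header_rate <- NA_real_
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("sample_rate_hz:\\s*([0-9.eE+-]+)", first))[[1L]]
    if (length(m) == 2L) header_rate <- as.numeric(m[2L])
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) < 5L)
    stop_lcosa(sprintf(
      "expected a timestamp column plus 4 sensor columns, found %d columns",
      ncol(df)), "lcosa_format_error")
  if (ncol(df) > 5L)
    stop_lcosa("more than 4 sensor columns present", "lcosa_format_error")
  t_s <- as.numeric(df[[1L]])
  if (anyNA(t_s))
    stop_lcosa("non-numeric timestamps", "lcosa_format_error")
  if (nrow(df) >= 2L && any(diff(t_s) <= 0))
    stop_lcosa("timestamps must be strictly increasing", "lcosa_data_error")
  rate <- if (is.finite(header_rate)) header_rate
          else if (nrow(df) >= 2L) 1 / median(diff(t_s))
          else stop_lcosa("cannot infer sample rate from a single row",
                          "lcosa_data_error")
  lc_recording(as.list(df[-1L]), sample_rate_hz = rate,
               subject_id = subject_id, night = night, setting = setting)
}

#' Write a load-cell recording to CSV
#'
#' Writes `t_s, lc1..lc4` with full double precision plus a
#' `# sample_rate_hz:` comment line, so that [read_lc_csv()] reproduces the
#' numeric content exactly.
#'
#' @param rec an [lc_recording()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_lc_csv <- function(rec, path) {
  stopifnot(inherits(rec, "lc_recording"))
  n <- length(rec$channels[[1L]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %.17g", rec$sample_rate_hz), con)
  writeLines("t_s,lc1,lc2,lc3,lc4", con)
  t_s <- (seq_len(n) - 1L) / rec$sample_rate_hz
  lines <- sprintf("%.17g,%.17g,%.17g,%.17g,%.17g", t_s,
                   rec$channels[[1L]], rec$channels[[2L]],
                   rec$channels[[3L]], rec$channels[[4L]])
  writeLines(lines, con)
  invisible(path)
}
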