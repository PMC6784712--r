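#' Sum the four load-cell channels into one raw composite sequence
#'
#' The four subassemblies sample the same body at different support points;
#' adding time-aligned samples concentrates the respiratory and cardiac
#' pressure variation into a single sequence.
#'
#' @param rec an [lc_recording()].
#' @return numeric vector, the elementwise sum of the 4 channels.
#' @export
combine_channels <- function(rec) {
  stopifnot(inherits(rec, "lc_recording"))
  if (length(unique(lengths(rec$channels))) != 1L)
    stop_lcosa("channel length mismatch", "lcosa_data_error")
  rec$channels[[1L]] + rec$channels[[2L]] + rec$channels[[3L]] +
    rec$channels[[4L]]
}

#' Zero-phase band-pass filter
#'
#' Removes slow baseline drift below `low_hz` and non-physiologic content
#' above `high_hz` (breathing, its harmonics and the ballistocardiogram all
#' live below 5 Hz). The signal is demeaned, then passed forward-backward
#' (zero phase, so moment features are not corrupted by phase distortion)
#' through a 2nd-order Butterworth high-pass at `low_hz` followed by a
#' 4th-order Butterworth low-pass at `high_hz`. The cascaded realization is
#' used because a direct band-pass transfer function with a drift-removal
#' edge near 4e-4 of Nyquist is numerically unstable in double precision.
#'
#' @param x numeric signal.
#' @param sample_rate_hz sampling rate in Hz.
#' @param low_hz,high_hz passband edges, `0 < low_hz < high_hz < Nyquist`.
#' @return filtered numeric vector of the same length; DC is removed.
#' @export
bandpass <- function(x, sample_rate_hz, low_hz = 0.05, high_hz = 5) {
  if (!is_scalar_number(sample_rate_hz) || sample_rate_hz <= 0)
    stop_lcosa("sample_rate_hz must be positive", "lcosa_parameter_error")
  nyq <- sample_rate_hz / 2
  if (!is_scalar_number(low_hz) || !is_scalar_number(high_hz) ||
      low_hz <= 0 || low_hz >= high_hz || high_hz >= nyq)
    stop_lcosa("need 0 < low_hz < high_hz < Nyquist", "lcosa_parameter_error")
  x <- as.numeric(x)
  # need a few cycles of the slowest passband component for the filter to
  # settle; below that the output is dominated by edge transients
  if (length(x) < 3 * sample_rate_hz / low_hz)
    stop_lcosa(sprintf(
      "signal too short for a %g Hz high-pass edge (need >= %d samples)",
      low_hz, ceiling(3 * sample_rate_hz / low_hz)), "lcosa_data_error")
  x <- x - mean(x)
  hp <- signal::butter(2, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  if (any(!is.finite(y)))
    stop_lcosa("filter output is not finite", "lcosa_numeric_error")
  y
}

#' Scale a signal to zero mean and unit standard deviation
#'
#' Uses the population (divide-by-n) standard deviation so that downstream
#' spectral magnitudes are exactly reproducible for a given input. A constant
#' signal indicates a flat or disconnected sensor and is an error.
#'
#' @param x numeric signal with non-zero variance.
#' @return standardized numeric vector (mean 0, population SD 1).
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop_lcosa("cannot standardize fewer than 2 samples", "lcosa_data_error")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0)
    stop_lcosa("constant (zero-variance) signal: flat or disconnected sensor",
               "lcosa_degenerate_error")
  (x - m) / s
}

#' Preprocess a recording into a composite signal
#'
#' Runs the full conditioning chain in order: sum the four channels, excise
#' clinician-invalidated spans (samples flagged `FALSE` in the valid mask are
#' dropped and the remainder concatenated, not zero-filled), band-pass
#' filter, and standardize.
#'
#' @param rec an [lc_recording()].
#' @param low_hz,high_hz passband edges passed to [bandpass()]. The default
#'   lower edge of 0.05 Hz preserves the slowest feature sub-band
#'   (0.06-0.08 Hz) while removing drift; the 5 Hz upper edge removes
#'   non-physiologic harmonics.
#' @param valid_mask optional logical mask overriding `rec$valid_mask`.
#' @return An object of class `composite_signal`: list with `samples`
#'   (standardized, dimensionless), `sample_rate_hz` and study provenance.
#' @export
preprocess_recording <- function(rec, low_hz = 0.05, high_hz = 5,
                                 valid_mask = NULL) {
  stopifnot(inherits(rec, "lc_recording"))
  raw <- combine_channels(rec)
  mask <- if (!is.null(valid_mask)) valid_mask else rec$valid_mask
  if (!is.null(mask)) {
    if (!is.logical(mask) || length(mask) != length(raw))
      stop_lcosa("valid_mask must be logical, one flag per sample",
                 "lcosa_format_error")
    raw <- raw[mask]
  }
  filtered <- bandpass(raw, rec$sample_rate_hz, low_hz, high_hz)
  structure(
    list(samples = standardize(filtered),
         sample_rate_hz = rec$sample_rate_hz,
         subject_id = rec$subject_id, night = rec$night,
         setting = rec$setting,
         band = c(low_hz = low_hz, high_hz = high_hz)),
    class = "composite_signal"
  )
}

#' @export
print.composite_signal <- function(x, ...) {
  cat(sprintf(
    "<composite_signal> subject %s, night %d, %s: %d samples @ %g Hz, band %g-%g Hz\n",
    x$subject_id, x$night, x$setting, length(x$samples), x$sample_rate_hz,
    x$band[["low_hz"]], x$band[["high_hz"]]))
  invisible(x)
}
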