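#' One-sided FFT magnitude spectrum
#'
#' Computes a single full-length FFT of the composite signal (no segment
#' averaging: the 0.02 Hz sub-band analysis needs the finest available
#' frequency resolution) and returns the one-sided magnitude spectrum from 0
#' to Nyquist. With the default rectangular window Parseval's identity holds
#' exactly; a Hann taper is available for leakage-sensitive exploration.
#'
#' @param sig a `composite_signal` from [preprocess_recording()], or a plain
#'   numeric vector (then `sample_rate_hz` must be given).
#' @param sample_rate_hz sampling rate, only for plain-vector input.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @param min_duration_s minimum signal duration; the default 150 s caps the
#'   resolution at 1/150 Hz so every 0.02 Hz sub-band spans at least 3 bins.
#' @return An object of class `magnitude_spectrum`: `frequencies_hz`,
#'   `magnitudes`, `resolution_hz`, `n`, `sample_rate_hz`.
#' @export
magnitude_spectrum <- function(sig, sample_rate_hz = NULL,
                               window = c("rectangular", "hann"),
                               min_duration_s = 150) {
  window <- match.arg(window)
  if (inherits(sig, "composite_signal")) {
    x <- sig$samples
    fs <- sig$sample_rate_hz
  } else {
    x <- as.numeric(sig)
    fs <- sample_rate_hz
    if (is.null(fs))
      stop_lcosa("sample_rate_hz required for plain-vector input",
                 "lcosa_parameter_error")
  }
  n <- length(x)
  if (n / fs < min_duration_s)
    stop_lcosa(sprintf(
      "signal of %.1f s is too short: need >= %g s for 0.02 Hz sub-band resolution",
      n / fs, min_duration_s), "lcosa_resolution_error")
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    x <- x * w
  }
  X <- fft(x)
  half <- seq_len(floor(n / 2) + 1L)
  structure(
    list(frequencies_hz = (half - 1L) * fs / n,
         magnitudes = Mod(X[half]),
         resolution_hz = fs / n,
         n = n, sample_rate_hz = fs, window = window),
    class = "magnitude_spectrum"
  )
}

#' @export
print.magnitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "<magnitude_spectrum> %d bins, 0-%.3g Hz, resolution %.3g Hz (%s window)\n",
    length(x$magnitudes), max(x$frequencies_hz), x$resolution_hz, x$window))
  invisible(x)
}

# moment conventions for sub-band features: adjusted Fisher-Pearson skewness
# (e1071 type 2) and excess kurtosis g2 (e1071 type 1, normal -> 0). g2 is
# used for kurtosis because it is defined from 2 bins up, whereas the
# adjusted form breaks down at the 3-bin minimum band occupancy.
band_skewness <- function(v) {
  if (length(v) < 3L || sd(v) == 0) return(NA_real_)
  e1071::skewness(v, type = 2)
}
band_kurtosis <- function(v) {
  if (length(v) < 2L || sd(v) == 0) return(NA_real_)
  e1071::kurtosis(v, type = 1)
}

#' Statistical moments of FFT magnitudes in 0.02 Hz sub-bands
#'
#' Tiles `[0, f_max)` with consecutive non-overlapping half-open sub-bands
#' `[k*width, (k+1)*width)` anchored at 0 Hz and computes, per band, the
#' mean, variance, skewness and kurtosis of the Fourier-coefficient
#' magnitudes falling inside it. These moments characterize the shape of the
#' magnitude distribution: sharp spectral lines and event-driven sideband
#' spread show up as heavy tails (high kurtosis, positive skew).
#'
#' Zero-variance (degenerate) bands get skewness and kurtosis 0 with a
#' warning; bands with fewer than 3 bins get `NA` moments with a warning.
#'
#' @param spec a [magnitude_spectrum()].
#' @param width_hz sub-band width (default 0.02 Hz).
#' @param f_max_hz upper edge of the tiled range (default 5 Hz, the filter
#'   passband).
#' @return A data frame of class `subband_moments`: `band` (index k),
#'   `f_lo`, `f_hi`, `n_bins`, `mean`, `variance`, `skewness`, `kurtosis`.
#' @export
subband_moments <- function(spec, width_hz = 0.02, f_max_hz = 5) {
  stopifnot(inherits(spec, "magnitude_spectrum"))
  if (spec$resolution_hz > width_hz / 3)
    stop_lcosa(sprintf(
      "spectral resolution %.3g Hz undersamples %.3g Hz sub-bands (need <= width/3)",
      spec$resolution_hz, width_hz), "lcosa_resolution_error")
  k_max <- ceiling(f_max_hz / width_hz) - 1L
  band <- 0:k_max
  f_lo <- band * width_hz
  f_hi <- (band + 1L) * width_hz
  idx <- findInterval(spec$frequencies_hz, c(f_lo, f_hi[length(f_hi)]),
                      rightmost.closed = FALSE)
  keep <- idx >= 1L & idx <= length(band) &
    spec$frequencies_hz < f_hi[length(f_hi)]
  groups <- split(spec$magnitudes[keep], idx[keep])
  out <- data.frame(band = band, f_lo = f_lo, f_hi = f_hi, n_bins = 0L,
                    mean = NA_real_, variance = NA_real_,
                    skewness = NA_real_, kurtosis = NA_real_)
  degenerate <- FALSE
  undersampled <- FALSE
  for (g in names(groups)) {
    i <- as.integer(g)
    v <- groups[[g]]
    out$n_bins[i] <- length(v)
    if (length(v) < 3L) { undersampled <- TRUE; next }
    out$mean[i] <- mean(v)
    out$variance[i] <- stats::var(v)
    if (sd(v) == 0) {
      degenerate <- TRUE
      out$skewness[i] <- 0
      out$kurtosis[i] <- 0
    } else {
      out$skewness[i] <- band_skewness(v)
      out$kurtosis[i] <- band_kurtosis(v)
    }
  }
  if (any(out$n_bins < 3L)) undersampled <- TRUE
  if (undersampled)
    warning("some sub-bands contain < 3 frequency bins; their moments are NA")
  if (degenerate)
    warning("zero-variance sub-band(s): skewness/kurtosis reported as 0")
  class(out) <- c("subband_moments", "data.frame")
  out
}

# the six selected sub-bands and the statistic taken in each, with the
# classification stage each feature feeds
feature_bands <- function() {
  data.frame(
    feature = paste0("X", 1:6),
    f_lo = c(0.06, 0.36, 0.96, 1.18, 1.40, 1.68),
    f_hi = c(0.08, 0.38, 0.98, 1.20, 1.42, 1.70),
    statistic = c("kurtosis", "skewness", "skewness", "kurtosis",
                  "kurtosis", "skewness"),
    stage = c("S1DT", "S2LR", "S2LR", "S1DT", "S2LR", "S1DT"),
    stringsAsFactors = FALSE
  )
}

#' Extract the six selected spectral features
#'
#' Projects the per-band moment table onto the six features used by the
#' two-stage classifier: X1 = kurtosis(0.06-0.08 Hz),
#' X2 = skewness(0.36-0.38 Hz), X3 = skewness(0.96-0.98 Hz),
#' X4 = kurtosis(1.18-1.20 Hz), X5 = kurtosis(1.40-1.42 Hz),
#' X6 = skewness(1.68-1.70 Hz). X1, X4 and X6 feed the stage-one decision
#' tree; X2, X3 and X5 feed the stage-two AHI regression.
#'
#' @param moments a [subband_moments()] table.
#' @return named numeric vector `X1..X6`.
#' @export
extract_features <- function(moments) {
  stopifnot(inherits(moments, "subband_moments"))
  fb <- feature_bands()
  out <- numeric(6L)
  for (i in seq_len(6L)) {
    row <- which(abs(moments$f_lo - fb$f_lo[i]) < 1e-9)
    if (length(row) != 1L)
      stop_lcosa(sprintf("sub-band %.2f-%.2f Hz missing from moment table",
                         fb$f_lo[i], fb$f_hi[i]), "lcosa_feature_error")
    v <- moments[[fb$statistic[i]]][row]
    if (!is.finite(v))
      stop_lcosa(sprintf("feature %s (%s of %.2f-%.2f Hz) is not finite",
                         fb$feature[i], fb$statistic[i], fb$f_lo[i],
                         fb$f_hi[i]), "lcosa_feature_error")
    out[i] <- v
  }
  names(out) <- fb$feature
  out
}

#' Full feature pipeline for one recording
#'
#' Convenience wrapper: [preprocess_recording()] then [magnitude_spectrum()],
#' [subband_moments()] and [extract_features()]. The feature path tapers
#' with a Hann window by default: narrow-band moments of strong spectral
#' lines are otherwise sensitive to how the line aligns with the FFT bin
#' grid (scalloping), which varies between recordings and adds nuisance
#' variance to the features.
#'
#' @param rec an [lc_recording()].
#' @inheritParams preprocess_recording
#' @inheritParams magnitude_spectrum
#' @return named numeric vector `X1..X6`.
#' @export
study_features <- function(rec, low_hz = 0.05, high_hz = 5,
                           window = "hann", valid_mask = NULL) {
  sig <- preprocess_recording(rec, low_hz, high_hz, valid_mask = valid_mask)
  extract_features(subband_moments(magnitude_spectrum(sig, window = window)))
}

#' Rank candidate sub-band moments by one-way ANOVA F statistic
#'
#' Given per-study candidate features and a severity class label per study,
#' computes the one-way ANOVA F statistic of each feature across the classes
#' (normal, mild, moderate-severe) and returns the features ranked by F.
#' This is the selection procedure that originally picked the six features of
#' [extract_features()] from the full band-by-statistic candidate grid.
#'
#' @param features_table data frame or matrix, one row per study, one column
#'   per candidate feature.
#' @param labels class label per study (factor or coercible; >= 2 classes,
#'   each with >= 2 studies).
#' @param k number of top-ranked features to return (default all).
#' @return data frame `feature`, `f_statistic`, `rank`, ordered by
#'   decreasing F, truncated to the top `k`.
#' @export
anova_select <- function(features_table, labels, k = ncol(features_table)) {
  ft <- as.data.frame(features_table)
  g <- factor(labels)
  if (nrow(ft) != length(g))
    stop_lcosa("labels must have one entry per study row", "lcosa_data_error")
  tab <- table(g)
  if (length(tab) < 2L || any(tab < 2L))
    stop_lcosa("need >= 2 classes with >= 2 studies each",
               "lcosa_selection_error")
  fstat <- vapply(ft, function(col) {
    col <- as.numeric(col)
    if (anyNA(col) || sd(col) == 0) return(NA_real_)
    anova(lm(col ~ g))[["F value"]][1L]
  }, numeric(1))
  ord <- order(fstat, decreasing = TRUE, na.last = TRUE)
  out <- data.frame(feature = names(fstat)[ord],
                    f_statistic = unname(fstat[ord]),
                    rank = seq_along(fstat), stringsAsFactors = FALSE)
  head(out, k)
}

#' Build the full candidate feature table from per-study moment tables
#'
#' One row per study, columns `skewness_<f_lo>` and `kurtosis_<f_lo>` for
#' every complete sub-band, ready for [anova_select()].
#'
#' @param moments_list list of [subband_moments()] tables, one per study.
#' @return data frame of candidate features.
#' @export
candidate_feature_table <- function(moments_list) {
  stopifnot(length(moments_list) >= 1L)
  one <- function(m) {
    ok <- is.finite(m$skewness) & is.finite(m$kurtosis)
    vals <- c(m$skewness[ok], m$kurtosis[ok])
    names(vals) <- c(sprintf("skewness_%.2f", m$f_lo[ok]),
                     sprintf("kurtosis_%.2f", m$f_lo[ok]))
    vals
  }
  rows <- lapply(moments_list, one)
  common <- Reduce(intersect, lapply(rows, names))
  as.data.frame(do.call(rbind, lapply(rows, function(r) r[common])))
}
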