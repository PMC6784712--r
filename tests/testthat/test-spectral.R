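# independent O(n^2) DFT oracle for small n
direct_dft_mag <- function(x) {
  n <- length(x)
  k <- 0:(floor(n / 2))
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))
  }, numeric(1))
}

# construct a magnitude_spectrum object directly (for moment-path tests)
fake_spectrum <- function(magnitudes, resolution_hz) {
  n <- (length(magnitudes) - 1L) * 2L
  structure(
    list(frequencies_hz = (seq_along(magnitudes) - 1L) * resolution_hz,
         magnitudes = magnitudes, resolution_hz = resolution_hz,
         n = n, sample_rate_hz = resolution_hz * n, window = "rectangular"),
    class = "magnitude_spectrum"
  )
}

test_that("magnitude spectrum matches a direct DFT and Parseval holds", {
  set.seed(11)
  x <- rnorm(1024)
  sp <- magnitude_spectrum(x, sample_rate_hz = 4)   # 256 s
  expect_equal(sp$magnitudes, direct_dft_mag(x), tolerance = 1e-9)

  # Parseval over the one-sided spectrum (interior bins count twice)
  w <- c(1, rep(2, length(sp$magnitudes) - 2L), 1)
  lhs <- sum(w * sp$magnitudes^2) / 1024
  expect_lt(abs(lhs - sum(x^2)) / sum(x^2), 1e-6)
})

test_that("pure tones concentrate in their bins", {
  fs <- 10
  t <- seq(0, 200 - 1 / fs, by = 1 / fs)
  sp <- magnitude_spectrum(sin(2 * pi * 1 * t), sample_rate_hz = fs)
  expect_equal(sp$frequencies_hz[which.max(sp$magnitudes)], 1)

  two <- sin(2 * pi * 0.25 * t) + sin(2 * pi * 1.2 * t)
  sp2 <- magnitude_spectrum(two, sample_rate_hz = fs)
  top2 <- sort(sp2$frequencies_hz[order(sp2$magnitudes,
                                        decreasing = TRUE)[1:2]])
  expect_equal(top2, c(0.25, 1.2))
})

test_that("too-short signals are rejected at the resolution floor", {
  expect_error(magnitude_spectrum(rnorm(1000), sample_rate_hz = 10),
               class = "lcosa_resolution_error")
})

test_that("sub-band moments match textbook formulas on a random spectrum", {
  set.seed(13)
  mags <- abs(rnorm(2501, 10, 3))       # resolution 0.004, 5 bins/band
  sp <- fake_spectrum(mags, 0.004)
  mom <- subband_moments(sp)
  expect_equal(nrow(mom), 250)

  for (k in c(0, 3, 120, 249)) {
    v <- mags[sp$frequencies_hz >= k * 0.02 &
                sp$frequencies_hz < (k + 1) * 0.02]
    n <- length(v)
    m2 <- mean((v - mean(v))^2)
    m3 <- mean((v - mean(v))^3)
    m4 <- mean((v - mean(v))^4)
    g1 <- m3 / m2^1.5
    skew_adj <- g1 * sqrt(n * (n - 1)) / (n - 2)   # adjusted Fisher-Pearson
    kurt_g2 <- m4 / m2^2 - 3                       # excess kurtosis
    i <- which(mom$band == k)
    expect_equal(mom$n_bins[i], n)
    expect_equal(mom$mean[i], mean(v))
    expect_equal(mom$variance[i], stats::var(v))
    expect_equal(mom$skewness[i], skew_adj, tolerance = 1e-12)
    expect_equal(mom$kurtosis[i], kurt_g2, tolerance = 1e-12)
  }
})

test_that("band tiling is exhaustive and non-overlapping below 5 Hz", {
  set.seed(14)
  sp <- fake_spectrum(abs(rnorm(2000, 5)), 0.004)
  mom <- subband_moments(sp)
  in_range <- sum(sp$frequencies_hz < 5)
  expect_equal(sum(mom$n_bins), in_range)
  expect_equal(mom$f_lo, (0:249) * 0.02)
  expect_equal(mom$f_hi, (1:250) * 0.02)
})

test_that("degenerate and symmetric bands follow the documented conventions", {
  sp <- fake_spectrum(rep(4, 200), 0.004)
  expect_warning(mom <- subband_moments(sp, f_max_hz = 0.5),
                 "zero-variance")
  expect_equal(mom$skewness[1], 0)
  expect_equal(mom$kurtosis[1], 0)

  # a symmetric magnitude set has zero skewness
  sp2 <- fake_spectrum(c(1, 2, 3, 4, 5, rep(1, 300)), 0.004)
  mom2 <- suppressWarnings(subband_moments(sp2, f_max_hz = 1))
  expect_equal(mom2$skewness[1], 0, tolerance = 1e-12)

  # undersampled resolution is an error
  sp3 <- fake_spectrum(abs(rnorm(100)), 0.01)
  expect_error(subband_moments(sp3), class = "lcosa_resolution_error")
})

test_that("feature extraction projects the six published band/statistic pairs", {
  set.seed(15)
  sp <- fake_spectrum(abs(rnorm(2501, 10, 3)), 0.004)
  mom <- subband_moments(sp)
  x <- extract_features(mom)
  expect_named(x, paste0("X", 1:6))
  expect_equal(x[["X2"]], mom$skewness[mom$f_lo == 0.36])
  expect_equal(x[["X4"]], mom$kurtosis[mom$f_lo == 1.18])

  # locality: perturbing non-selected bands leaves the features unchanged
  mom2 <- mom
  sel <- vapply(mom2$f_lo, function(f) any(abs(f - c(0.06, 0.36, 0.96, 1.18, 1.40, 1.68)) < 1e-9), logical(1))
  mom2$skewness[!sel] <- mom2$skewness[!sel] + 100
  mom2$kurtosis[!sel] <- -mom2$kurtosis[!sel]
  expect_equal(extract_features(mom2), x)

  # a missing selected band is an error
  mom3 <- mom[mom$f_lo != 0.96, ]
  class(mom3) <- class(mom)
  expect_error(extract_features(mom3), class = "lcosa_feature_error")
})

test_that("features are invariant to sensor gain", {
  sim <- simulate_recording(sim_config(duration_h = 0.2, sample_rate_hz = 25,
                                       target_ahi = 15, seed = 21))
  rec <- sim$recording
  scaled <- rec
  scaled$channels <- lapply(scaled$channels, function(ch) 37.2 * ch)
  expect_equal(study_features(scaled), study_features(rec),
               tolerance = 1e-9)
})

test_that("ANOVA selection ranks a planted 3-SD shift first", {
  set.seed(16)
  n_per <- 10
  g <- rep(c("normal", "mild", "moderate_severe"), each = n_per)
  tab <- as.data.frame(replicate(8, rnorm(3 * n_per)))
  names(tab) <- paste0("noise", 1:8)
  tab$planted <- rnorm(3 * n_per) + 3 * (as.integer(factor(g)) - 1)
  ranked <- anova_select(tab, g)
  expect_equal(ranked$feature[1], "planted")
  expect_equal(nrow(anova_select(tab, g, k = 3)), 3)
})

test_that("stronger shifts outrank weaker ones in almost every replicate", {
  wins <- 0L
  for (r in 1:100) {
    set.seed(100 + r)
    g <- rep(c("a", "b", "c"), each = 8)
    shift <- as.integer(factor(g)) - 1
    tab <- data.frame(strong = rnorm(24) + 3 * shift,
                      weak = rnorm(24) + 1 * shift,
                      noise = rnorm(24))
    ranked <- anova_select(tab, g)
    if (ranked$feature[1] == "strong" &&
        which(ranked$feature == "weak") <
          which(ranked$feature == "noise")) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("ANOVA selection guards its preconditions but runs on null data", {
  set.seed(17)
  tab <- data.frame(a = rnorm(20), b = rnorm(20))
  g_null <- rep(c("x", "y"), each = 10)
  out <- anova_select(tab, g_null)       # identical distributions: executes
  expect_true(all(is.finite(out$f_statistic)))
  expect_error(anova_select(tab, rep(c("x", "y"), c(19, 1))),
               class = "lcosa_selection_error")
})

test_that("candidate feature tables feed selection end to end", {
  set.seed(18)
  sims <- lapply(c(0, 30), function(a)
    simulate_recording(sim_config(duration_h = 0.2, sample_rate_hz = 25,
                                  target_ahi = a)))
  moms <- lapply(sims, function(s)
    subband_moments(magnitude_spectrum(preprocess_recording(s$recording))))
  tab <- candidate_feature_table(moms)
  expect_equal(nrow(tab), 2)
  expect_true(any(grepl("skewness_0.36", names(tab), fixed = TRUE)))
})
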