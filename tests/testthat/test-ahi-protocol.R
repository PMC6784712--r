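# night-estimate constructor shortcut for aggregation tests
ne <- function(subject, night, ahi, censored = FALSE) {
  lcosa:::night_estimate(
    list(subject_id = subject, night = night, setting = "home_lc_only"),
    ahi = if (censored) NA_real_ else ahi, censored = censored,
    severity = if (censored) factor("normal",
                                    levels = lcosa:::severity_levels)
               else severity_from_ahi(ahi),
    n_used = 1L, n_rejected = 0L)
}

test_that("whole-night estimation runs the full pipeline once", {
  fit <- toy_model()
  sim <- simulate_recording(sim_config(duration_h = 0.2, sample_rate_hz = 25,
                                       target_ahi = 20, seed = 61),
                            subject_id = "wn")
  est <- whole_night_ahi(sim$recording, fit)
  expect_s3_class(est, "night_estimate")
  expect_equal(est$n_windows_used, 1L)
  expect_equal(est$censored, is.na(est$ahi))

  short <- simulate_recording(sim_config(duration_h = 0.02,
                                         sample_rate_hz = 25, seed = 62))
  expect_error(whole_night_ahi(short$recording, fit),
               class = "lcosa_insufficient_data_error")
})

test_that("windowed estimation produces the arithmetic window count", {
  fit <- toy_model()
  rec6 <- simulate_recording(sim_config(duration_h = 6, sample_rate_hz = 12,
                                        target_ahi = 10, seed = 63))$recording
  s6 <- windowed_ahi(rec6, fit, window_h = 3, step_h = 1)
  expect_equal(nrow(s6), 4)
  expect_equal(s6$start_s, c(0, 3600, 7200, 10800))
  expect_true(all(s6$end_s - s6$start_s == 3 * 3600))

  rec3 <- simulate_recording(sim_config(duration_h = 3, sample_rate_hz = 12,
                                        target_ahi = 10, seed = 64))$recording
  s3 <- windowed_ahi(rec3, fit, window_h = 3, step_h = 1)
  expect_equal(nrow(s3), 1)

  rec2 <- simulate_recording(sim_config(duration_h = 2, sample_rate_hz = 12,
                                        seed = 65))$recording
  expect_error(windowed_ahi(rec2, fit, window_h = 3),
               class = "lcosa_insufficient_data_error")
})

test_that("rolling-median rejection removes the planted outlier and nothing else", {
  out <- reject_outliers(c(10, 11, 65, 10, 9), median_window = 5,
                         threshold = 10)
  expect_equal(as.numeric(out), c(10, 11, 10, 9))
  expect_equal(attr(out, "n_rejected"), 1L)

  const <- reject_outliers(rep(12, 8))
  expect_equal(as.numeric(const), rep(12, 8))
  expect_equal(attr(const, "n_rejected"), 0L)

  single <- reject_outliers(7.3)
  expect_equal(as.numeric(single), 7.3)

  # never drops everything
  crazy <- reject_outliers(c(0, 100), threshold = 10)
  expect_gte(length(crazy), 1L)
})

test_that("night aggregation averages survivors and honours the majority vote", {
  mk_series <- function(ahi, category) {
    df <- data.frame(start_s = seq_along(ahi) - 1, end_s = seq_along(ahi),
                     ahi = ahi,
                     category = factor(category,
                                       levels = c("normal", "abnormal")))
    attr(df, "provenance") <- list(subject = "s", night = 1L,
                                   setting = "home_lc_only")
    class(df) <- c("ahi_series", "data.frame")
    df
  }
  est <- night_from_series(mk_series(c(8, 10, 12), rep("abnormal", 3)))
  expect_equal(est$ahi, 10)
  expect_equal(as.character(est$severity), "mild")

  est2 <- night_from_series(mk_series(7.3, "abnormal"))
  expect_equal(est2$ahi, 7.3)

  est3 <- night_from_series(mk_series(c(10, 11, 10, 9),
                                      rep("abnormal", 4)))
  expect_equal(est3$ahi, 10)

  # normal-majority night is censored
  est4 <- night_from_series(mk_series(c(2.5, 2.5, 9),
                                      c("normal", "normal", "abnormal")))
  expect_true(est4$censored)
  expect_equal(as.character(est4$severity), "normal")
})

test_that("subject aggregation takes the highest night and censors only if all censored", {
  d1 <- aggregate_subject(list(ne("1", 1, 9.38), ne("1", 2, 8.66)))
  expect_equal(d1$final_ahi, 9.38)
  expect_equal(as.character(d1$final_severity), "mild")

  d2 <- aggregate_subject(list(ne("6", 1, NA, censored = TRUE),
                               ne("6", 2, 6.63)))
  expect_equal(d2$final_ahi, 6.63)
  expect_false(d2$final_censored)
  expect_equal(as.character(d2$final_severity), "mild")

  d3 <- aggregate_subject(list(ne("14", 1, NA, censored = TRUE),
                               ne("14", 2, NA, censored = TRUE)))
  expect_true(d3$final_censored)
  expect_equal(as.character(d3$final_severity), "normal")

  expect_error(aggregate_subject(list()), class = "lcosa_data_error")
  expect_error(aggregate_subject(list(ne("a", 1, 7), ne("b", 1, 8))),
               class = "lcosa_data_error")
})

test_that("raising one night's AHI never lowers the final diagnosis", {
  set.seed(66)
  for (r in 1:25) {
    vals <- runif(3, 0, 30)
    cens <- runif(3) < 0.3
    nights <- lapply(1:3, function(i) ne("m", i, vals[i], cens[i]))
    base <- aggregate_subject(nights)
    i <- sample(3, 1)
    vals2 <- vals; vals2[i] <- vals2[i] + runif(1, 0, 20)
    cens2 <- cens; cens2[i] <- FALSE
    bumped <- aggregate_subject(lapply(1:3, function(j)
      ne("m", j, vals2[j], cens2[j])))
    base_val <- if (base$final_censored) 0 else base$final_ahi
    bump_val <- if (bumped$final_censored) 0 else bumped$final_ahi
    expect_gte(bump_val, base_val)
    expect_gte(as.integer(bumped$final_severity),
               as.integer(base$final_severity))
  }
})

test_that("window accounting survives the full windowed protocol", {
  fit <- toy_model()
  rec <- simulate_recording(sim_config(duration_h = 5, sample_rate_hz = 12,
                                       target_ahi = 25, seed = 67))$recording
  series <- windowed_ahi(rec, fit, window_h = 3, step_h = 0.5)
  kept <- reject_outliers(series)
  est <- night_from_series(kept, rec = rec)
  expect_equal(est$n_windows_used + est$n_windows_rejected, nrow(series))
  tab <- night_results_table(list(est))
  expect_equal(nrow(tab), 1)
  expect_true(all(c("windows_used", "windows_rejected") %in% names(tab)))
})
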