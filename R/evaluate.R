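# Diagnostic-accuracy and agreement statistics over per-night study tables.
# All metrics treat `abnormal` as the positive class and are reported as
# percentages rounded half-up to one decimal for display; the underlying
# unrounded values are kept in the returned objects.

combine_gold_tables <- function(tables) {
  keep <- c("subject", "night", "setting", "actual_category",
            "predicted_category", "actual_ahi", "predicted_ahi",
            "predicted_censored")
  rbind(tables$clinic_psg[, keep], tables$home_hsat[, keep])
}

scope_filter <- function(records, scope = c("all", "clinic", "home")) {
  scope <- match.arg(scope)
  if (scope == "clinic") records <- records[records$setting == "clinic_psg", ]
  if (scope == "home") records <- records[records$setting == "home_hsat", ]
  records
}

#' Per-night confusion metrics for OSA detection
#'
#' Scores predicted against actual clinical category (normal/abnormal) per
#' study-night, with `abnormal` as the positive class. Studies without a
#' gold-standard category (the failed 0.00 h clinic study) are excluded.
#'
#' @param records data frame with `setting`, `actual_category` and
#'   `predicted_category` columns, e.g. [combine_gold_tables()] of
#'   [load_study_tables()].
#' @param scope `"all"`, `"clinic"` (PSG nights) or `"home"` (HSAT nights).
#' @return object of class `confusion_metrics`: counts `tp`, `fp`, `tn`,
#'   `fn` and percentages `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` (unrounded).
#' @export
confusion_metrics <- function(records, scope = "all") {
  records <- scope_filter(records, scope)
  ok <- !is.na(records$actual_category) & !is.na(records$predicted_category)
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0L)
    stop_lcosa("no scored studies in scope", "lcosa_data_error")
  act <- records$actual_category == "abnormal"
  prd <- records$predicted_category == "abnormal"
  tp <- sum(act & prd); fp <- sum(!act & prd)
  tn <- sum(!act & !prd); fn <- sum(act & !prd)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
         accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         ppv = 100 * tp / (tp + fp),
         npv = 100 * tn / (tn + fn),
         scope = scope),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics> scope %s, n = %d (TP %d, FP %d, TN %d, FN %d)\n",
    x$scope, x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
    round_half_up(x$accuracy), round_half_up(x$sensitivity),
    round_half_up(x$specificity), round_half_up(x$ppv),
    round_half_up(x$npv)))
  invisible(x)
}

#' Three-class severity accuracy per study-night
#'
#' Scores the combined two-stage severity grade per study-night. Both actual
#' and predicted severities are resolved from the AHI values through
#' [severity_from_ahi()] (censored `"<5"` predictions are `normal`; actual
#' moderate and severe collapse into `moderate_severe` by the mapping).
#' Study-nights whose severity cannot be resolved are skipped with a warning.
#'
#' @inheritParams confusion_metrics
#' @return list with `accuracy` (percent, unrounded), `n_correct`, `n`.
#' @export
severity_accuracy <- function(records, scope = "all") {
  records <- scope_filter(records, scope)
  actual_sev <- rep(NA_character_, nrow(records))
  ok_a <- !is.na(records$actual_ahi)
  actual_sev[ok_a] <- as.character(severity_from_ahi(records$actual_ahi[ok_a]))
  pred_sev <- rep(NA_character_, nrow(records))
  pred_sev[records$predicted_censored] <- "normal"
  ok_p <- !records$predicted_censored & !is.na(records$predicted_ahi)
  pred_sev[ok_p] <- as.character(severity_from_ahi(records$predicted_ahi[ok_p]))
  scored <- !is.na(actual_sev) & !is.na(pred_sev)
  if (any(!scored & !(is.na(records$actual_category))))
    warning("study-nights with unresolvable severity skipped")
  if (!any(scored))
    stop_lcosa("no study-nights with resolvable severity", "lcosa_data_error")
  list(accuracy = 100 * mean(actual_sev[scored] == pred_sev[scored]),
       n_correct = sum(actual_sev[scored] == pred_sev[scored]),
       n = sum(scored))
}

#' Bland-Altman agreement between actual and predicted AHI
#'
#' Differences are oriented actual minus predicted (positive bias means the
#' pipeline underestimates). Limits of agreement are bias +/- 1.96 times the
#' population SD of the differences. Only study-nights where both AHI values
#' are numeric enter (censored `"<5"` predictions are excluded, since no
#' numeric estimate exists for them).
#'
#' @param records data frame with `actual_ahi`, `predicted_ahi`,
#'   `predicted_censored`.
#' @return object of class `agreement_stats`: `n_pairs`, `bias`,
#'   `loa_lower`, `loa_upper`, `sd_diff` (population SD),
#'   `median_abs_error`, `pearson_r`, plus the paired values.
#' @export
agreement_stats <- function(records) {
  ok <- !is.na(records$actual_ahi) & !is.na(records$predicted_ahi) &
    !records$predicted_censored
  a <- records$actual_ahi[ok]
  p <- records$predicted_ahi[ok]
  if (length(a) < 2L)
    stop_lcosa("need >= 2 numeric actual/predicted AHI pairs",
               "lcosa_data_error")
  d <- a - p
  bias <- mean(d)
  sd_pop <- sqrt(mean((d - bias)^2))
  structure(
    list(n_pairs = length(d), bias = bias, sd_diff = sd_pop,
         loa_lower = bias - 1.96 * sd_pop, loa_upper = bias + 1.96 * sd_pop,
         median_abs_error = median(abs(d)),
         pearson_r = if (sd(a) > 0 && sd(p) > 0) cor(a, p) else NA_real_,
         actual = a, predicted = p),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> %d numeric AHI pairs\n", x$n_pairs))
  cat(sprintf("  bias %.2f events/h, limits of agreement %.2f to %.2f\n",
              round_half_up(x$bias, 2), round_half_up(x$loa_lower, 2),
              round_half_up(x$loa_upper, 2)))
  cat(sprintf("  median |error| %.2f events/h, Pearson r %.2f\n",
              round_half_up(x$median_abs_error, 2),
              round_half_up(x$pearson_r, 2)))
  invisible(x)
}

#' @export
plot.agreement_stats <- function(x, ...) {
  m <- (x$actual + x$predicted) / 2
  d <- x$actual - x$predicted
  plot(m, d, xlab = "mean of actual and predicted AHI (events/h)",
       ylab = "actual - predicted AHI (events/h)",
       main = "Bland-Altman agreement", ...)
  abline(h = x$bias, lty = 1)
  abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Subject-level confusion after multi-night max-rule aggregation
#'
#' Aggregates each subject's gold-standard-concurrent nights: the subject is
#' actually abnormal if any scored night is abnormal, and predicted abnormal
#' if any night is predicted abnormal (the max rule applied to categories).
#' Subjects without any scored night are excluded with a warning.
#'
#' @param records combined gold-standard study-nights (clinic + home HSAT).
#' @return a `confusion_metrics` object at subject level.
#' @export
subject_level_confusion <- function(records) {
  ok <- !is.na(records$actual_category) & !is.na(records$predicted_category)
  dropped <- setdiff(unique(records$subject), unique(records$subject[ok]))
  if (length(dropped))
    warning(sprintf("subjects with no scored nights excluded: %s",
                    paste(dropped, collapse = ", ")))
  records <- records[ok, , drop = FALSE]
  agg <- function(v) any(v == "abnormal")
  act <- tapply(records$actual_category, records$subject, agg)
  prd <- tapply(records$predicted_category, records$subject, agg)
  stopifnot(identical(names(act), names(prd)))
  tp <- sum(act & prd); fp <- sum(!act & prd)
  tn <- sum(!act & !prd); fn <- sum(act & !prd)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = length(act),
         accuracy = 100 * (tp + tn) / length(act),
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         ppv = 100 * tp / (tp + fp),
         npv = 100 * tn / (tn + fn),
         scope = "subject"),
    class = "confusion_metrics"
  )
}

#' Paired comparison of AHI estimates with and without HSAT sensors
#'
#' Tests whether wearing the home-sleep-apnea-test sensors changes the
#' load-cell AHI estimate: per subject, the mean predicted AHI over the
#' HSAT-concurrent nights is compared against the mean over the
#' load-cell-only nights with a two-sided paired t-test. Censored `"<5"`
#' estimates are imputed at `censor_value` (default 2.5 events/h, the
#' midpoint of the normal range) before averaging.
#'
#' @param hsat_records,lc_only_records per-night tables with `subject`,
#'   `predicted_ahi`, `predicted_censored` (e.g. `home_hsat` and
#'   `home_lc_only` from [load_study_tables()]).
#' @param censor_value imputation value for censored estimates.
#' @return list with `t`, `df`, `p_value`, `n_subjects`, `censor_value`.
#' @export
compare_hsat_effect <- function(hsat_records, lc_only_records,
                                censor_value = 2.5) {
  impute <- function(df) {
    v <- ifelse(df$predicted_censored, censor_value, df$predicted_ahi)
    tapply(v, df$subject, mean)
  }
  a <- impute(hsat_records)
  b <- impute(lc_only_records)
  common <- intersect(names(a), names(b))
  if (length(common) < 3L)
    stop_lcosa("need >= 3 subjects present in both tables", "lcosa_data_error")
  d <- a[common] - b[common]
  if (sd(d) == 0) {
    # identical paired estimates: no evidence of any effect
    return(list(t = 0, df = length(common) - 1L, p_value = 1,
                n_subjects = length(common), censor_value = censor_value))
  }
  tt <- t.test(a[common], b[common], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_subjects = length(common),
       censor_value = censor_value)
}

#' Full diagnostic-accuracy report over the packaged study tables
#'
#' Computes every headline statistic of the evaluation suite from the
#' packaged per-night tables: per-night confusion metrics overall, in-clinic
#' and in-home; three-class severity accuracy per scope; Bland-Altman
#' agreement and median absolute AHI error over the numeric pairs;
#' subject-level confusion after max-rule aggregation; and the paired
#' HSAT-effect comparison.
#'
#' @param tables result of [load_study_tables()] (the default).
#' @return object of class `osa_evaluation` with components `confusion`
#'   (list all/clinic/home), `severity` (list all/clinic/home),
#'   `agreement`, `subject_level`, `hsat_effect`.
#' @export
#' @examples
#' evaluate_tables()
evaluate_tables <- function(tables = load_study_tables()) {
  gold <- combine_gold_tables(tables)
  structure(
    list(
      confusion = list(all = confusion_metrics(gold, "all"),
                       clinic = confusion_metrics(gold, "clinic"),
                       home = confusion_metrics(gold, "home")),
      severity = list(all = severity_accuracy(gold, "all"),
                      clinic = severity_accuracy(gold, "clinic"),
                      home = severity_accuracy(gold, "home")),
      agreement = agreement_stats(gold),
      subject_level = subject_level_confusion(gold),
      hsat_effect = compare_hsat_effect(tables$home_hsat,
                                        tables$home_lc_only)
    ),
    class = "osa_evaluation"
  )
}

#' @export
print.osa_evaluation <- function(x, ...) {
  f1 <- function(v) sprintf("%.1f", round_half_up(v, 1))
  cm <- function(m) sprintf(
    "accuracy %s%%, sensitivity %s%%, specificity %s%%, PPV %s%%, NPV %s%%",
    f1(m$accuracy), f1(m$sensitivity), f1(m$specificity), f1(m$ppv),
    f1(m$npv))
  cat("Per-night OSA detection (positive class: abnormal)\n")
  cat("  all studies:     ", cm(x$confusion$all), "\n", sep = "")
  cat("  in-clinic (PSG): ", cm(x$confusion$clinic), "\n", sep = "")
  cat("  in-home (HSAT):  ", cm(x$confusion$home), "\n", sep = "")
  cat("Severity classification (normal / mild / moderate-severe)\n")
  cat(sprintf("  all %s%% (%d/%d), clinic %s%% (%d/%d), home %s%% (%d/%d)\n",
              f1(x$severity$all$accuracy), x$severity$all$n_correct,
              x$severity$all$n, f1(x$severity$clinic$accuracy),
              x$severity$clinic$n_correct, x$severity$clinic$n,
              f1(x$severity$home$accuracy), x$severity$home$n_correct,
              x$severity$home$n))
  ag <- x$agreement
  cat(sprintf(
    "AHI agreement over %d numeric pairs: bias %.2f events/h, limits %.2f to %.2f, median |error| %.2f, Pearson r %.2f\n",
    ag$n_pairs, round_half_up(ag$bias, 2), round_half_up(ag$loa_lower, 2),
    round_half_up(ag$loa_upper, 2), round_half_up(ag$median_abs_error, 2),
    round_half_up(ag$pearson_r, 2)))
  sl <- x$subject_level
  cat(sprintf(
    "Subject-level (max rule over nights, n = %d): sensitivity %s%%, specificity %s%%\n",
    sl$n, f1(sl$sensitivity), f1(sl$specificity)))
  he <- x$hsat_effect
  cat(sprintf(
    "HSAT-sensor effect on AHI estimates (paired t, %d subjects): t = %.2f, p = %.2f\n",
    he$n_subjects, round_half_up(he$t, 2), round_half_up(he$p_value, 2)))
  invisible(x)
}

#' Flatten an evaluation report to a named numeric vector
#'
#' Convenience for machine-readable output (JSON, acceptance checks).
#'
#' @param x an `osa_evaluation`.
#' @return named numeric vector of all headline statistics.
#' @export
evaluation_values <- function(x) {
  stopifnot(inherits(x, "osa_evaluation"))
  c(accuracy_all_pct = x$confusion$all$accuracy,
    sensitivity_all_pct = x$confusion$all$sensitivity,
    specificity_all_pct = x$confusion$all$specificity,
    ppv_all_pct = x$confusion$all$ppv,
    npv_all_pct = x$confusion$all$npv,
    accuracy_clinic_pct = x$confusion$clinic$accuracy,
    sensitivity_clinic_pct = x$confusion$clinic$sensitivity,
    specificity_clinic_pct = x$confusion$clinic$specificity,
    accuracy_home_pct = x$confusion$home$accuracy,
    sensitivity_home_pct = x$confusion$home$sensitivity,
    specificity_home_pct = x$confusion$home$specificity,
    severity_accuracy_all_pct = x$severity$all$accuracy,
    severity_accuracy_clinic_pct = x$severity$clinic$accuracy,
    severity_accuracy_home_pct = x$severity$home$accuracy,
    median_abs_ahi_error = x$agreement$median_abs_error,
    bland_altman_bias = x$agreement$bias,
    bland_altman_lower = x$agreement$loa_lower,
    bland_altman_upper = x$agreement$loa_upper,
    pearson_r = x$agreement$pearson_r,
    subject_sensitivity_pct = x$subject_level$sensitivity,
    subject_specificity_pct = x$subject_level$specificity,
    hsat_effect_t = x$hsat_effect$t,
    hsat_effect_p = x$hsat_effect$p_value)
}
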