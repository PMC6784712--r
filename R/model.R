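# Two-stage OSA classifier: a stage-one decision tree (S1DT) separates
# normal from abnormal studies on features X1, X4, X6; a stage-two linear
# regression (S2LR) estimates AHI for abnormal studies from X2^2, X3, X5.

# reference S2LR coefficients: AHI = 11.94 + 23.06*X2^2 + 8.74*X3 - 15.04*X5
.reference_s2lr <- c(intercept = 11.94, X2sq = 23.06, X3 = 8.74, X5 = -15.04)

#' Map an AHI value to an OSA severity grade
#'
#' Severity grading used throughout the pipeline: AHI below 5 events/h is
#' `normal`, 5 to 15 events/h inclusive is `mild`, and above 15 events/h is
#' `moderate_severe`. Moderate and severe OSA are graded as a single class
#' because both are managed with the same first-line therapy (CPAP).
#'
#' @param ahi numeric vector of AHI values (events/h, must be >= 0).
#' @return factor with levels `normal`, `mild`, `moderate_severe`.
#' @export
#' @examples
#' severity_from_ahi(c(2, 9.92, 20.06))
severity_from_ahi <- function(ahi) {
  ahi <- as.numeric(ahi)
  if (anyNA(ahi) || any(ahi < 0))
    stop_lcosa("AHI must be non-negative and non-missing", "lcosa_parameter_error")
  out <- ifelse(ahi < 5, "normal", ifelse(ahi <= 15, "mild", "moderate_severe"))
  factor(out, levels = severity_levels)
}

#' Stage-two linear regression AHI prediction
#'
#' Evaluates the stage-two regression
#' `AHI = b0 + b1 * X2^2 + b2 * X3 + b3 * X5` for one or more feature
#' vectors. The default coefficients are the frozen reference model
#' (11.94, 23.06, 8.74, -15.04); refitted coefficients from [osa_fit()] may
#' be supplied instead. The squared X2 term makes the prediction symmetric
#' in the sign of X2.
#'
#' @param x named numeric vector with elements `X2`, `X3`, `X5` (extra
#'   elements ignored), or a data frame with those columns.
#' @param coefficients numeric vector `c(intercept, X2sq, X3, X5)`.
#' @return numeric AHI prediction(s) in events/h; may be below 5 (the
#'   clamp to the abnormal range happens in [predict_study()]).
#' @export
#' @examples
#' s2lr_predict(c(X2 = 0, X3 = 0, X5 = 0))  # 11.94
s2lr_predict <- function(x, coefficients = .reference_s2lr) {
  if (length(coefficients) != 4L || !all(is.finite(coefficients)))
    stop_lcosa("coefficients must be 4 finite numbers (intercept, X2sq, X3, X5)",
               "lcosa_parameter_error")
  if (is.data.frame(x)) {
    need <- c("X2", "X3", "X5")
    if (!all(need %in% names(x)))
      stop_lcosa("feature data must contain X2, X3, X5", "lcosa_feature_error")
    X2 <- x$X2; X3 <- x$X3; X5 <- x$X5
  } else {
    x <- unlist(x)
    if (!all(c("X2", "X3", "X5") %in% names(x)))
      stop_lcosa("feature vector must name X2, X3, X5", "lcosa_feature_error")
    X2 <- x[["X2"]]; X3 <- x[["X3"]]; X5 <- x[["X5"]]
  }
  if (any(!is.finite(X2)) || any(!is.finite(X3)) || any(!is.finite(X5)))
    stop_lcosa("features must be finite", "lcosa_feature_error")
  unname(coefficients[1L] + coefficients[2L] * X2^2 +
           coefficients[3L] * X3 + coefficients[4L] * X5)
}

#' Construct an OSA pipeline object
#'
#' Bundles the stage-two regression coefficients with an optional trained
#' stage-one decision tree. The default object carries the frozen reference
#' regression but no tree (the tree's split thresholds were never published
#' and must be learned from data with [osa_fit()]); calling
#' [predict_study()] on a tree-less pipeline is an error.
#'
#' @param coefficients stage-two coefficients `c(intercept, X2sq, X3, X5)`.
#' @param tree optional fitted `rpart` classification tree on X1, X4, X6.
#' @return object of class `osa_model`.
#' @export
osa_model <- function(coefficients = .reference_s2lr, tree = NULL) {
  if (length(coefficients) != 4L || !all(is.finite(coefficients)))
    stop_lcosa("coefficients must be 4 finite numbers", "lcosa_parameter_error")
  names(coefficients) <- names(.reference_s2lr)
  structure(list(coefficients = coefficients, tree = tree),
            class = "osa_model")
}

#' @export
print.osa_model <- function(x, ...) {
  cat("<osa_model> two-stage OSA classifier\n")
  b <- x$coefficients
  cat(sprintf("  S2LR: AHI = %.2f + %.2f*X2^2 + %.2f*X3 + %.2f*X5\n",
              b[1L], b[2L], b[3L], b[4L]))
  cat(if (is.null(x$tree)) "  S1DT: <untrained>\n"
      else sprintf("  S1DT: decision tree with %d terminal node(s)\n",
                   sum(x$tree$frame$var == "<leaf>")))
  invisible(x)
}

#' @export
coef.osa_model <- function(object, ...) object$coefficients

#' Stage-one decision-tree classification
#'
#' Classifies feature vectors as `normal` or `abnormal` with the trained
#' stage-one decision tree (thresholds on X1, X4, X6).
#'
#' @param x named numeric vector or data frame with `X1`, `X4`, `X6`.
#' @param model an [osa_model()] or [osa_fit()] with a trained tree.
#' @return factor with levels `normal`, `abnormal`.
#' @export
s1dt_classify <- function(x, model) {
  if (!inherits(model, "osa_model"))
    stop_lcosa("model must be an osa_model", "lcosa_parameter_error")
  if (is.null(model$tree))
    stop_lcosa("stage-one tree is untrained; fit one with osa_fit()",
               "lcosa_untrained_error")
  df <- if (is.data.frame(x)) x else as.data.frame(as.list(unlist(x)))
  if (!all(c("X1", "X4", "X6") %in% names(df)))
    stop_lcosa("features X1, X4, X6 required", "lcosa_feature_error")
  cls <- predict(model$tree, newdata = df, type = "class")
  factor(as.character(cls), levels = category_levels)
}

#' Two-stage per-study prediction
#'
#' Applies the full two-stage rule to one or more feature vectors: studies
#' the stage-one tree calls `normal` get the censored AHI token "<5" and
#' severity `normal`; studies called `abnormal` get the stage-two regression
#' AHI clamped from below at 5 events/h (the abnormal gate asserts AHI >= 5,
#' so a lower regression value is inconsistent and is raised to the boundary)
#' and a severity from [severity_from_ahi()].
#'
#' @param x named numeric vector `X1..X6` or data frame with those columns.
#' @param model an [osa_model()] or [osa_fit()] with a trained tree.
#' @return data frame with one row per study: `category`, `ahi` (numeric,
#'   `NA` where censored), `censored`, `severity`.
#' @export
predict_study <- function(x, model) {
  df <- if (is.data.frame(x)) x else as.data.frame(as.list(unlist(x)))
  category <- s1dt_classify(df, model)
  ahi <- rep(NA_real_, nrow(df))
  abn <- category == "abnormal"
  if (any(abn))
    ahi[abn] <- pmax(5, s2lr_predict(df[abn, , drop = FALSE],
                                     model$coefficients))
  severity <- factor(rep("normal", nrow(df)), levels = severity_levels)
  if (any(abn)) severity[abn] <- severity_from_ahi(ahi[abn])
  data.frame(category = category, ahi = ahi, censored = !abn,
             severity = severity)
}

#' Fit the two-stage OSA classifier
#'
#' Trains the stage-one decision tree (Gini impurity, depth at most 3,
#' restricted to features X1, X4 and X6) on all studies, and refits the
#' stage-two AHI regression on `ahi ~ X2^2 + X3 + X5` using only studies
#' whose gold-standard grade is abnormal (actual AHI >= 5): the regression
#' only ever predicts for studies the tree has already called abnormal, so
#' normal studies would only dilute it.
#'
#' @param data data frame with feature columns `X1..X6`, gold-standard
#'   `ahi` (events/h) and/or `category` (`normal`/`abnormal`; derived from
#'   `ahi` when absent), and optionally `subject`.
#' @param minsplit,cp tree growth controls passed to [rpart::rpart()];
#'   depth is fixed at 3.
#' @return object of classes `osa_fit` and `osa_model` with components
#'   `tree` (rpart), `s2lr` (lm), `coefficients`, `n_studies`,
#'   `n_regression`, `call`.
#' @seealso [osa_lopo()] for leave-one-patient-out evaluation.
#' @export
osa_fit <- function(data, minsplit = 10, cp = 0.01) {
  data <- as.data.frame(data)
  need <- paste0("X", 1:6)
  if (!all(need %in% names(data)))
    stop_lcosa("data must contain feature columns X1..X6", "lcosa_feature_error")
  if (is.null(data$category)) {
    if (is.null(data$ahi))
      stop_lcosa("data must contain `category` or gold-standard `ahi`",
                 "lcosa_data_error")
    data$category <- factor(ifelse(data$ahi < 5, "normal", "abnormal"),
                            levels = category_levels)
  } else {
    data$category <- factor(as.character(data$category),
                            levels = category_levels)
  }
  if (nlevels(droplevels(data$category)) < 2L)
    stop_lcosa("training data must contain both normal and abnormal studies",
               "lcosa_data_error")
  tree <- rpart::rpart(
    category ~ X1 + X4 + X6, data = data, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(maxdepth = 3, minsplit = minsplit,
                                   cp = cp, xval = 0)
  )
  abn <- data[!is.na(data$ahi) & data$ahi >= 5, , drop = FALSE]
  if (nrow(abn) < 4L)
    stop_lcosa("need >= 4 abnormal studies with numeric AHI to fit the stage-two regression",
               "lcosa_data_error")
  s2lr <- lm(ahi ~ I(X2^2) + X3 + X5, data = abn)
  coefficients <- setNames(unname(coef(s2lr)), names(.reference_s2lr))
  structure(
    list(coefficients = coefficients, tree = tree, s2lr = s2lr,
         n_studies = nrow(data), n_regression = nrow(abn),
         training_accuracy = mean(predict(tree, type = "class") ==
                                    data$category),
         call = match.call()),
    class = c("osa_fit", "osa_model")
  )
}

#' @export
print.osa_fit <- function(x, ...) {
  cat("<osa_fit> two-stage OSA classifier\n")
  cat(sprintf("  trained on %d studies (%d abnormal in regression)\n",
              x$n_studies, x$n_regression))
  b <- x$coefficients
  cat(sprintf("  S2LR: AHI = %.2f + %.2f*X2^2 + %.2f*X3 + %.2f*X5\n",
              b[1L], b[2L], b[3L], b[4L]))
  cat(sprintf("  S1DT training accuracy: %.1f%%\n",
              100 * x$training_accuracy))
  invisible(x)
}

#' @export
summary.osa_fit <- function(object, ...) {
  cat("Stage-one decision tree (X1, X4, X6):\n")
  print(object$tree)
  cat("\nStage-two AHI regression (X2^2, X3, X5):\n")
  print(summary(object$s2lr))
  invisible(object)
}

#' @export
predict.osa_fit <- function(object, newdata, ...) {
  predict_study(newdata, object)
}

#' @export
residuals.osa_fit <- function(object, ...) residuals(object$s2lr)

#' @export
plot.osa_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    plot(x$s2lr, which = 1, ...)
    return(invisible(x))
  }
  pred <- predict_study(data, x)
  ok <- !pred$censored & !is.na(data$ahi)
  plot(data$ahi[ok], pred$ahi[ok], xlab = "gold-standard AHI (events/h)",
       ylab = "predicted AHI (events/h)",
       main = "Two-stage OSA classifier", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Leave-one-patient-out cross-validation of the two-stage classifier
#'
#' For each subject, all of that subject's studies (every night, every
#' setting) are held out, the pipeline is refit on the remaining subjects'
#' studies with [osa_fit()], and the held-out studies are predicted. This
#' prevents within-subject leakage: repeated nights from one person are
#' never split across training and test. A final pipeline trained on all
#' studies is also returned.
#'
#' @param data data frame as for [osa_fit()], with a `subject` column.
#' @param ... passed on to [osa_fit()].
#' @return object of class `osa_lopo`: `predictions` (one row per study:
#'   `subject`, fold id, gold labels, predicted `category`, `ahi`,
#'   `censored`, `severity`), `fit` (final [osa_fit()] on all data),
#'   `fold_errors` (named list of per-fold failures, empty when clean),
#'   `fold_train_rows` (per-fold training row indices, for leakage audits).
#' @export
osa_lopo <- function(data, ...) {
  data <- as.data.frame(data)
  if (is.null(data$subject))
    stop_lcosa("data must contain a `subject` column", "lcosa_data_error")
  subjects <- unique(as.character(data$subject))
  if (length(subjects) < 3L)
    stop_lcosa("leave-one-patient-out needs >= 3 subjects", "lcosa_data_error")
  preds <- vector("list", length(subjects))
  fold_errors <- list()
  fold_train_rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    hold <- as.character(data$subject) == s
    fold_train_rows[[s]] <- which(!hold)
    fit_i <- tryCatch(osa_fit(data[!hold, , drop = FALSE], ...),
                      lcosa_error = function(e) e)
    if (inherits(fit_i, "error")) {
      fold_errors[[s]] <- conditionMessage(fit_i)
      next
    }
    p <- predict_study(data[hold, , drop = FALSE], fit_i)
    p$subject <- s
    p$fold <- i
    if (!is.null(data$night)) p$night <- data$night[hold]
    if (!is.null(data$ahi)) p$actual_ahi <- data$ahi[hold]
    if (!is.null(data$category))
      p$actual_category <- factor(as.character(data$category[hold]),
                                  levels = category_levels)
    preds[[i]] <- p
  }
  structure(
    list(predictions = do.call(rbind, preds),
         fit = osa_fit(data, ...),
         fold_errors = fold_errors,
         fold_train_rows = fold_train_rows,
         subjects = subjects),
    class = "osa_lopo"
  )
}

#' @export
print.osa_lopo <- function(x, ...) {
  p <- x$predictions
  cat(sprintf("<osa_lopo> %d subjects, %d held-out study predictions\n",
              length(x$subjects), if (is.null(p)) 0L else nrow(p)))
  if (!is.null(p$actual_category)) {
    acc <- mean(p$category == p$actual_category, na.rm = TRUE)
    cat(sprintf("  held-out normal/abnormal accuracy: %.1f%%\n", 100 * acc))
  }
  if (length(x$fold_errors))
    cat(sprintf("  %d fold(s) failed: %s\n", length(x$fold_errors),
                paste(names(x$fold_errors), collapse = ", ")))
  invisible(x)
}
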