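# independent polynomial oracle for the stage-two closed form
s2lr_oracle <- function(X2, X3, X5, b = c(11.94, 23.06, 8.74, -15.04)) {
  b[1] + b[2] * X2 * X2 + b[3] * X3 + b[4] * X5
}

test_that("the frozen stage-two regression is an exact closed form", {
  expect_equal(s2lr_predict(c(X2 = 0, X3 = 0, X5 = 0)), 11.94)
  expect_equal(s2lr_predict(c(X2 = 1, X3 = 1, X5 = 1)), 28.70,
               tolerance = 1e-12)
  # symmetry in the sign of X2 (squared term)
  expect_equal(s2lr_predict(c(X2 = -1.3, X3 = 0.2, X5 = 0.7)),
               s2lr_predict(c(X2 = 1.3, X3 = 0.2, X5 = 0.7)))

  set.seed(31)
  for (i in 1:50) {
    x <- c(X2 = rnorm(1), X3 = rnorm(1), X5 = rnorm(1))
    expect_equal(s2lr_predict(x),
                 s2lr_oracle(x[["X2"]], x[["X3"]], x[["X5"]]),
                 tolerance = 1e-12)
  }
  expect_error(s2lr_predict(c(X2 = NaN, X3 = 0, X5 = 0)),
               class = "lcosa_feature_error")
})

test_that("severity mapping is total with the documented boundaries", {
  expect_equal(as.character(severity_from_ahi(9.92)), "mild")
  expect_equal(as.character(severity_from_ahi(20.06)), "moderate_severe")
  expect_equal(as.character(severity_from_ahi(c(0, 4.999, 5, 15))),
               c("normal", "normal", "mild", "mild"))
  expect_equal(as.character(severity_from_ahi(15 + 1e-9)),
               "moderate_severe")
  expect_error(severity_from_ahi(-0.1), class = "lcosa_parameter_error")

  # totality: every non-negative AHI maps to exactly one of three levels
  grid <- c(seq(0, 120, by = 0.25), 4.999999, 5.000001, 14.999999,
            15.000001)
  sev <- severity_from_ahi(grid)
  expect_false(anyNA(sev))
  expect_setequal(levels(sev), c("normal", "mild", "moderate_severe"))
})

test_that("an untrained pipeline refuses to classify", {
  m <- osa_model()
  expect_error(s1dt_classify(c(X1 = 0, X4 = 0, X6 = 0), m),
               class = "lcosa_untrained_error")
  expect_equal(coef(m), c(intercept = 11.94, X2sq = 23.06, X3 = 8.74,
                          X5 = -15.04))
})

test_that("two-stage predictions satisfy the censoring invariants", {
  fit <- toy_model()
  dat <- fabricated_cohort(seed = 99)
  p <- predict_study(dat, fit)
  expect_equal(nrow(p), nrow(dat))
  # category = normal <=> censored <=> severity = normal
  expect_equal(p$censored, p$category == "normal")
  expect_equal(p$severity == "normal", p$category == "normal")
  abn <- !p$censored
  expect_true(all(p$ahi[abn] >= 5))
  expect_true(all(is.na(p$ahi[!abn])))
  # self-consistency on the training data
  expect_gte(mean(predict(fit, fabricated_cohort())$category ==
                    fabricated_cohort()$category), fit$training_accuracy)
})

test_that("abnormal studies with a low regression value clamp to 5 (mild)", {
  fit <- toy_model()
  # coefficients that always predict a negative AHI
  low <- osa_model(coefficients = c(-50, 0, 0, 0), tree = fit$tree)
  dat <- fabricated_cohort(seed = 7)
  p <- predict_study(dat, low)
  abn <- !p$censored
  expect_true(any(abn))
  expect_true(all(p$ahi[abn] == 5))
  expect_true(all(p$severity[abn] == "mild"))
})

test_that("the fitted tree uses only X1, X4, X6 and the regression only X2^2, X3, X5", {
  fit <- toy_model()
  used <- setdiff(unique(as.character(fit$tree$frame$var)), "<leaf>")
  expect_true(all(used %in% c("X1", "X4", "X6")))
  expect_setequal(names(coef(fit$s2lr)),
                  c("(Intercept)", "I(X2^2)", "X3", "X5"))
})

test_that("LOPO folds account for every study exactly once", {
  dat <- fabricated_cohort(n_subjects = 5, nights = 2, seed = 55)
  cv <- osa_lopo(dat)
  expect_equal(length(cv$subjects), 5)
  expect_equal(nrow(cv$predictions), 10)
  expect_equal(as.integer(table(cv$predictions$subject)), rep(2L, 5))
  expect_length(cv$fold_errors, 0)
  expect_error(osa_lopo(fabricated_cohort(n_subjects = 2)),
               class = "lcosa_data_error")
})

test_that("held-out folds carry no trace of the held-out subject", {
  dat <- fabricated_cohort(n_subjects = 6, nights = 2, seed = 56)
  cv <- osa_lopo(dat)
  for (s in cv$subjects) {
    rows <- cv$fold_train_rows[[s]]
    expect_false(any(dat$subject[rows] == s))
    # refitting on exactly those rows reproduces the fold predictions
    refit <- osa_fit(dat[rows, ])
    again <- predict_study(dat[dat$subject == s, ], refit)
    fold <- cv$predictions[cv$predictions$subject == s, ]
    expect_equal(again$category, fold$category)
    expect_equal(again$ahi, fold$ahi)
  }
})

test_that("fitting is deterministic for fixed data", {
  dat <- fabricated_cohort(seed = 57)
  cv1 <- osa_lopo(dat)
  cv2 <- osa_lopo(dat)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(coef(cv1$fit), coef(cv2$fit))
})

test_that("refitting recovers the generating regression law within 2 SE", {
  set.seed(58)
  n <- 200
  X2 <- rnorm(n, 0, 0.6); X3 <- rnorm(n, 1, 0.6); X5 <- rnorm(n, 0, 0.6)
  truth <- c(11.94, 23.06, 8.74, -15.04)
  ahi <- pmax(5, truth[1] + truth[2] * X2^2 + truth[3] * X3 +
                truth[4] * X5 + rnorm(n, 0, 1))
  dat <- data.frame(subject = rep(sprintf("s%02d", 1:50), each = 4),
                    X1 = rnorm(n, 3), X2 = X2, X3 = X3,
                    X4 = rnorm(n, 3), X5 = X5, X6 = rnorm(n, 3),
                    ahi = ahi)
  # add a block of normal studies so the tree can be grown
  normals <- fabricated_cohort(n_subjects = 10, nights = 2, seed = 59)
  normals <- normals[normals$category == "normal",
                     c("subject", paste0("X", 1:6), "ahi")]
  normals$subject <- paste0("n", normals$subject)
  fit <- osa_fit(rbind(dat, normals))
  est <- coef(fit$s2lr)
  se <- summary(fit$s2lr)$coefficients[, "Std. Error"]
  expect_true(all(abs(est - truth) <= 2 * se))
})

test_that("permuted labels yield chance-level held-out detection", {
  accs <- numeric(20)
  for (r in 1:20) {
    set.seed(200 + r)
    dat <- fabricated_cohort(n_subjects = 10, nights = 2,
                             seed = 300 + r)
    perm <- sample(nrow(dat))
    dat$ahi <- dat$ahi[perm]
    dat$category <- dat$category[perm]
    cv <- osa_lopo(dat)
    p <- cv$predictions
    accs[r] <- mean(p$category == p$actual_category)
  }
  majority <- 0.5  # fabricated cohorts are class-balanced
  expect_lt(abs(mean(accs) - majority), 0.10)
})
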