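# Shared fixtures built in code. Expensive objects are cached per session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small random 4-channel recording
toy_recording <- function(n = 4000, fs = 20, seed = 1) {
  set.seed(seed)
  lc_recording(replicate(4, rnorm(n), simplify = FALSE), sample_rate_hz = fs,
               subject_id = "toy")
}

# fabricated per-study feature table with a known two-class structure:
# abnormal studies shift X1/X4/X6 and carry an AHI generated from the
# reference regression law on X2/X3/X5 plus noise
fabricated_cohort <- function(n_subjects = 12, nights = 2, seed = 42,
                              shift = 3, noise_sd = 1) {
  set.seed(seed)
  n <- n_subjects * nights
  abn <- rep(rep(c(TRUE, FALSE), length.out = n_subjects), each = nights)
  X2 <- rnorm(n, 0, 0.5)
  X3 <- rnorm(n, ifelse(abn, 1.5, 0), 0.5)
  X5 <- rnorm(n, 0, 0.5)
  ahi_law <- 11.94 + 23.06 * X2^2 + 8.74 * X3 - 15.04 * X5
  ahi <- ifelse(abn, pmax(5.5, ahi_law + rnorm(n, 0, noise_sd)),
                runif(n, 0, 4))
  data.frame(
    subject = rep(sprintf("f%02d", seq_len(n_subjects)), each = nights),
    night = rep(seq_len(nights), n_subjects),
    X1 = rnorm(n, ifelse(abn, shift, 0)),
    X2 = X2, X3 = X3,
    X4 = rnorm(n, ifelse(abn, shift, 0)),
    X5 = X5,
    X6 = rnorm(n, ifelse(abn, shift, 0)),
    ahi = ahi,
    category = factor(ifelse(abn, "abnormal", "normal"),
                      levels = c("normal", "abnormal"))
  )
}

# a trained pipeline on cleanly separable fabricated features
toy_model <- function() {
  cached("toy_model", osa_fit(fabricated_cohort()))
}

# small simulated cohort shared across simulator/model tests
small_sim_cohort <- function() {
  cached("small_sim_cohort",
         simulate_cohort(10, 1, seed = 101, duration_h = 2,
                         sample_rate_hz = 16))
}
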