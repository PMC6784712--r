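# Shared internal helpers.

# round half away from zero at `digits`, matching clinical-report presentation
# (base round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

severity_levels <- c("normal", "mild", "moderate_severe")
category_levels <- c("normal", "abnormal")

stop_lcosa <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "lcosa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
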