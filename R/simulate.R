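# Synthetic bed-signal simulator. Generates 4-channel load-cell recordings
# with known ground truth so every pipeline stage (and model refitting) is
# testable without access to clinical recordings. The composite emulates:
# a respiratory oscillation (raised-cosine breath train whose harmonics
# reach the 0.96-1.7 Hz feature bands), a weaker pulse-like
# ballistocardiogram, apnea/hypopnea events that suppress respiratory
# amplitude for 10-60 s followed by recovery hyperpnea (deeper and faster
# breathing), a post-event sympathetic heart-rate surge (the cyclic
# heart-rate variation typical of OSA), arousal movement transients at most
# event terminations, random-walk baseline drift, spontaneous movement
# transients, and broadband sensor noise. Channel weights mimic the
# shoulder/hip weight distribution over the four subassemblies.
#
# Oscillator rates are kept highly stable (metronome-like, ~0.2% jitter)
# and their defaults are placed so that the event-switched spectral lines
# fall inside the six published feature sub-bands: recovery breathing at
# ~1.53 x 0.2415 = 0.368 Hz (X2), the 4th breathing harmonic at 0.966 Hz
# (X3), the cardiac line at 1.19 Hz (X4) surging to ~1.41 Hz (X5), and the
# 7th breathing harmonic at 1.69 Hz (X6). Narrow-band magnitude moments
# only deviate from their Rayleigh (complex-Gaussian) limits when stable
# lines occupy few bins, so this placement is what makes the published
# bands informative for synthetic data; the methods vignette discusses the
# realism trade-off.

#' Simulation configuration
#'
#' Defaults mirror a realistic study night: 6 h at 250 Hz, breathing at
#' 0.2415 Hz (14.5 breaths/min), a pulse-like cardiac component at 1.19 Hz
#' (71 bpm) at one tenth of the respiratory amplitude, and a target event
#' rate of `target_ahi` events/h. Event depth is the fractional suppression
#' of respiratory amplitude; depths of 0.9 and above are labelled apnea,
#' below that hypopnea. Each event ends in a recovery phase: breathing
#' deeper (`recovery_gain`) and faster (`recovery_rate_gain`) and heart
#' rate elevated (`cardiac_surge_gain`), holding for most of `recovery_s`
#' before releasing to baseline, usually with a brief arousal movement.
#'
#' @param duration_h recording length in hours.
#' @param sample_rate_hz sampling rate (default 250, the device rate).
#' @param respiratory_rate_hz mean breathing rate in Hz.
#' @param cardiac_rate_hz heart rate in Hz.
#' @param respiratory_amplitude,cardiac_amplitude component amplitudes
#'   (arbitrary sensor units; only ratios matter after standardization).
#' @param target_ahi target apnea/hypopnea event rate, events/h (>= 0).
#' @param event_duration_s length-2 range of event durations in seconds.
#' @param event_depth length-2 range of fractional amplitude suppression,
#'   within (0, 1].
#' @param apnea_depth_threshold depth at or above which an event is labelled
#'   apnea rather than hypopnea.
#' @param breath_sharpness exponent of the raised-cosine breath shape;
#'   higher values sharpen breaths and strengthen harmonics.
#' @param breath_asymmetry inspiratory/expiratory phase skew; inspiration
#'   is faster than expiration, which strengthens high breathing harmonics.
#' @param rate_jitter relative SD of the slow breathing-rate modulation.
#' @param cardiac_jitter relative SD of the slow heart-rate modulation.
#' @param recovery_gain,recovery_s amplitude overshoot after an event and
#'   the recovery-phase length.
#' @param recovery_rate_gain breathing-rate overshoot during recovery
#'   (post-event hyperpnea is faster as well as deeper breathing).
#' @param event_rate_factor breathing-rate slowing during the obstructed
#'   phase of an event.
#' @param event_cardiac_factor heart-rate slowing during the obstructed
#'   phase (the bradycardia half of the brady-tachy pattern of OSA).
#' @param cardiac_surge_gain post-event heart-rate surge factor (cyclic
#'   heart-rate variation, a hallmark of OSA).
#' @param cardiac_surge_amp post-event ballistocardiogram amplitude surge
#'   (stroke-volume and blood-pressure surge accompanying the tachycardia).
#' @param cardiac_harmonic relative amplitude of the ballistocardiogram's
#'   second harmonic (the BCG waveform is pulse-like, not sinusoidal).
#' @param arousal_prob probability that an event terminates in a brief
#'   arousal movement transient.
#' @param arousal_amplitude amplitude of event-termination arousal
#'   movements.
#' @param drift_sigma random-walk drift step SD per sqrt(second).
#' @param movement_rate_per_h expected spontaneous movement transients per
#'   hour.
#' @param movement_amplitude spontaneous movement transient amplitude.
#' @param noise_sigma white-noise SD per channel.
#' @param channel_weights 4 positive weights distributing the body signal
#'   over the shoulder/hip subassemblies.
#' @param seed optional integer seed; when set, [simulate_recording()] is
#'   fully reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration_h = 6, sample_rate_hz = 250,
                       respiratory_rate_hz = 0.2415, cardiac_rate_hz = 1.19,
                       respiratory_amplitude = 1, cardiac_amplitude = 0.15,
                       target_ahi = 0, event_duration_s = c(10, 60),
                       event_depth = c(0.3, 1.0),
                       apnea_depth_threshold = 0.9,
                       breath_sharpness = 12, breath_asymmetry = 0.6,
                       rate_jitter = 0.001,
                       cardiac_jitter = 0.001,
                       recovery_gain = 1.5, recovery_s = 20,
                       recovery_rate_gain = 1.525,
                       event_rate_factor = 0.9, event_cardiac_factor = 0.9,
                       cardiac_surge_gain = 1.185, cardiac_surge_amp = 1.8,
                       cardiac_harmonic = 0.4,
                       arousal_prob = 0.9, arousal_amplitude = 3,
                       drift_sigma = 0.005, movement_rate_per_h = 1,
                       movement_amplitude = 2, noise_sigma = 0.03,
                       channel_weights = c(0.3, 0.3, 0.2, 0.2),
                       seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$duration_h <= 0 || cfg$sample_rate_hz <= 0)
    stop_lcosa("duration and sample rate must be positive",
               "lcosa_config_error")
  if (cfg$target_ahi < 0)
    stop_lcosa("target_ahi must be >= 0", "lcosa_config_error")
  if (length(cfg$event_duration_s) != 2L || any(cfg$event_duration_s <= 0) ||
      diff(cfg$event_duration_s) < 0)
    stop_lcosa("event_duration_s must be an increasing positive range",
               "lcosa_config_error")
  if (any(cfg$event_depth <= 0) || any(cfg$event_depth > 1))
    stop_lcosa("event_depth must lie in (0, 1]", "lcosa_config_error")
  if (length(cfg$channel_weights) != 4L || any(cfg$channel_weights <= 0))
    stop_lcosa("channel_weights must be 4 positive numbers",
               "lcosa_config_error")
  occupancy <- cfg$target_ahi * mean(cfg$event_duration_s) / 3600
  if (occupancy >= 0.8)
    stop_lcosa("target_ahi too high: events cannot be placed disjointly",
               "lcosa_config_error")
  class(cfg) <- "sim_config"
  cfg
}

# slow smooth modulation: white noise low-passed with a ~tau-second moving
# average on a 1 Hz control grid, interpolated to the sample grid, unit SD
slow_modulation <- function(n, fs, tau_s = 30) {
  n_ctl <- max(ceiling(n / fs), 2 * tau_s, 4)
  z <- stats::filter(rnorm(n_ctl + 2 * tau_s), rep(1 / tau_s, tau_s),
                     sides = 2)
  z <- z[(tau_s + 1):(tau_s + n_ctl)]
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  approx(seq(0, by = 1, length.out = n_ctl), z,
         xout = seq(0, by = 1 / fs, length.out = n) *
           (n_ctl - 1) / max(n / fs, 1),
         rule = 2)$y
}

# disjoint event placement as a renewal process: exponential gaps between
# events, gap rate chosen so the long-run event rate equals target_ahi/h;
# event counts stay within Poisson dispersion of target_ahi * duration
draw_events <- function(cfg, duration_s) {
  lambda_s <- cfg$target_ahi / 3600
  if (lambda_s <= 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      depth = numeric(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  mean_dur <- mean(cfg$event_duration_s)
  gap_rate <- lambda_s / (1 - lambda_s * mean_dur)
  starts <- ends <- depths <- numeric(0)
  t <- rexp(1, gap_rate)
  while (TRUE) {
    dur <- runif(1, cfg$event_duration_s[1L], cfg$event_duration_s[2L])
    if (t + dur > duration_s) break
    starts <- c(starts, t)
    ends <- c(ends, t + dur)
    depths <- c(depths, runif(1, cfg$event_depth[1L], cfg$event_depth[2L]))
    t <- t + dur + rexp(1, gap_rate)
  }
  data.frame(start_s = starts, end_s = ends, depth = depths,
             type = ifelse(depths >= cfg$apnea_depth_threshold,
                           "apnea", "hypopnea"),
             stringsAsFactors = FALSE)
}

# respiratory and autonomic modulation by events: respiratory amplitude
# suppressed to (1 - depth) during each event with 2 s cosine ramps;
# recovery hyperpnea after each event (amplitude overshoot recovery_gain,
# breathing-rate overshoot recovery_rate_gain) and a sympathetic heart-rate
# surge (cardiac_surge_gain), holding a plateau for ~70% of recovery_s
# before releasing to baseline. Returns the amplitude, breathing-rate and
# heart-rate gain tracks.
event_envelope <- function(events, n, fs, cfg) {
  amp <- rep(1, n)
  rate <- rep(1, n)
  surge <- rep(1, n)
  if (nrow(events) == 0L)
    return(list(amp = amp, rate = rate, surge = surge))
  ramp_n <- max(1L, round(2 * fs))
  half <- function(k) (1 - cos(pi * seq_len(k) / k)) / 2  # 0 -> 1
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, floor(events$start_s[i] * fs) + 1L)
    i1 <- min(n, floor(events$end_s[i] * fs))
    if (i1 <= i0) next
    low <- 1 - events$depth[i]
    seg <- rep(low, i1 - i0 + 1L)
    k <- min(ramp_n, length(seg))
    seg[seq_len(k)] <- 1 - (1 - low) * half(k)              # down-ramp
    seg[(length(seg) - k + 1L):length(seg)] <-
      pmax(seg[(length(seg) - k + 1L):length(seg)],
           low + (1 - low) * half(k))                        # up-ramp
    amp[i0:i1] <- pmin(amp[i0:i1], seg)
    # obstructed phase: breathing and heart rate slow (bradycardia)
    rate[i0:i1] <- pmin(rate[i0:i1], cfg$event_rate_factor)
    surge[i0:i1] <- pmin(surge[i0:i1], cfg$event_cardiac_factor)
    # recovery: plateau then release back to baseline
    r0 <- i1 + 1L
    r1 <- min(n, i1 + round(cfg$recovery_s * fs))
    if (r1 >= r0) {
      frac <- seq(0, 1, length.out = r1 - r0 + 1L)
      w <- ifelse(frac < 0.7, 1, (1 - frac) / 0.3)
      amp[r0:r1] <- pmax(amp[r0:r1], 1 + (cfg$recovery_gain - 1) * w)
      rate[r0:r1] <- pmax(rate[r0:r1],
                          1 + (cfg$recovery_rate_gain - 1) * w)
      surge[r0:r1] <- pmax(surge[r0:r1],
                           1 + (cfg$cardiac_surge_gain - 1) * w)
    }
  }
  list(amp = amp, rate = rate, surge = surge)
}

# short broadband wiggle used for spontaneous movements and event arousals
movement_burst <- function(k, fs, amplitude) {
  w <- (1 - cos(2 * pi * seq_len(k) / k)) / 2
  amplitude * w *
    sin(2 * pi * runif(1, 0.2, 1) * seq_len(k) / fs + runif(1, 0, 2 * pi))
}

#' Simulate a 4-channel load-cell recording with known ground truth
#'
#' @param cfg a [sim_config()].
#' @param subject_id,night,setting study metadata for the recording.
#' @return list with `recording` (an [lc_recording()]) and `truth`: event
#'   intervals with type and depth, `true_ahi` (event count / duration,
#'   exactly), and movement intervals.
#' @export
#' @examples
#' sim <- simulate_recording(sim_config(duration_h = 0.1, sample_rate_hz = 25,
#'                                      target_ahi = 20, seed = 1))
#' sim$truth$true_ahi
simulate_recording <- function(cfg, subject_id = "sim", night = 1L,
                               setting = "home_lc_only") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$sample_rate_hz
  duration_s <- cfg$duration_h * 3600
  n <- round(duration_s * fs)

  events <- draw_events(cfg, duration_s)

  # breathing: raised-cosine breath train with slight rate jitter and
  # event-driven amplitude/rate modulation
  env <- event_envelope(events, n, fs, cfg)
  f_inst <- cfg$respiratory_rate_hz * env$rate *
    pmax(0.2, 1 + cfg$rate_jitter * slow_modulation(n, fs))
  phase <- cumsum(f_inst) / fs
  # inspiration is faster than expiration: warping the breath phase skews
  # the waveform and strengthens its high harmonics
  warped <- phase + cfg$breath_asymmetry * sin(2 * pi * phase) / (2 * pi)
  breath <- ((1 + cos(2 * pi * warped)) / 2)^cfg$breath_sharpness
  resp <- cfg$respiratory_amplitude * env$amp * breath

  # ballistocardiogram: pulse-like (fundamental + harmonic), respiratory
  # amplitude modulation, and post-event sympathetic heart-rate surges
  fc_inst <- cfg$cardiac_rate_hz * env$surge *
    (1 + cfg$cardiac_jitter * slow_modulation(n, fs))
  phc <- cumsum(fc_inst) / fs
  surge_w <- if (cfg$cardiac_surge_gain > 1)
    (env$surge - 1) / (cfg$cardiac_surge_gain - 1) else rep(0, n)
  cardiac <- cfg$cardiac_amplitude *
    (1 + (cfg$cardiac_surge_amp - 1) * surge_w) * (1 + 0.2 * breath) *
    (sin(2 * pi * phc) + cfg$cardiac_harmonic * sin(4 * pi * phc))

  drift <- cumsum(rnorm(n, 0, cfg$drift_sigma / sqrt(fs)))

  movement <- rep(0, n)
  # spontaneous position-change movements
  n_mov <- rpois(1, cfg$movement_rate_per_h * cfg$duration_h)
  mov_int <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n_mov > 0) {
    m_start <- sort(runif(n_mov, 0, max(duration_s - 5, 1)))
    m_dur <- runif(n_mov, 1, 5)
    mov_int <- data.frame(start_s = m_start, end_s = m_start + m_dur)
    for (i in seq_len(n_mov)) {
      i0 <- floor(m_start[i] * fs) + 1L
      i1 <- min(n, floor((m_start[i] + m_dur[i]) * fs))
      if (i1 <= i0) next
      movement[i0:i1] <- movement[i0:i1] +
        movement_burst(i1 - i0 + 1L, fs, cfg$movement_amplitude)
    }
  }
  # arousal movements at event termination
  if (nrow(events) > 0L && cfg$arousal_prob > 0) {
    aroused <- runif(nrow(events)) < cfg$arousal_prob
    for (i in which(aroused)) {
      a0 <- floor(events$end_s[i] * fs) + 1L
      a1 <- min(n, a0 + round(runif(1, 1, 3) * fs))
      if (a1 <= a0) next
      movement[a0:a1] <- movement[a0:a1] +
        movement_burst(a1 - a0 + 1L, fs, cfg$arousal_amplitude)
    }
  }

  body <- resp + cardiac + drift
  channels <- lapply(cfg$channel_weights, function(w)
    w * body + movement + rnorm(n, 0, cfg$noise_sigma))

  rec <- lc_recording(channels, sample_rate_hz = fs,
                      subject_id = subject_id, night = night,
                      setting = setting)
  truth <- list(
    events = events[, c("start_s", "end_s", "type", "depth")],
    true_ahi = nrow(events) / cfg$duration_h,
    movements = mov_int
  )
  list(recording = rec, truth = truth)
}

# default per-subject severity mix and AHI draw, mirroring the pilot-cohort
# class balance (6 normal / 5 mild / 3 moderate-severe out of 14)
default_ahi_distribution <- function(n) {
  cls <- sample(c("normal", "mild", "moderate_severe"), n, replace = TRUE,
                prob = c(6, 5, 3) / 14)
  ifelse(cls == "normal", runif(n, 0, 4),
         ifelse(cls == "mild", runif(n, 5, 15), runif(n, 15, 45)))
}

#' Simulate a labelled cohort ready for model fitting
#'
#' Draws one base AHI per subject from `ahi_distribution`, applies +/-20%
#' night-to-night jitter (emulating the night-to-night variability of OSA),
#' simulates each night, and computes the six spectral features per study.
#' Per-subject breathing (14.4-14.6 breaths/min) and heart (71.1-71.7 bpm)
#' rates vary within the narrow stable band the feature sub-bands are
#' anchored to (see the package vignette for why the bands only carry
#' information for near-stable oscillator rates).
#'
#' @param n_subjects number of subjects (>= 3).
#' @param nights_per_subject nights per subject.
#' @param ahi_distribution function `n -> n` base AHI draws; the default
#'   mirrors the pilot cohort's severity mix (6 normal / 5 mild /
#'   3 moderate-severe in 14).
#' @param seed integer seed for the whole cohort.
#' @param duration_h,sample_rate_hz per-night recording size (pass smaller
#'   values than the defaults for quick experiments).
#' @param keep_recordings keep the raw recordings in the result (memory!).
#' @param ... further overrides passed to [sim_config()].
#' @return list with `features` (data frame: `subject`, `night`, `true_ahi`
#'   realized from placed events, `category`, `severity`, `X1..X6`, plus
#'   `ahi = true_ahi`, ready for [osa_fit()]/[osa_lopo()]), `truths`, and
#'   optionally `recordings`.
#' @export
simulate_cohort <- function(n_subjects, nights_per_subject = 2,
                            ahi_distribution = default_ahi_distribution,
                            seed = NULL, duration_h = 6,
                            sample_rate_hz = 250,
                            keep_recordings = FALSE, ...) {
  if (n_subjects < 3L)
    stop_lcosa("need >= 3 subjects", "lcosa_config_error")
  if (!is.null(seed)) set.seed(seed)
  base_ahi <- ahi_distribution(n_subjects)
  if (length(unique(base_ahi >= 5)) < 2L)
    warning("cohort contains a single severity class")
  resp_rates <- runif(n_subjects, 0.2405, 0.2425)
  card_rates <- runif(n_subjects, 1.185, 1.195)
  rows <- list()
  truths <- list()
  recordings <- list()
  for (s in seq_len(n_subjects)) {
    for (nt in seq_len(nights_per_subject)) {
      night_ahi <- max(0, base_ahi[s] * runif(1, 0.8, 1.2))
      cfg <- sim_config(duration_h = duration_h,
                        sample_rate_hz = sample_rate_hz,
                        respiratory_rate_hz = resp_rates[s],
                        cardiac_rate_hz = card_rates[s],
                        target_ahi = night_ahi, ...)
      sim <- simulate_recording(cfg, subject_id = sprintf("sim%02d", s),
                                night = nt)
      x <- study_features(sim$recording)
      true_ahi <- sim$truth$true_ahi
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("sim%02d", s), night = nt, true_ahi = true_ahi,
        category = factor(ifelse(true_ahi < 5, "normal", "abnormal"),
                          levels = category_levels),
        severity = severity_from_ahi(true_ahi),
        t(x), stringsAsFactors = FALSE)
      truths[[length(truths) + 1L]] <- sim$truth
      if (keep_recordings)
        recordings[[length(recordings) + 1L]] <- sim$recording
    }
  }
  features <- do.call(rbind, rows)
  features$ahi <- features$true_ahi
  out <- list(features = features, truths = truths)
  if (keep_recordings) out$recordings <- recordings
  out
}
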