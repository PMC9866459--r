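#' Subject profile for the gait simulator
#'
#' Describes one synthetic subject: recording duration, walking cadence,
#' oscillation amplitude, noise level, and the fraction of the recording
#' spent walking. Defaults mirror the kind of care-home protocol the pipeline
#' targets: recordings of roughly 4.5-9 minutes containing one walking bout
#' embedded in longer sitting/standing and "active" (fidgeting) episodes,
#' with walking making up about a fifth of the samples.
#'
#' @param subject_id Character id.
#' @param duration_s Recording length in seconds (study range 278-527).
#' @param step_frequency_hz Walking cadence in Hz; must be below the Nyquist
#'   frequency `fs / 2`.
#' @param walk_amplitude Amplitude of the cadence oscillation (arbitrary
#'   acceleration units, the same scale as the unit gravity offset).
#' @param noise_sd Baseline accelerometer noise standard deviation.
#' @param walking_fraction Fraction of samples labelled walking, in (0, 1).
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed.
#' @param meta Optional metadata list (sex, age, walking aid, diagnosis).
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, duration_s = 400,
                            step_frequency_hz = 1.4, walk_amplitude = 0.5,
                            noise_sd = 0.08, walking_fraction = 0.2,
                            fs = 11, seed = 1L, meta = list()) {
  stopifnot(walking_fraction > 0, walking_fraction < 1,
            step_frequency_hz > 0, step_frequency_hz < fs / 2,
            duration_s > 0, noise_sd >= 0)
  structure(list(subject_id = subject_id, duration_s = duration_s,
                 step_frequency_hz = step_frequency_hz,
                 walk_amplitude = walk_amplitude, noise_sd = noise_sd,
                 walking_fraction = walking_fraction, fs = fs,
                 seed = as.integer(seed), meta = meta),
            class = "subject_profile")
}

#' Cohort specification for the gait simulator
#'
#' Per-subject parameters are drawn from the given ranges using seeds derived
#' from the master seed, so cohorts are reproducible and subjects are
#' independent. Defaults emulate the study conditions the pipeline was built
#' for: 20 subjects at 11 Hz, durations 278-527 s, cadences 0.8-2.0 Hz
#' (slow, aid-assisted gait included), and walking fractions around 0.2,
#' which yields roughly the 20:73 walking:non-walking segment imbalance the
#' oversampling stage exists for.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param fs Sampling frequency in Hz (default 11).
#' @param duration_range,cadence_range,amplitude_range,noise_range,walking_fraction_range
#'   Min-max ranges for the per-subject draws.
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, fs = 11,
                        duration_range = c(278, 527),
                        cadence_range = c(0.8, 2.0),
                        amplitude_range = c(0.4, 0.7),
                        noise_range = c(0.06, 0.12),
                        walking_fraction_range = c(0.15, 0.28),
                        seed = 1L) {
  stopifnot(n_subjects >= 2)
  structure(list(n_subjects = as.integer(n_subjects), fs = fs,
                 duration_range = duration_range,
                 cadence_range = cadence_range,
                 amplitude_range = amplitude_range,
                 noise_range = noise_range,
                 walking_fraction_range = walking_fraction_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate one subject's recording
#'
#' Builds an episode schedule and samples a triaxial signal at `fs`:
#' \itemize{
#'   \item sitting/standing: unit gravity offset on the vertical axis,
#'     low-variance noise, and occasional slow postural drifts;
#'   \item active episodes: the same baseline with moderate noise bursts
#'     (fidgeting, reaching) but no sustained cadence;
#'   \item one walking bout of `walking_fraction * duration_s` seconds:
#'     sinusoids at the cadence and its first harmonic on the vertical and
#'     anteroposterior axes, plus noise.
#' }
#' Labels are exact by construction, which is what makes parameter-recovery
#' experiments possible. Each episode also gets a small random orientation
#' offset so the gravity direction is not perfectly constant.
#'
#' @param profile A [subject_profile()].
#' @return An [accel_recording()] with per-sample ground-truth labels.
#' @export
simulate_subject <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  fs <- profile$fs
  n <- round(profile$duration_s * fs)
  walk_len <- round(profile$walking_fraction * n)
  min_bout <- round(10 * fs)  # at least 10 s of walking and of non-walking
  if (walk_len < min_bout || n - walk_len < min_bout) {
    stop("walking_fraction leaves less than a 10 s bout on one side",
         call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(profile$seed)

  # non-walking time split into 3-6 sitting/standing or active episodes,
  # with the walking bout inserted between two of them
  n_other <- n - walk_len
  n_ep <- sample(3:6, 1)
  cuts <- sort(sample.int(n_other - 1L, n_ep - 1L))
  ep_len <- diff(c(0L, cuts, n_other))
  ep_type <- sample(c("sit", "active"), n_ep, replace = TRUE,
                    prob = c(0.6, 0.4))
  walk_after <- sample.int(n_ep - 1L, 1)

  x <- y <- z <- numeric(0)
  labels <- character(0)
  append_episode <- function(len, type) {
    t <- seq_len(len) / fs
    tilt <- stats::rnorm(3, 0, 0.03)  # per-episode orientation jitter
    if (type == "sit") {
      drift <- 0.05 * sin(2 * pi * t / (30 + stats::runif(1, 0, 30)))
      sd0 <- profile$noise_sd
      ex <- 1 + tilt[1] + drift + stats::rnorm(len, 0, sd0)
      ey <- tilt[2] + stats::rnorm(len, 0, sd0)
      ez <- tilt[3] + 0.5 * drift + stats::rnorm(len, 0, sd0)
    } else if (type == "active") {
      sd0 <- 2.5 * profile$noise_sd
      burst <- stats::rbinom(len, 1, 0.1) * stats::rnorm(len, 0, 3 * sd0)
      ex <- 1 + tilt[1] + stats::rnorm(len, 0, sd0) + burst
      ey <- tilt[2] + stats::rnorm(len, 0, sd0)
      ez <- tilt[3] + stats::rnorm(len, 0, sd0) + 0.5 * burst
    } else { # walking
      f0 <- profile$step_frequency_hz
      a <- profile$walk_amplitude
      ph <- stats::runif(3, 0, 2 * pi)
      sd0 <- 1.5 * profile$noise_sd
      ex <- 1 + tilt[1] + a * sin(2 * pi * f0 * t + ph[1]) +
        0.4 * a * sin(2 * pi * 2 * f0 * t + ph[2]) +
        stats::rnorm(len, 0, sd0)
      ey <- tilt[2] + 0.25 * a * sin(2 * pi * f0 * t + ph[3]) +
        stats::rnorm(len, 0, sd0)
      ez <- tilt[3] + 0.6 * a * sin(2 * pi * f0 * t + ph[2]) +
        0.25 * a * sin(2 * pi * 2 * f0 * t + ph[1]) +
        stats::rnorm(len, 0, sd0)
    }
    x <<- c(x, ex); y <<- c(y, ey); z <<- c(z, ez)
    labels <<- c(labels, rep(if (type == "walk") "walking" else "other", len))
  }
  for (e in seq_len(n_ep)) {
    append_episode(ep_len[e], ep_type[e])
    if (e == walk_after) append_episode(walk_len, "walk")
  }
  accel_recording(profile$subject_id, x, y, z, labels, fs = fs,
                  meta = profile$meta)
}

#' Simulate a cohort of recordings
#'
#' @param spec A [cohort_spec()].
#' @return List of [accel_recording()] objects, one per subject, with
#'   profiles attached as the `profiles` attribute.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 3, seed = 7))
#' vapply(cohort, duration, 0)
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  draw <- function(rg) stats::runif(spec$n_subjects, rg[1], rg[2])
  dur <- draw(spec$duration_range)
  cad <- draw(spec$cadence_range)
  amp <- draw(spec$amplitude_range)
  noi <- draw(spec$noise_range)
  wf <- draw(spec$walking_fraction_range)
  profiles <- lapply(seq_len(spec$n_subjects), function(i) {
    subject_profile(sprintf("s%02d", i), duration_s = dur[i],
                    step_frequency_hz = cad[i], walk_amplitude = amp[i],
                    noise_sd = noi[i], walking_fraction = wf[i],
                    fs = spec$fs,
                    seed = (spec$seed %% 1000000L) * 1000L + i)
  })
  recordings <- lapply(profiles, simulate_subject)
  attr(recordings, "profiles") <- profiles
  recordings
}

#' Write a cohort to disk
#'
#' One CSV per recording in the [write_recording()] dialect plus a JSON
#' manifest of the generating profiles and seeds.
#'
#' @param recordings A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in recordings) {
    write_recording(rec, file.path(dir, paste0(rec$subject_id, ".csv")))
  }
  profiles <- attr(recordings, "profiles")
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    lapply(profiles, function(p) unclass(p)[setdiff(names(p), "meta")]),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
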