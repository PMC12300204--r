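#' Stimulus schedule for a jumping-point trial
#'
#' @param positions Two-column matrix (`x`, `y`) of target positions in DVA.
#' @param dwell_ms Display duration per position (ms).
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(positions, dwell_ms = 1000) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L || ncol(positions) != 2L) {
    stop_gazeid("positions must be an n x 2 matrix with n >= 1",
                "gazeid_validation_error")
  }
  if (dwell_ms < 1) {
    stop_gazeid("dwell_ms must be positive", "gazeid_validation_error")
  }
  colnames(positions) <- c("x", "y")
  structure(list(positions = positions, dwell_ms = dwell_ms,
                 count = nrow(positions)),
            class = "stimulus_schedule")
}

#' Generate a random jumping-point schedule
#'
#' Target positions jump along the horizontal axis with amplitudes drawn
#' uniformly from `amplitude_range` (saccade amplitudes of roughly 4--20
#' degrees are the physiological working range); jump direction is chosen so
#' the target stays within `bounds`. Vertical position is held at 0: the
#' horizontal channel carries the dynamics used for identification.
#'
#' @param count Number of stimulus positions (the task standard is 100).
#' @param dwell_ms Display time per position in ms (standard: 1000).
#' @param amplitude_range Length-2 numeric, min/max jump amplitude in DVA.
#' @param bounds Horizontal excursion limit in DVA (symmetric about 0).
#' @param seed Integer seed; the schedule is a pure function of it.
#' @return A [stimulus_schedule()] spanning `count * dwell_ms` milliseconds.
#' @export
generate_schedule <- function(count = 100, dwell_ms = 1000,
                              amplitude_range = c(4, 20), bounds = 15,
                              seed = NULL) {
  if (count < 1L) {
    stop_gazeid("count must be >= 1", "gazeid_validation_error")
  }
  if (length(amplitude_range) != 2L || diff(amplitude_range) < 0 ||
      any(amplitude_range <= 0)) {
    stop_gazeid("amplitude_range must be a positive, non-empty range",
                "gazeid_validation_error")
  }
  if (amplitude_range[1] > 2 * bounds) {
    stop_gazeid("amplitude_range exceeds what the screen bounds allow",
                "gazeid_validation_error")
  }
  with_seed(seed, {
    x <- numeric(count)
    x[1] <- stats::runif(1, -bounds / 2, bounds / 2)
    if (count > 1L) {
      for (i in 2:count) {
        amp <- stats::runif(1, amplitude_range[1], amplitude_range[2])
        can_right <- x[i - 1] + amp <= bounds
        can_left <- x[i - 1] - amp >= -bounds
        dir <- if (can_right && can_left) {
          sample(c(-1, 1), 1)
        } else if (can_right) 1 else if (can_left) -1 else {
          # amplitude larger than both margins: clamp toward centre
          amp <- bounds + abs(x[i - 1]) # reach the far bound
          -sign(x[i - 1])
        }
        x[i] <- x[i - 1] + dir * amp
      }
    }
    stimulus_schedule(cbind(x, rep(0, count)), dwell_ms = dwell_ms)
  })
}

#' Oculomotor profile of one simulated subject
#'
#' The parameter set that gives a simulated person an individual oculomotor
#' signature. Defaults sit at the physiological midpoints: saccadic latency
#' 150--200 ms, peak saccade velocity in the 300--500 deg/s band over the
#' 4--20 degree amplitude range, saccade durations of a few tens of ms.
#'
#' @param latency_mean,latency_sd Saccadic latency distribution in ms;
#'   `latency_mean` must lie in \[100, 300\].
#' @param vpeak_scale Peak velocity (deg/s) of a full-amplitude (20 deg)
#'   saccade; the main sequence scales smaller saccades down by a saturating
#'   exponential, so this is the subject's velocity gain.
#' @param duration_slope Additional saccade duration per degree of amplitude
#'   (ms/deg), individualising the duration main sequence.
#' @param fixation_noise_sd White fixation micro-movement noise, DVA.
#' @param drift_rate Scale of slow fixation drift, DVA/s.
#' @param undershoot_frac Fraction of the target step left uncovered by the
#'   primary saccade (corrected during fixation); in \[0, 0.2\].
#' @param blink_rate Expected blinks per stimulus position (Poisson rate).
#' @param seed Optional integer recorded with the profile.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(latency_mean = 175, latency_sd = 15,
                            vpeak_scale = 480, duration_slope = 0.5,
                            fixation_noise_sd = 0.05, drift_rate = 0.3,
                            undershoot_frac = 0.08, blink_rate = 0.05,
                            seed = NULL) {
  if (latency_mean < 100 || latency_mean > 300) {
    stop_gazeid("latency_mean must lie within [100, 300] ms",
                "gazeid_validation_error")
  }
  if (undershoot_frac < 0 || undershoot_frac > 0.2) {
    stop_gazeid("undershoot_frac must lie within [0, 0.2]",
                "gazeid_validation_error")
  }
  if (any(c(latency_sd, vpeak_scale, duration_slope, fixation_noise_sd,
            drift_rate, blink_rate) < 0)) {
    stop_gazeid("profile rate/scale parameters must be non-negative",
                "gazeid_validation_error")
  }
  structure(list(latency_mean = latency_mean, latency_sd = latency_sd,
                 vpeak_scale = vpeak_scale, duration_slope = duration_slope,
                 fixation_noise_sd = fixation_noise_sd, drift_rate = drift_rate,
                 undershoot_frac = undershoot_frac, blink_rate = blink_rate,
                 seed = seed),
            class = "subject_profile")
}

#' Session-level perturbation of a subject profile
#'
#' Emulates template aging across recording sessions: a bounded multiplicative
#' drift of the velocity gain, an additive latency shift and inflation of the
#' fixation noise.
#'
#' @param gain_drift Multiplier on `vpeak_scale`; `|log(gain_drift)|` must not
#'   exceed `max_log_gain`.
#' @param latency_shift Additive shift of `latency_mean`, ms.
#' @param noise_inflation Multiplier on `fixation_noise_sd`.
#' @param max_log_gain Bound on the log-scale perturbations.
#' @return An object of class `session_effect`.
#' @export
session_effect <- function(gain_drift = 1, latency_shift = 0,
                           noise_inflation = 1, max_log_gain = 0.2) {
  if (abs(log(gain_drift)) > max_log_gain + 1e-12 ||
      abs(log(noise_inflation)) > max_log_gain + 1e-12) {
    stop_gazeid("session perturbations must stay bounded (|log gain| <= 0.2)",
                "gazeid_validation_error")
  }
  structure(list(gain_drift = gain_drift, latency_shift = latency_shift,
                 noise_inflation = noise_inflation),
            class = "session_effect")
}

# Main-sequence target peak velocity (deg/s) for amplitude A (deg), normalised
# so that a 20-degree saccade reaches vpeak_scale.
main_sequence_vpeak <- function(amplitude, vpeak_scale, a0 = 5) {
  vpeak_scale * (1 - exp(-amplitude / a0)) / (1 - exp(-20 / a0))
}

# Minimum-jerk position profile on [0, 1]: s(0)=0, s(1)=1, zero endpoint
# velocity/acceleration; peak velocity 1.875/duration in normalised units.
min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

#' Simulate one jumping-point trial
#'
#' For each stimulus position the simulated gaze holds the previous fixation
#' for a sampled saccadic latency, executes a minimum-jerk saccade whose peak
#' velocity follows the subject's main sequence, lands short of the target by
#' `undershoot_frac`, and then fixates with an exponential corrective glide,
#' linear drift and white micro-movement noise. Sampling is 1000 Hz. The
#' output contains no missing samples; use [inject_missing()] to add blinks.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [stimulus_schedule()].
#' @param effect A [session_effect()] (defaults to the identity effect).
#' @param seed Integer seed; the trial is a pure function of
#'   (profile, schedule, effect, seed).
#' @param subject_id,session_id Labels for the resulting recording.
#' @return A [gaze_recording()] of `count * dwell_ms` samples.
#' @export
simulate_trial <- function(profile, schedule, effect = session_effect(),
                           seed = NULL, subject_id = "S1", session_id = "1") {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(schedule, "stimulus_schedule"),
            inherits(effect, "session_effect"))
  dwell <- schedule$dwell_ms
  count <- schedule$count
  n <- count * dwell
  vgain <- profile$vpeak_scale * effect$gain_drift
  lat_mu <- profile$latency_mean + effect$latency_shift
  noise_sd <- profile$fixation_noise_sd * effect$noise_inflation

  with_seed(seed, {
    gaze <- numeric(n)
    tx <- rep(schedule$positions[, "x"], each = dwell)
    ty <- rep(schedule$positions[, "y"], each = dwell)
    cur <- schedule$positions[1, "x"] # assume gaze starts on the first target
    for (p in seq_len(count)) {
      idx0 <- (p - 1L) * dwell
      tgt <- schedule$positions[p, "x"]
      amp <- abs(tgt - cur)
      seg <- numeric(dwell)
      if (p == 1L || amp < 1e-9) {
        land <- cur + (tgt - cur) # no saccade needed on the first position
        lat_n <- 0L
        dur_n <- 0L
        seg[] <- land
      } else {
        lat <- stats::rnorm(1, lat_mu, profile$latency_sd)
        lat <- min(max(lat, 80), dwell * 0.4)
        lat_n <- as.integer(round(lat))
        vp <- main_sequence_vpeak(amp, vgain)
        dur <- 1.875 * amp / vp * 1000 + profile$duration_slope * amp
        dur_n <- as.integer(round(min(max(dur, 12), dwell - lat_n - 50)))
        land <- cur + (tgt - cur) * (1 - profile$undershoot_frac)
        seg[seq_len(lat_n)] <- cur
        tau <- seq_len(dur_n) / dur_n
        seg[lat_n + seq_len(dur_n)] <- cur + (land - cur) * min_jerk(tau)
        fix_n <- dwell - lat_n - dur_n
        if (fix_n > 0L) {
          tfix <- seq_len(fix_n) / 1000 # seconds since landing
          glide <- land + (tgt - land) * (1 - exp(-tfix * 1000 / 60))
          drift_dir <- stats::rnorm(1, 0, profile$drift_rate)
          seg[(lat_n + dur_n + 1L):dwell] <- glide + drift_dir * tfix
        }
      }
      gaze[idx0 + seq_len(dwell)] <- seg
      cur <- gaze[idx0 + dwell]
    }
    gaze <- gaze + stats::rnorm(n, 0, noise_sd)
    gy <- stats::rnorm(n, 0, noise_sd)
    gaze_recording(timestamps = seq_len(n) - 1, gaze_x = gaze, gaze_y = gy,
                   target_x = tx, target_y = ty,
                   subject_id = subject_id, session_id = session_id)
  })
}

#' Inject blink-like missing-data runs
#'
#' Blink counts per stimulus position are Poisson(`blink_rate`); each blink
#' replaces a contiguous run (length uniform in `blink_len_ms`) with `NaN`
#' gaze and `valid = FALSE`, mimicking tracker dropouts.
#'
#' @param rec A [gaze_recording()].
#' @param blink_rate Expected blinks per stimulus position; must be >= 0.
#' @param blink_len_ms Length-2 range of blink durations in ms.
#' @param dwell_ms Stimulus dwell used to define position blocks.
#' @param seed Integer seed.
#' @return A [gaze_recording()] with an updated NaN/validity mask.
#' @export
inject_missing <- function(rec, blink_rate, blink_len_ms = c(50, 150),
                           dwell_ms = 1000, seed = NULL) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (blink_rate < 0) {
    stop_gazeid("blink_rate must be non-negative", "gazeid_validation_error")
  }
  if (blink_rate == 0) {
    return(rec)
  }
  n <- length(rec)
  n_pos <- n %/% dwell_ms
  with_seed(seed, {
    gx <- rec$gaze_x
    gy <- rec$gaze_y
    for (p in seq_len(n_pos)) {
      k <- stats::rpois(1, blink_rate)
      if (k == 0L) next
      for (b in seq_len(k)) {
        len <- as.integer(round(stats::runif(1, blink_len_ms[1],
                                             blink_len_ms[2])))
        start <- (p - 1L) * dwell_ms +
          sample.int(max(dwell_ms - len, 1L), 1L)
        idx <- start:min(start + len - 1L, n)
        gx[idx] <- NaN
        gy[idx] <- NaN
      }
    }
    gaze_recording(timestamps = rec$timestamps, gaze_x = gx, gaze_y = gy,
                   target_x = rec$target_x, target_y = rec$target_y,
                   subject_id = rec$subject_id, session_id = rec$session_id)
  })
}

#' Draw a cohort of distinct subject profiles
#'
#' Profiles are sampled uniformly over physiological ranges: latency mean
#' 150--200 ms, velocity gain 380--560 deg/s, duration slope 0.2--1.0 ms/deg,
#' fixation noise 0.02--0.08 DVA, drift 0.1--0.5 DVA/s, undershoot 2--12%.
#'
#' @param n Number of subjects.
#' @param blink_rate Common expected blink rate per position.
#' @param seed Integer seed.
#' @return List of [subject_profile()] objects named `S1..Sn`.
#' @export
random_profiles <- function(n, blink_rate = 0.05, seed = NULL) {
  with_seed(seed, {
    profs <- lapply(seq_len(n), function(i) {
      subject_profile(latency_mean = stats::runif(1, 150, 200),
                      latency_sd = stats::runif(1, 8, 20),
                      vpeak_scale = stats::runif(1, 380, 560),
                      duration_slope = stats::runif(1, 0.2, 1.0),
                      fixation_noise_sd = stats::runif(1, 0.02, 0.08),
                      drift_rate = stats::runif(1, 0.1, 0.5),
                      undershoot_frac = stats::runif(1, 0.02, 0.12),
                      blink_rate = blink_rate)
    })
    names(profs) <- paste0("S", seq_len(n))
    profs
  })
}

#' Simulate a multi-session cohort
#'
#' One trial per subject per session on a common schedule (every participant
#' sees the same jumping-point sequence, as in the random-saccades task), with
#' per-session aging effects shared across subjects and per-trial blink
#' injection driven by each profile's `blink_rate`.
#'
#' @param profiles List of [subject_profile()] (e.g. [random_profiles()]).
#' @param n_sessions Number of recording sessions.
#' @param schedule A [stimulus_schedule()].
#' @param seed Integer seed controlling session effects, trials and blinks.
#' @return List with elements `recordings` (flat list of [gaze_recording()]),
#'   `profiles`, `effects` and `schedule`.
#' @export
simulate_cohort <- function(profiles, n_sessions, schedule, seed = 1) {
  stopifnot(length(profiles) >= 1, n_sessions >= 1)
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("S", seq_along(profiles))
  effects <- with_seed(seed, {
    lapply(seq_len(n_sessions), function(s) {
      if (s == 1L) {
        session_effect()
      } else {
        session_effect(gain_drift = exp(stats::runif(1, -0.1, 0.1)),
                       latency_shift = stats::runif(1, -10, 10),
                       noise_inflation = exp(stats::runif(1, -0.1, 0.1)))
      }
    })
  })
  recs <- list()
  for (s in seq_len(n_sessions)) {
    for (i in seq_along(profiles)) {
      trial_seed <- (seed * 1009L + s * 131L + i * 7L) %% .Machine$integer.max
      rec <- simulate_trial(profiles[[i]], schedule, effects[[s]],
                            seed = trial_seed, subject_id = ids[i],
                            session_id = as.character(s))
      if (profiles[[i]]$blink_rate > 0) {
        rec <- inject_missing(rec, profiles[[i]]$blink_rate,
                              dwell_ms = schedule$dwell_ms,
                              seed = trial_seed + 1L)
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  list(recordings = recs, profiles = profiles, effects = effects,
       schedule = schedule)
}
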