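# Shared fixtures, built in code at test time.

# Small clean cohort: n subjects x n_sessions sessions on a common schedule,
# no blinks, cached per parameter set so several test files can reuse it.
tiny_cohort <- local({
  cache <- list()
  function(n_subjects = 4, n_sessions = 2, positions = 12, seed = 101) {
    key <- paste(n_subjects, n_sessions, positions, seed, sep = "_")
    if (is.null(cache[[key]])) {
      sched <- generate_schedule(count = positions, seed = seed)
      profs <- random_profiles(n_subjects, blink_rate = 0, seed = seed + 1)
      cache[[key]] <<- c(simulate_cohort(profs, n_sessions, sched,
                                         seed = seed + 2),
                         list(schedule = sched))
    }
    cache[[key]]
  }
})

# A deterministic ramp recording: gaze follows the target instantly, no noise.
ramp_recording <- function(n_positions = 3, dwell = 1000) {
  n <- n_positions * dwell
  tx <- rep(seq_len(n_positions), each = dwell)
  gaze_recording(timestamps = seq_len(n) - 1,
                 gaze_x = seq_len(n) / 1000, gaze_y = rep(0, n),
                 target_x = tx, target_y = rep(0, n))
}

# Well-separated identification cohort: 8 subjects whose velocity gains are
# geometrically spaced 25% apart, 3 sessions, blink-free so all positions
# stay valid; 20 positions are retained downstream.
separated_cohort <- function(seed = 2024) {
  sched <- generate_schedule(count = 24, seed = seed)
  profs <- random_profiles(8, blink_rate = 0, seed = seed + 1)
  for (i in seq_along(profs)) {
    profs[[i]]$vpeak_scale <- 300 * 1.25^(i - 1)
  }
  c(simulate_cohort(profs, 3, sched, seed = seed + 2),
    list(schedule = sched))
}

# Brute-force O(n^2) DFT amplitude spectrum, the independent oracle for
# amplitude_spectrum().
brute_dft_amplitude <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    m <- 0:(n - 1)
    Mod(sum(x * exp(-2i * pi * m * k / n)))
  }, numeric(1))
}

# Cohen's kappa straight from the contingency table definition.
brute_kappa <- function(pred, truth, l) {
  n <- length(pred)
  po <- mean(pred == truth)
  pe <- 0
  for (k in seq_len(l)) {
    pe <- pe + (sum(pred == k) / n) * (sum(truth == k) / n)
  }
  (po - pe) / (1 - pe)
}
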