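#' Point-to-point derivative of a sampled signal
#'
#' Forward difference divided by the sampling interval; applied once, twice
#' and three times to horizontal position it yields velocity (deg/s),
#' acceleration (deg/s^2) and jerk (deg/s^3). A length-`n` input gives a
#' length-`n - 1` output, so a 303-sample window supports series of lengths
#' 302, 301 and 300.
#'
#' @param x Numeric sequence (length >= 2).
#' @param dt Sampling interval in seconds (1000 Hz -> 0.001).
#' @return Numeric vector of length `length(x) - 1`.
#' @export
derivative <- function(x, dt = 0.001) {
  if (length(x) < 2L) {
    stop_gazeid("derivative needs at least 2 samples", "gazeid_validation_error")
  }
  if (!is.finite(dt) || dt <= 0) {
    stop_gazeid("dt must be positive", "gazeid_validation_error")
  }
  diff(x) / dt
}

#' Point-to-point percentage change
#'
#' `out[i] = (s[i+1] - s[i]) / s[i]`, kept as a fraction. Denominators with
#' magnitude below `eps` yield 0: fixation-phase velocities hover around zero
#' and would otherwise blow the ratio up.
#'
#' @param s Numeric sequence (length >= 2).
#' @param eps Denominator guard.
#' @return Numeric vector of length `length(s) - 1`.
#' @export
pct_change <- function(s, eps = 1e-12) {
  if (length(s) < 2L) {
    stop_gazeid("pct_change needs at least 2 samples", "gazeid_validation_error")
  }
  den <- s[-length(s)]
  out <- (s[-1] - den) / den
  out[abs(den) < eps] <- 0
  out
}

#' DFT amplitude spectrum of a segment
#'
#' `A_k = |sum_m a_m exp(-2 pi i m k / n)|` for k = 0..n-1, computed with the
#' FFT. All `n = 100` bins are kept as a 100-element frequency-domain channel
#' (for real input the upper half mirrors the lower, which simply duplicates
#' energy across the channel).
#'
#' @param seg Numeric vector of length 100 (one segment of velocity).
#' @param n Required segment length.
#' @return Numeric vector of length `n`: moduli of the DFT coefficients.
#' @export
amplitude_spectrum <- function(seg, n = 100) {
  if (length(seg) != n) {
    stop_gazeid(sprintf("amplitude_spectrum expects length %d, got %d",
                        n, length(seg)),
                "gazeid_validation_error")
  }
  Mod(stats::fft(seg))
}

#' Min-max scaling with reference extrema
#'
#' `(s - lo) / (hi - lo)`, clipped to \[0, 1\]. Values outside the reference
#' range (e.g. test data scaled with training extrema) are clipped; a
#' degenerate `hi == lo` channel maps to all zeros.
#'
#' @param s Numeric vector.
#' @param lo,hi Reference minimum and maximum (`hi >= lo`).
#' @return Scaled vector in \[0, 1\].
#' @export
minmax_scale <- function(s, lo = min(s), hi = max(s)) {
  if (hi < lo) {
    stop_gazeid("minmax_scale requires hi >= lo", "gazeid_validation_error")
  }
  if (hi == lo) {
    return(rep(0, length(s)))
  }
  pmin(pmax((s - lo) / (hi - lo), 0), 1)
}

# Channel names of the time-series feature vector, in layout order.
TS_CHANNELS <- c("v", "a", "j", "vc", "ac", "jc", "Ft")

# Channels that feed the statistical feature vector.
STAT_CHANNELS <- c("v", "a", "j", "Ft")

# Pad a length n-1 series back to n by repeating its final value, so all
# channels of a segment share the 100-element layout.
pad_last <- function(s, n) c(s, rep(s[length(s)], n - length(s)))

#' Build the seven time-series channels of each segment
#'
#' From a 303-sample window: velocity, acceleration and jerk are the first
#' three point-to-point derivatives of horizontal position, each truncated to
#' its last 300 elements so all three cover the same raw samples as jerk;
#' that common support is split into the bundle's segments. Per segment the
#' channels are the segment's `v`, `a`, `j`, their percentage changes
#' (padded by repeating the final value to stay 100-element), and the
#' amplitude spectrum `Ft` of the segment's unscaled velocity. When `scalers`
#' is supplied each channel is min-max scaled with the reference extrema
#' (fitted on training data via [fit_scalers()]).
#'
#' @param window A [extract_window()] result.
#' @param bundle A [split_segments()] result for that window.
#' @param scalers Optional list of `c(lo, hi)` per channel, or `NULL` for
#'   unscaled output.
#' @param dt Sampling interval in seconds.
#' @return List of `g` matrices, each `segment_len x 7` with columns
#'   `v, a, j, vc, ac, jc, Ft`.
#' @export
build_ts_features <- function(window, bundle, scalers = NULL, dt = 0.001) {
  stopifnot(inherits(window, "position_window"),
            inherits(bundle, "segment_bundle"))
  x <- window$raw_x
  v_full <- derivative(x, dt) # 302
  a_full <- derivative(v_full, dt) # 301
  j_full <- derivative(a_full, dt) # 300
  support <- length(j_full)
  v <- v_full[(length(v_full) - support + 1L):length(v_full)]
  a <- a_full[(length(a_full) - support + 1L):length(a_full)]
  j <- j_full
  n <- bundle$segment_len
  out <- lapply(bundle$segments, function(idx) {
    vs <- v[idx]; as <- a[idx]; js <- j[idx]
    m <- cbind(v = vs, a = as, j = js,
               vc = pad_last(pct_change(vs), n),
               ac = pad_last(pct_change(as), n),
               jc = pad_last(pct_change(js), n),
               Ft = amplitude_spectrum(vs, n))
    if (!is.null(scalers)) {
      for (ch in TS_CHANNELS) {
        m[, ch] <- minmax_scale(m[, ch], scalers[[ch]][1], scalers[[ch]][2])
      }
    }
    m
  })
  out
}

#' Statistical feature vector of one segment
#'
#' Sixteen values: `(min, max, mean, std)` of each of the `v`, `a`, `j` and
#' `Ft` channels, in that fixed order. `std` is the population standard
#' deviation (divide by N).
#'
#' @param ts A `segment_len x 7` channel matrix from [build_ts_features()].
#' @return Named numeric vector of length 16.
#' @export
build_stat_features <- function(ts) {
  stopifnot(is.matrix(ts), all(STAT_CHANNELS %in% colnames(ts)))
  out <- unlist(lapply(STAT_CHANNELS, function(ch) {
    s <- ts[, ch]
    c(min(s), max(s), mean(s), sqrt(mean((s - mean(s))^2)))
  }))
  names(out) <- as.vector(t(outer(STAT_CHANNELS, c("min", "max", "mean", "std"),
                                  paste, sep = "_")))
  out
}

#' Fit per-channel min-max scalers
#'
#' @param ts_array Array `[samples, time, channels]` of unscaled features.
#' @param sample_idx Rows to fit on (the training split).
#' @return Named list of `c(lo, hi)` per channel.
#' @export
fit_scalers <- function(ts_array, sample_idx = seq_len(dim(ts_array)[1])) {
  channels <- dimnames(ts_array)[[3]]
  scalers <- lapply(seq_along(channels), function(k) {
    vals <- ts_array[sample_idx, , k]
    c(min(vals), max(vals))
  })
  names(scalers) <- channels
  scalers
}

# Apply fitted scalers to an [N, time, channels] array.
apply_scalers <- function(ts_array, scalers) {
  channels <- dimnames(ts_array)[[3]]
  for (k in seq_along(channels)) {
    ts_array[, , k] <- minmax_scale(ts_array[, , k],
                                    scalers[[channels[k]]][1],
                                    scalers[[channels[k]]][2])
  }
  ts_array
}

#' Build the labelled feature dataset of a cohort
#'
#' Runs filter/select/extract/split/feature over every trial: positions with
#' missing samples are dropped, the first `x_count` positions valid in every
#' trial are retained, and each retained position contributes `g` segments of
#' unscaled channels. Scaling is deferred to evaluation time so that scaler
#' extrema can be fitted on the training sessions only.
#'
#' @param recordings List of [gaze_recording()] (one per subject x session).
#' @param schedule The common [stimulus_schedule()].
#' @param x_count Stimulus positions to retain per trial.
#' @param g,segment_len Segmentation parameters.
#' @param window_len Event window length in samples.
#' @return An object of class `gaze_features`: list with `ts` (array
#'   `[N, segment_len, 7]`, unscaled) and `meta` (data.frame with columns
#'   `subject`, `session`, `position`, `segment`).
#' @export
build_feature_dataset <- function(recordings, schedule, x_count = 50,
                                  g = 3, segment_len = 100, window_len = 303) {
  stopifnot(length(recordings) >= 1)
  valid_sets <- lapply(recordings, filter_valid_positions, schedule = schedule)
  keep <- select_common_positions(valid_sets, x_count)
  n_total <- length(recordings) * x_count * g
  ts <- array(NA_real_, dim = c(n_total, segment_len, length(TS_CHANNELS)),
              dimnames = list(NULL, NULL, TS_CHANNELS))
  meta <- data.frame(subject = character(n_total), session = character(n_total),
                     position = integer(n_total), segment = integer(n_total),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (rec in recordings) {
    for (p in keep) {
      w <- extract_window(rec, p, schedule, window_len = window_len)
      b <- split_segments(w, g = g, segment_len = segment_len)
      feats <- build_ts_features(w, b)
      for (s in seq_len(g)) {
        row <- row + 1L
        ts[row, , ] <- feats[[s]]
        meta$subject[row] <- rec$subject_id
        meta$session[row] <- rec$session_id
        meta$position[row] <- p
        meta$segment[row] <- s
      }
    }
  }
  structure(list(ts = ts, meta = meta, positions = keep, g = g,
                 segment_len = segment_len, x_count = x_count),
            class = "gaze_features")
}

#' @export
print.gaze_features <- function(x, ...) {
  cat(sprintf("<gaze_features> %d samples (%d subjects x %d sessions x %d positions x %d segments)\n",
              dim(x$ts)[1], length(unique(x$meta$subject)),
              length(unique(x$meta$session)), x$x_count, x$g))
  invisible(x)
}

# Stats matrix [N, 16] from a scaled ts array.
stat_matrix <- function(ts_array) {
  n <- dim(ts_array)[1]
  out <- t(vapply(seq_len(n), function(i) {
    m <- ts_array[i, , ]
    colnames(m) <- dimnames(ts_array)[[3]]
    build_stat_features(m)
  }, numeric(16)))
  out
}
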