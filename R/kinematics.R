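#' Angular acceleration from angular velocity
#'
#' Differentiates each gyroscope channel with central differences at
#' interior samples and one-sided differences at the ends. Run on the
#' raw stream, before any segmentation or time-scaling, so the
#' acceleration range still reflects how many cycles a subject packed
#' into the fixed task window.
#'
#' @param gyro A data frame / tibble of gyroscope channels (deg/s), or a
#'   single numeric vector.
#' @param rate Sampling rate in Hz.
#' @return Same shape as the input, in deg/s^2.
#' @export
derive_angular_acceleration <- function(gyro, rate) {
  if (is.numeric(gyro) && is.null(dim(gyro))) {
    return(diff_central(gyro, rate))
  }
  out <- tibble::as_tibble(lapply(gyro, diff_central, rate = rate))
  names(out) <- sub("^gyro", "angacc", names(gyro))
  out
}

diff_central <- function(v, rate) {
  n <- length(v)
  assert_that(n >= 3, "need at least 3 samples to differentiate",
              class = "trunkstrat_insufficient_data")
  dt <- 1 / rate
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Zero-phase low-pass filter for the flexion/extension gyro axis
#'
#' 4th-order Butterworth low-pass (default cutoff 1 Hz) applied
#' forward-backward ([signal::filtfilt()]), so the filtered signal has
#' no phase lag and its zero crossings keep the timing of the raw
#' movement — which cycle detection depends on. Isolates the slow
#' flexion/extension component from noise and faster content.
#'
#' @param x Numeric series (gyro X, deg/s).
#' @param rate Sampling rate, Hz.
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist
#'   rate.
#' @param order Filter order.
#' @return Filtered series, same length.
#' @export
lowpass_gyro_x <- function(x, rate, cutoff_hz = 1, order = 4) {
  assert_that(rate > 2 * cutoff_hz,
              "cutoff must be below the Nyquist frequency (rate / 2)",
              class = "trunkstrat_invalid_parameter")
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  # Odd-symmetric reflection padding suppresses the start/end
  # transients of the forward-backward pass, so crossings near the
  # edges of the trial keep their timing.
  n <- length(x)
  pad <- min(n - 1, 3 * ceiling(rate / cutoff_hz))
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(pad + 1):(pad + n)]
}

#' Detect flexion/extension cycle starts
#'
#' A cycle starts where the (filtered) flexion/extension angular
#' velocity crosses from negative to non-negative: sample `i` is a
#' start when `x[i-1] < 0` and `x[i] >= 0` (an exact zero counts as
#' positive, a deterministic tie-break).
#'
#' @param x Numeric series, typically [lowpass_gyro_x()] output.
#' @return Integer vector of start indices (possibly empty), strictly
#'   increasing.
#' @export
detect_cycle_starts <- function(x) {
  assert_that(length(x) >= 2, "need at least 2 samples",
              class = "trunkstrat_insufficient_data")
  which(x[-1] >= 0 & head(x, -1) < 0) + 1L
}

#' Segment all channels at shared cycle boundaries and time-scale
#'
#' Slices every channel at the same start indices (cycles are the spans
#' between consecutive starts, endpoints shared; partial movement
#' before the first and after the last start is discarded) and
#' linearly resamples each cycle to exactly 101 points over a uniform
#' normalized-time grid. Because the boundaries come from one channel
#' (the filtered gyro X) and are applied to all, the per-channel cycle
#' stacks stay synchronized.
#'
#' @param channels Data frame / tibble of the 9 kinematic channels
#'   (gyro X/Y/Z, accel X/Y/Z, angular-accel X/Y/Z), one row per
#'   sample. A `time` column, if present, is ignored.
#' @param starts Cycle start indices from [detect_cycle_starts()].
#' @param n_points Points per time-scaled cycle.
#' @return A `cycle_stack_set`: named list (per channel) of
#'   `n_cycles x n_points` matrices, with attributes `n_cycles` and
#'   `starts`.
#' @export
segment_and_scale <- function(channels, starts, n_points = 101) {
  channels <- channels[, setdiff(names(channels), "time"), drop = FALSE]
  assert_that(length(starts) >= 2,
              "fewer than 2 cycle starts: no complete cycle detected",
              class = "trunkstrat_no_cycle")
  n <- nrow(channels)
  assert_that(all(starts >= 1 & starts <= n) && !is.unsorted(starts),
              "starts must be increasing indices into the channels",
              class = "trunkstrat_invalid_parameter")
  n_cycles <- length(starts) - 1L
  grid <- seq(0, 1, length.out = n_points)
  stacks <- lapply(channels, function(v) {
    out <- matrix(NA_real_, n_cycles, n_points)
    for (j in seq_len(n_cycles)) {
      seg <- v[starts[j]:starts[j + 1]]
      out[j, ] <- approx(x = seq(0, 1, length.out = length(seg)),
                         y = seg, xout = grid)$y
    }
    out
  })
  structure(stacks, n_cycles = n_cycles, starts = starts,
            class = "cycle_stack_set")
}

#' RMS-aggregate a cycle stack into one movement profile
#'
#' Collapses all of a subject's time-scaled cycles into a single
#' representative cycle: at each normalized time point, the root mean
#' square across cycles. The first of the 101 points is excluded —
#' every segment starts at the same boundary sample, so it carries no
#' information — leaving a 100-point profile. RMS discards sign, so
#' profiles are non-negative.
#'
#' @param stack An `n_cycles x 101` matrix (one channel of
#'   [segment_and_scale()] output).
#' @return Numeric vector of 100 non-negative values.
#' @export
aggregate_cycles <- function(stack) {
  assert_that(is.matrix(stack) && nrow(stack) >= 1,
              "empty cycle stack", class = "trunkstrat_no_cycle")
  sqrt(colMeans(stack[, -1, drop = FALSE]^2))
}

#' Concatenate the nine aggregated profiles into the full-signal vector
#'
#' Fixed layout: gyro X,Y,Z; accel X,Y,Z; angular-accel X,Y,Z — 100
#' points each, 900 values total. Returns a named vector
#' (`fs_<channel>_<point>`) so any position maps back to its channel
#' and normalized time point.
#'
#' @param profiles Named list of nine 100-point profiles (names as in
#'   the canonical layout).
#' @return Named numeric vector of length 900.
#' @export
build_full_signal <- function(profiles) {
  missing <- setdiff(CHANNELS_ALL, names(profiles))
  assert_that(length(missing) == 0,
              sprintf("missing channel(s): %s",
                      paste(missing, collapse = ", ")),
              class = "trunkstrat_assembly_error")
  bad <- names(which(vapply(profiles[CHANNELS_ALL], length,
                            integer(1)) != 100))
  assert_that(length(bad) == 0,
              sprintf("profile '%s' does not have 100 points", bad[1]),
              class = "trunkstrat_assembly_error")
  vals <- unlist(profiles[CHANNELS_ALL], use.names = FALSE)
  names(vals) <- as.vector(vapply(
    CHANNELS_ALL, function(ch) sprintf("fs_%s_%03d", ch, 1:100),
    character(100)))
  vals
}

#' Run the full preprocessing chain on one recording
#'
#' Derives angular acceleration from the raw gyro stream, low-pass
#' filters the gyro X axis to find cycle starts, segments all nine
#' channels at those boundaries, time-scales each cycle to 101 points,
#' RMS-aggregates to 100-point profiles, and concatenates into the
#' 900-value full-signal vector. Segmentation slices the unfiltered
#' channels; the filtered signal is used only to locate starts.
#'
#' @param rec A `trunk_recording`.
#' @param cutoff_hz Low-pass cutoff for cycle detection, Hz.
#' @return List of class `trunk_profiles`: `subject_id`, `n_cycles`,
#'   `starts`, `profiles` (named list of nine 100-point vectors) and
#'   `full_signal` (named length-900 vector).
#' @export
preprocess_recording <- function(rec, cutoff_hz = 1) {
  validate_recording(rec)
  angacc <- derive_angular_acceleration(
    rec$imu[, c("gyro_x", "gyro_y", "gyro_z")], rec$imu_rate)
  channels <- dplyr::bind_cols(rec$imu[, CHANNELS_IMU], angacc)
  filtered <- lowpass_gyro_x(rec$imu$gyro_x, rec$imu_rate, cutoff_hz)
  starts <- detect_cycle_starts(filtered)
  stacks <- segment_and_scale(channels, starts)
  profiles <- lapply(stacks, aggregate_cycles)
  list_out <- list(subject_id = rec$subject_id,
                   n_cycles = attr(stacks, "n_cycles"),
                   starts = starts,
                   profiles = profiles,
                   full_signal = build_full_signal(profiles))
  structure(list_out, class = "trunk_profiles")
}

#' Aggregated movement profiles as a tidy tibble
#'
#' @param x A `trunk_profiles` object.
#' @param ... Unused.
#' @return Tibble with columns `subject_id`, `channel`, `point`
#'   (normalized time index 1-100) and `value`.
#' @export
#' @method tidy trunk_profiles
tidy.trunk_profiles <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    channel = rep(CHANNELS_ALL, each = 100),
    point = rep(1:100, times = length(CHANNELS_ALL)),
    value = unlist(x$profiles[CHANNELS_ALL], use.names = FALSE)
  )
}

#' Plot a subject's aggregated movement profiles
#'
#' One panel per channel, normalized cycle time on the x axis.
#'
#' @param object A `trunk_profiles` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot trunk_profiles
autoplot.trunk_profiles <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "normalized cycle time (points)",
                  y = "RMS-aggregated amplitude",
                  title = sprintf("Subject %s (%d cycles)",
                                  object$subject_id, object$n_cycles)) +
    ggplot2::theme_minimal()
}
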