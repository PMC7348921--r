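test_that("angular acceleration matches analytic derivatives", {
  rate <- 20
  t <- seq(0, 10, by = 1 / rate)
  # constant velocity -> zero acceleration
  expect_equal(derive_angular_acceleration(rep(3, 50), rate),
               rep(0, 50))
  # linear ramp v = 10 t -> exactly 10 everywhere (central and
  # one-sided differences are both exact for degree-1 polynomials)
  ramp <- derive_angular_acceleration(10 * t, rate)
  expect_equal(ramp, rep(10, length(t)), tolerance = 1e-10)
  # sinusoid: O(dt^2) error at interior points
  v <- sin(2 * pi * 0.5 * t)
  a <- derive_angular_acceleration(v, rate)
  truth <- 2 * pi * 0.5 * cos(2 * pi * 0.5 * t)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(a[interior] - truth[interior])),
            (2 * pi * 0.5)^3 * (1 / rate)^2 / 6 * 1.01)
  expect_error(derive_angular_acceleration(c(1, 2), rate),
               class = "trunkstrat_insufficient_data")
})

test_that("the 1 Hz low-pass keeps slow movement and rejects fast content", {
  rate <- 20
  t <- seq(0, 14, by = 1 / rate)
  slow <- sin(2 * pi * 0.5 * t)
  fast <- sin(2 * pi * 5 * t)
  # amplitude measured away from the filtfilt edges
  core <- seq(2 * rate, length(t) - 2 * rate)
  expect_gte(max(abs(lowpass_gyro_x(slow, rate)[core])), 0.95)
  expect_lte(max(abs(lowpass_gyro_x(fast, rate)[core])), 0.1)
  expect_equal(lowpass_gyro_x(rep(2.5, 200), rate), rep(2.5, 200),
               tolerance = 1e-4)
  expect_error(lowpass_gyro_x(slow, rate, cutoff_hz = 10),
               class = "trunkstrat_invalid_parameter")
})

test_that("cycle starts are negative-to-positive crossings", {
  rate <- 20
  t <- seq(0, 14 - 1 / rate, by = 1 / rate)
  x <- sin(pi * t)
  starts <- detect_cycle_starts(x)
  # oracle: scan every adjacent pair
  oracle <- integer(0)
  for (i in 2:length(x)) {
    if (x[i - 1] < 0 && x[i] >= 0) oracle <- c(oracle, i)
  }
  expect_identical(starts, oracle)
  # boundary samples sit within one sample of the analytic crossings
  # (sin(pi * t) at integer t is zero only up to floating error)
  expect_equal(length(starts), 6)
  expect_lte(max(abs(t[starts] - c(2, 4, 6, 8, 10, 12))),
             1 / rate + 1e-12)

  expect_identical(detect_cycle_starts(abs(x) + 1), integer(0))
  expect_identical(detect_cycle_starts(c(-1, 1)), 2L)
  # exact zero counts as positive
  expect_identical(detect_cycle_starts(c(-1, 0, 1)), 2L)
})

test_that("segmentation shares boundaries across channels and rescales to 101", {
  # two cycles of different raw lengths: starts 1, 41, 91
  n <- 120
  chans <- tibble::tibble(a = seq_len(n) / n, b = sin(seq_len(n)))
  stacks <- segment_and_scale(chans, starts = c(1L, 41L, 91L))
  expect_equal(attr(stacks, "n_cycles"), 2)
  expect_equal(dim(stacks$a), c(2, 101))
  expect_equal(dim(stacks$b), c(2, 101))

  # linear interpolation preserves linear segments exactly
  ramp <- tibble::tibble(r = seq(0, 1, length.out = 41))
  st <- segment_and_scale(ramp, starts = c(1L, 41L))
  expect_equal(st$r[1, ], seq(0, 1, length.out = 101))

  # trailing partials are discarded: samples beyond the last start
  # never influence the stack
  chans2 <- chans
  chans2$a[92:120] <- 99
  stacks2 <- segment_and_scale(chans2, starts = c(1L, 41L, 91L))
  expect_equal(stacks2$a, stacks$a)

  expect_error(segment_and_scale(chans, starts = 5L),
               class = "trunkstrat_no_cycle")
})

test_that("RMS aggregation drops the shared first point and discards sign", {
  # two cycles, constant 3 and 4 -> sqrt((9 + 16) / 2) at every point
  st <- rbind(rep(3, 101), rep(4, 101))
  expect_equal(aggregate_cycles(st), rep(sqrt(12.5), 100))
  # values -2 and 2 -> 2
  st2 <- rbind(rep(-2, 101), rep(2, 101))
  expect_equal(aggregate_cycles(st2), rep(2, 100))
  # single cycle -> elementwise absolute value (first point dropped)
  v <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(aggregate_cycles(matrix(v, 1)), abs(v[-1]))
  expect_error(aggregate_cycles(matrix(numeric(0), 0, 101)),
               class = "trunkstrat_no_cycle")
})

test_that("vectorized aggregation equals the naive loop on random stacks", {
  for (case in 1:50) {
    st <- rand_stack(n_cycles = sample(1:10, 1), seed = case)
    agg <- aggregate_cycles(st)
    expect_equal(agg, naive_rms_aggregate(st), tolerance = 1e-12)
    expect_length(agg, 100)
    expect_true(all(agg >= 0))
  }
})

test_that("the full-signal vector has the fixed 900-value layout", {
  channels <- c("gyro_x", "gyro_y", "gyro_z",
                "accel_x", "accel_y", "accel_z",
                "angacc_x", "angacc_y", "angacc_z")
  profiles <- stats::setNames(
    lapply(seq_along(channels), function(i) rep(i, 100)), channels)
  fs <- build_full_signal(profiles)
  expect_length(fs, 900)
  # layout arithmetic: position (c-1)*100 + p belongs to channel c,
  # point p; e.g. position 350 is accel_x, point 50
  expect_equal(names(fs)[350], "fs_accel_x_050")
  expect_equal(unname(fs[350]), 4)
  expect_equal(unname(fs[1:100]), rep(1, 100))

  expect_error(build_full_signal(profiles[-3]),
               class = "trunkstrat_assembly_error")
  short <- profiles
  short$gyro_x <- short$gyro_x[-1]
  expect_error(build_full_signal(short),
               class = "trunkstrat_assembly_error")
})

test_that("preprocessing keeps channel boundaries synchronized end-to-end", {
  subj <- generate_subject(noise_free_params(period = 2), seed = 6)
  prep <- preprocess_recording(subj$recording)
  expect_length(prep$full_signal, 900)
  expect_true(all(vapply(prep$profiles, length, integer(1)) == 100))
  expect_true(all(unlist(prep$profiles) >= 0))
  # boundaries come from one detection pass, shared by construction;
  # the aggregated gyro-X profile of a noise-free subject peaks twice
  # (flexion and extension half-cycles fold onto the RMS profile)
  spec_peak <- which.max(abs(fft(prep$profiles$gyro_x -
                                   mean(prep$profiles$gyro_x))[2:50]))
  expect_equal(spec_peak, 2)
})
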