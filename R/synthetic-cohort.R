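#' Simulation parameters for one synthetic subject
#'
#' Defines the kinematic and psychometric model of a simulated NSLBP
#' (nonspecific low back pain) subject performing the timed trunk
#' flexion/extension task. The trunk angle is modelled per cycle as a
#' raised cosine rising to `rom_amplitude` degrees and returning to
#' upright; the gyroscope flexion/extension axis carries its analytic
#' derivative scaled by `velocity_scale`, and the accelerometer channels
#' combine the gravity projection of the instantaneous sagittal angle
#' with a lever-arm motion term plus white noise. The anteroposterior
#' centre of pressure follows the trunk angle with gain `cop_gain`.
#'
#' @param risk_class One of `"low"`, `"medium"`, `"high"` (SBST risk group).
#' @param cycle_period_mean Mean duration of one flexion/extension cycle,
#'   seconds (> 0).
#' @param cycle_period_cv Within-subject coefficient of variation of the
#'   cycle period (>= 0); periods are drawn lognormally so they stay
#'   positive.
#' @param rom_amplitude Peak trunk flexion, degrees (0, 120].
#' @param velocity_scale Dimensionless multiplier on the angular-velocity
#'   amplitude (captures slower/faster movement execution at a given range
#'   of motion).
#' @param imu_noise_sd Additive white-noise SD on the gyroscope channels,
#'   deg/s. Accelerometer noise uses `imu_noise_sd / 25` m/s^2 so both
#'   stay proportional to one dial.
#' @param cop_gain Anteroposterior COP excursion per degree of trunk
#'   flexion, cm/deg.
#' @param cop_noise_sd Additive white-noise SD on the COP axes, cm.
#' @param psych_means Length-3 numeric: expected HADS-anxiety,
#'   HADS-depression (each 0-21) and TSK (17-68) scores.
#' @param psych_sds Length-3 numeric SDs for the questionnaire draws.
#' @param between_subject_cv Coefficient of variation applied by
#'   [generate_cohort()] when instantiating individual subjects from a
#'   group profile (jitters period, range of motion and velocity scale
#'   across subjects so groups overlap realistically).
#' @param task_duration Task length in seconds (the protocol uses 14 s).
#'
#' @return An object of class `subject_sim_params` (a validated list).
#' @seealso [generate_subject()], [generate_cohort()], [cohort_config()]
#' @export
subject_sim_params <- function(risk_class = "low",
                               cycle_period_mean = 2,
                               cycle_period_cv = 0.1,
                               rom_amplitude = 50,
                               velocity_scale = 1,
                               imu_noise_sd = 8,
                               cop_gain = 0.06,
                               cop_noise_sd = 0.3,
                               psych_means = c(6, 5, 32),
                               psych_sds = c(3, 3, 6),
                               between_subject_cv = 0.22,
                               task_duration = 14) {
  risk_class <- match.arg(risk_class, RISK_LEVELS)
  assert_that(is.numeric(cycle_period_mean) && cycle_period_mean > 0,
              "`cycle_period_mean` must be a positive number of seconds",
              class = "trunkstrat_invalid_parameter")
  assert_that(is.numeric(task_duration) && task_duration > 0,
              "`task_duration` must be a positive number of seconds",
              class = "trunkstrat_invalid_parameter")
  assert_that(cycle_period_cv >= 0, "`cycle_period_cv` must be >= 0",
              class = "trunkstrat_invalid_parameter")
  assert_that(rom_amplitude > 0 && rom_amplitude <= 120,
              "`rom_amplitude` must lie in (0, 120] degrees",
              class = "trunkstrat_invalid_parameter")
  assert_that(velocity_scale > 0, "`velocity_scale` must be > 0",
              class = "trunkstrat_invalid_parameter")
  assert_that(imu_noise_sd >= 0 && cop_noise_sd >= 0,
              "noise scales must be >= 0",
              class = "trunkstrat_invalid_parameter")
  assert_that(between_subject_cv >= 0, "`between_subject_cv` must be >= 0",
              class = "trunkstrat_invalid_parameter")
  assert_that(length(psych_means) == 3 && length(psych_sds) == 3,
              "`psych_means` and `psych_sds` must have length 3",
              class = "trunkstrat_invalid_parameter")
  assert_that(psych_means[1] >= 0 && psych_means[1] <= 21 &&
                psych_means[2] >= 0 && psych_means[2] <= 21,
              "HADS subscale means must lie in [0, 21]",
              class = "trunkstrat_invalid_parameter")
  assert_that(psych_means[3] >= 17 && psych_means[3] <= 68,
              "TSK mean must lie in [17, 68]",
              class = "trunkstrat_invalid_parameter")
  structure(
    list(risk_class = risk_class,
         cycle_period_mean = cycle_period_mean,
         cycle_period_cv = cycle_period_cv,
         rom_amplitude = rom_amplitude,
         velocity_scale = velocity_scale,
         imu_noise_sd = imu_noise_sd,
         cop_gain = cop_gain,
         cop_noise_sd = cop_noise_sd,
         psych_means = as.numeric(psych_means),
         psych_sds = as.numeric(psych_sds),
         between_subject_cv = between_subject_cv,
         task_duration = task_duration),
    class = "subject_sim_params"
  )
}

#' Default per-risk-group simulation profiles
#'
#' High-risk subjects move more slowly (longer cycle period), with a
#' smaller range of motion and a lower velocity scale, and score higher
#' on HADS and TSK; low-risk subjects are the opposite extreme and the
#' medium group sits between, closer to low. Group separation relative
#' to the between-subject spread is moderate by design: the groups
#' overlap, so downstream classifiers operate in a realistic
#' imperfect-accuracy regime rather than a separable toy one.
#'
#' @return Named list of [subject_sim_params()] for `low`, `medium`, `high`.
#' @export
default_group_profiles <- function() {
  list(
    low = subject_sim_params(
      risk_class = "low", cycle_period_mean = 1.7, cycle_period_cv = 0.08,
      rom_amplitude = 55, velocity_scale = 1.0,
      psych_means = c(5, 4, 30)),
    medium = subject_sim_params(
      risk_class = "medium", cycle_period_mean = 1.9, cycle_period_cv = 0.10,
      rom_amplitude = 50, velocity_scale = 0.92,
      psych_means = c(8, 7, 38)),
    high = subject_sim_params(
      risk_class = "high", cycle_period_mean = 2.3, cycle_period_cv = 0.14,
      rom_amplitude = 42, velocity_scale = 0.78,
      psych_means = c(12, 10, 46))
  )
}

#' Cohort-level simulation configuration
#'
#' @param group_sizes Named integer vector of subject counts per risk
#'   class. The default 29/37/28 (low/medium/high) mirrors the study
#'   cohort of 94 male NSLBP patients.
#' @param profiles Named list of [subject_sim_params()], one per class.
#' @param seed Integer master seed; all per-subject seeds derive from it.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(low = 29, medium = 37, high = 28),
                          profiles = default_group_profiles(),
                          seed = 1L) {
  assert_that(all(RISK_LEVELS %in% names(group_sizes)),
              "`group_sizes` must name counts for low, medium and high",
              class = "trunkstrat_config_error")
  assert_that(all(group_sizes[RISK_LEVELS] >= 1),
              "all group sizes must be >= 1",
              class = "trunkstrat_config_error")
  assert_that(all(RISK_LEVELS %in% names(profiles)),
              "`profiles` must contain low, medium and high entries",
              class = "trunkstrat_config_error")
  for (cls in RISK_LEVELS) {
    assert_that(inherits(profiles[[cls]], "subject_sim_params"),
                sprintf("profile for class '%s' is not subject_sim_params", cls),
                class = "trunkstrat_config_error")
  }
  assert_that(is_count(seed), "`seed` must be a single integer",
              class = "trunkstrat_config_error")
  structure(
    list(group_sizes = group_sizes[RISK_LEVELS],
         profiles = profiles[RISK_LEVELS],
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Piecewise raised-cosine trunk-angle model evaluated at times `t`.
# Returns angle (deg), angular velocity (deg/s) and angular acceleration
# (deg/s^2), all analytic. `periods` are the per-cycle durations; times
# beyond the last cycle hold the upright posture.
trunk_angle_model <- function(t, periods, rom_amplitude, velocity_scale) {
  bounds <- c(0, cumsum(periods))
  idx <- findInterval(t, bounds, rightmost.closed = FALSE)
  idx[idx > length(periods)] <- NA_integer_
  angle <- numeric(length(t))
  vel <- numeric(length(t))
  acc <- numeric(length(t))
  ok <- !is.na(idx)
  p <- periods[idx[ok]]
  u <- (t[ok] - bounds[idx[ok]]) / p
  w <- 2 * pi / p
  phase <- 2 * pi * u
  angle[ok] <- rom_amplitude / 2 * (1 - cos(phase))
  vel[ok] <- velocity_scale * rom_amplitude / 2 * w * sin(phase)
  acc[ok] <- velocity_scale * rom_amplitude / 2 * w^2 * cos(phase)
  list(angle = angle, velocity = vel, acceleration = acc)
}

#' Simulate one subject's sensor recording and metadata
#'
#' Generates a synchronized 6-channel IMU stream (20 Hz) and 2-axis COP
#' trajectory (40 Hz) for the 14-s trunk flexion/extension task, plus
#' questionnaire scores and demographics drawn around the profile means.
#' Cycle periods are drawn lognormally with the configured
#' within-subject CV; gyroscope samples are clipped to the sensor
#' full-scale of +/-2000 deg/s. The generator is a pure function of
#' `(params, seed)`.
#'
#' @param params A [subject_sim_params()] object.
#' @param seed Integer seed for this subject.
#' @param subject_id Identifier stored in the recording and metadata.
#'
#' @return A list with elements `recording` (class `trunk_recording`,
#'   see [new_recording()]) and `meta` (one-row tibble of class
#'   `subject_meta` columns: subject_id, sbst_label, hads_a, hads_d,
#'   tsk, age, height, weight).
#' @examples
#' subj <- generate_subject(subject_sim_params(cycle_period_cv = 0,
#'                                             imu_noise_sd = 0), seed = 1)
#' nrow(subj$recording$imu) # 20 Hz x 14 s = 280 samples
#' @export
generate_subject <- function(params, seed, subject_id = "S001") {
  assert_that(inherits(params, "subject_sim_params"),
              "`params` must be built with subject_sim_params()",
              class = "trunkstrat_invalid_parameter")
  assert_that(is_count(seed), "`seed` must be a single integer",
              class = "trunkstrat_invalid_parameter")
  dur <- params$task_duration
  imu_rate <- 20
  cop_rate <- 40

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # Per-cycle periods: lognormal with the requested mean and CV.
  n_guess <- ceiling(dur / params$cycle_period_mean) + 10
  if (params$cycle_period_cv > 0) {
    sdlog <- sqrt(log(1 + params$cycle_period_cv^2))
    meanlog <- log(params$cycle_period_mean) - sdlog^2 / 2
    periods <- stats::rlnorm(n_guess, meanlog, sdlog)
  } else {
    periods <- rep(params$cycle_period_mean, n_guess)
  }
  keep <- which(cumsum(periods) >= dur)[1]
  periods <- periods[seq_len(if (is.na(keep)) n_guess else keep)]

  t_imu <- seq(0, by = 1 / imu_rate, length.out = round(imu_rate * dur))
  t_cop <- seq(0, by = 1 / cop_rate, length.out = round(cop_rate * dur))
  k_imu <- trunk_angle_model(t_imu, periods, params$rom_amplitude,
                             params$velocity_scale)
  k_cop <- trunk_angle_model(t_cop, periods, params$rom_amplitude,
                             params$velocity_scale)

  noise <- function(n, s) if (s > 0) rnorm(n, 0, s) else numeric(n)
  n_imu <- length(t_imu)

  gyro_x <- k_imu$velocity + noise(n_imu, params$imu_noise_sd)
  # Small deterministic cross-talk onto the off-axis gyro channels keeps
  # them correlated with the movement, as a chest-worn sensor's are.
  gyro_y <- 0.15 * k_imu$velocity + noise(n_imu, params$imu_noise_sd)
  gyro_z <- 0.10 * k_imu$velocity + noise(n_imu, params$imu_noise_sd)

  g <- 9.81
  lever <- 0.45 # m, sternum height above the lumbar pivot
  theta <- k_imu$angle * pi / 180
  omega <- k_imu$velocity * pi / 180
  alpha <- k_imu$acceleration * pi / 180
  accel_noise_sd <- params$imu_noise_sd / 25
  accel_x <- g * cos(theta) - lever * omega^2 + noise(n_imu, accel_noise_sd)
  accel_y <- noise(n_imu, accel_noise_sd)
  accel_z <- g * sin(theta) + lever * alpha + noise(n_imu, accel_noise_sd)

  clip <- function(x) pmin(pmax(x, -GYRO_FULL_SCALE), GYRO_FULL_SCALE)
  imu <- tibble::tibble(
    time = t_imu,
    gyro_x = clip(gyro_x), gyro_y = clip(gyro_y), gyro_z = clip(gyro_z),
    accel_x = accel_x, accel_y = accel_y, accel_z = accel_z
  )

  n_cop <- length(t_cop)
  cop <- tibble::tibble(
    time = t_cop,
    cop_x = noise(n_cop, params$cop_noise_sd),
    cop_y = params$cop_gain * k_cop$angle + noise(n_cop, params$cop_noise_sd)
  )

  rec <- new_recording(subject_id = subject_id, imu = imu, cop = cop,
                       imu_rate = imu_rate, cop_rate = cop_rate,
                       duration = dur)

  score <- function(mu, s, lo, hi) {
    as.integer(round(pmin(pmax(rnorm(1, mu, s), lo), hi)))
  }
  meta <- tibble::tibble(
    subject_id = subject_id,
    sbst_label = params$risk_class,
    hads_a = score(params$psych_means[1], params$psych_sds[1], 0, 21),
    hads_d = score(params$psych_means[2], params$psych_sds[2], 0, 21),
    tsk = score(params$psych_means[3], params$psych_sds[3], 17, 68),
    age = round(rnorm(1, 43.6, 6.9), 1),
    height = round(rnorm(1, 172.6, 7.3), 1),
    weight = round(rnorm(1, 79.5, 12.5), 1)
  )
  class(meta) <- c("subject_meta", class(meta))
  list(recording = rec, meta = meta)
}

# Save/restore the global RNG state so generators are pure functions of
# their explicit seeds without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Instantiate one subject's parameters from a group profile by jittering
# period, range of motion and velocity scale lognormally with the
# profile's between-subject CV.
individualize_params <- function(profile, seed) {
  cv <- profile$between_subject_cv
  if (cv == 0) return(profile)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  jitter <- function(x) x * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  p <- profile
  p$cycle_period_mean <- jitter(profile$cycle_period_mean)
  p$rom_amplitude <- min(jitter(profile$rom_amplitude), 120)
  p$velocity_scale <- jitter(profile$velocity_scale)
  p
}

#' Simulate a full cohort
#'
#' Generates one recording + metadata pair per subject, with the
#' configured counts per risk class. Each subject gets a seed derived
#' deterministically from `config$seed`, so the cohort is a pure
#' function of its configuration. Within a class, subjects are
#' individualized by jittering the profile's kinematic parameters with
#' its `between_subject_cv`.
#'
#' @param config A [cohort_config()] object.
#'
#' @return A list of class `trunk_cohort` with elements `subjects`
#'   (list of `list(recording, meta)`) and `manifest` (tibble, one row
#'   per subject).
#' @examples
#' cohort <- generate_cohort(cohort_config(group_sizes =
#'   c(low = 2, medium = 2, high = 2), seed = 7))
#' cohort$manifest$sbst_label
#' @export
generate_cohort <- function(config = cohort_config()) {
  assert_that(inherits(config, "cohort_config"),
              "`config` must be built with cohort_config()",
              class = "trunkstrat_config_error")
  n_total <- sum(config$group_sizes)
  ids <- sprintf("S%03d", seq_len(n_total))
  classes <- rep(RISK_LEVELS, times = config$group_sizes[RISK_LEVELS])
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    profile <- config$profiles[[classes[i]]]
    seed_params <- derive_seed(config$seed, 2L * i - 1L)
    seed_signal <- derive_seed(config$seed, 2L * i)
    params_i <- individualize_params(profile, seed_params)
    subjects[[i]] <- generate_subject(params_i, seed_signal,
                                      subject_id = ids[i])
  }
  manifest <- dplyr::bind_rows(lapply(subjects, `[[`, "meta"))
  structure(list(subjects = subjects, manifest = manifest),
            class = "trunk_cohort")
}

#' @export
print.trunk_cohort <- function(x, ...) {
  counts <- table(factor(x$manifest$sbst_label, levels = RISK_LEVELS))
  cat(sprintf("<trunk_cohort> %d subjects (low %d / medium %d / high %d)\n",
              nrow(x$manifest), counts["low"], counts["medium"],
              counts["high"]))
  invisible(x)
}
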