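# Internal helpers shared across modules.

# Canonical 9-channel layout: angular velocity, linear acceleration, then
# angular acceleration, X/Y/Z within each block. Every stage that touches
# per-channel data orders it this way.
CHANNELS_IMU <- c("gyro_x", "gyro_y", "gyro_z",
                  "accel_x", "accel_y", "accel_z")
CHANNELS_ALL <- c(CHANNELS_IMU, "angacc_x", "angacc_y", "angacc_z")

RISK_LEVELS <- c("low", "medium", "high")

GYRO_FULL_SCALE <- 2000 # deg/s, sensor full-scale range

#' @noRd
assert_that <- function(ok, msg, class = "trunkstrat_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# Deterministic child-seed derivation (Lehmer step keeps values in
# [1, 2^31 - 2] so they remain valid 32-bit integer seeds).
#' @noRd
derive_seed <- function(seed, index) {
  m <- 2147483647
  x <- (as.double(seed) %% m) + 1
  for (i in seq_len(index)) {
    x <- (x * 48271) %% m
  }
  as.integer(x)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' @noRd
feature_columns <- function(features) {
  setdiff(names(features), "subject_id")
}

#' @noRd
feature_matrix_values <- function(features) {
  as.matrix(features[, feature_columns(features), drop = FALSE])
}
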