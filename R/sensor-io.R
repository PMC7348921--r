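#' Construct and validate a trunk sensor recording
#'
#' A `trunk_recording` bundles the two synchronized streams of one
#' subject's flexion/extension trial: the chest IMU block (time plus
#' gyro X/Y/Z in deg/s and accel X/Y/Z in m/s^2; X = flexion/extension
#' axis for the gyro, vertical for the accelerometer, Y = mediolateral,
#' Z = anteroposterior) and the balance-board COP block (time plus
#' cop_x/cop_y in cm). The streams run at different rates (nominally 20
#' and 40 Hz), which is why they live in two tibbles rather than one
#' rectangular table.
#'
#' @param subject_id Subject identifier string.
#' @param imu Tibble with columns `time, gyro_x, gyro_y, gyro_z,
#'   accel_x, accel_y, accel_z`.
#' @param cop Tibble with columns `time, cop_x, cop_y`.
#' @param imu_rate,cop_rate Sampling rates in Hz.
#' @param duration Task duration in seconds.
#'
#' @return A validated object of class `trunk_recording`.
#' @export
new_recording <- function(subject_id, imu, cop, imu_rate = 20,
                          cop_rate = 40, duration = 14) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         imu_rate = imu_rate, cop_rate = cop_rate, duration = duration,
         imu = tibble::as_tibble(imu), cop = tibble::as_tibble(cop)),
    class = "trunk_recording"
  )
  validate_recording(rec)
}

#' @rdname new_recording
#' @param rec A `trunk_recording`.
#' @export
validate_recording <- function(rec) {
  assert_that(inherits(rec, "trunk_recording"),
              "not a trunk_recording", class = "trunkstrat_format_error")
  need_imu <- c("time", CHANNELS_IMU)
  assert_that(identical(names(rec$imu), need_imu),
              sprintf("IMU block must have columns %s",
                      paste(need_imu, collapse = ", ")),
              class = "trunkstrat_format_error")
  assert_that(identical(names(rec$cop), c("time", "cop_x", "cop_y")),
              "COP block must have columns time, cop_x, cop_y",
              class = "trunkstrat_format_error")
  assert_that(all(vapply(rec$imu, is.numeric, logical(1))) &&
                all(vapply(rec$cop, is.numeric, logical(1))),
              "all recording columns must be numeric",
              class = "trunkstrat_format_error")
  assert_that(!anyNA(rec$imu) && !anyNA(rec$cop),
              "recording contains missing samples",
              class = "trunkstrat_format_error")
  assert_that(nrow(rec$imu) >= 1 && nrow(rec$cop) >= 1,
              "recording has empty streams",
              class = "trunkstrat_format_error")
  assert_that(abs(nrow(rec$imu) - rec$imu_rate * rec$duration) <= 1,
              "IMU length inconsistent with rate x duration",
              class = "trunkstrat_format_error")
  assert_that(abs(nrow(rec$cop) - rec$cop_rate * rec$duration) <= 1,
              "COP length inconsistent with rate x duration",
              class = "trunkstrat_format_error")
  gyro <- as.matrix(rec$imu[, c("gyro_x", "gyro_y", "gyro_z")])
  assert_that(all(abs(gyro) <= GYRO_FULL_SCALE + 1e-9),
              "gyroscope samples exceed the +/-2000 deg/s full scale",
              class = "trunkstrat_format_error")
  rec
}

#' @export
print.trunk_recording <- function(x, ...) {
  cat(sprintf(
    "<trunk_recording> %s: %d IMU samples @ %g Hz, %d COP samples @ %g Hz, %g s\n",
    x$subject_id, nrow(x$imu), x$imu_rate, nrow(x$cop), x$cop_rate,
    x$duration))
  invisible(x)
}

#' Write a recording to its plain-text format
#'
#' One file per subject: a header of `# key: value` lines (subject id,
#' rates, duration, units, channel order) followed by an `[IMU]` block
#' and a `[COP]` block, each a comma-delimited table with its own time
#' column. Values are written with 17 significant digits so a
#' write/read round trip reproduces every double bit-exactly.
#'
#' @param rec A `trunk_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  fmt_block <- function(df) {
    cols <- lapply(df, function(x) sprintf("%.17g", x))
    c(paste(names(df), collapse = ","),
      do.call(paste, c(cols, sep = ",")))
  }
  lines <- c(
    "# trunkstrat recording v1",
    sprintf("# subject_id: %s", rec$subject_id),
    sprintf("# imu_rate_hz: %.17g", rec$imu_rate),
    sprintf("# cop_rate_hz: %.17g", rec$cop_rate),
    sprintf("# duration_s: %.17g", rec$duration),
    "# imu_units: s,deg/s,deg/s,deg/s,m/s2,m/s2,m/s2",
    "# cop_units: s,cm,cm",
    "[IMU]",
    fmt_block(rec$imu),
    "[COP]",
    fmt_block(rec$cop)
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  assert_that(ok, sprintf("cannot write recording to '%s'", path),
              class = "trunkstrat_io_error")
  invisible(path)
}

#' Read a recording from its plain-text format
#'
#' Parses the header and both blocks, normalizes the channel order to
#' the canonical one (gyro X,Y,Z then accel X,Y,Z) regardless of the
#' column order on disk, and validates stream geometry. Sampling rates
#' are taken from the header, not assumed, so recordings at other rates
#' propagate correctly to downstream filtering.
#'
#' @param path Path to a file written by [write_recording()].
#' @return A validated `trunk_recording`.
#' @export
read_recording <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              class = "trunkstrat_io_error")
  lines <- readLines(path)
  header <- grep("^# ", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(sprintf("^# %s:", key), header, value = TRUE)
    assert_that(length(hit) == 1,
                sprintf("header field '%s' missing in '%s'", key, path),
                class = "trunkstrat_format_error")
    trimws(sub(sprintf("^# %s:", key), "", hit))
  }
  num_field <- function(key) {
    v <- suppressWarnings(as.numeric(get_field(key)))
    assert_that(!is.na(v), sprintf("header field '%s' is not numeric", key),
                class = "trunkstrat_format_error")
    v
  }
  imu_at <- match("[IMU]", lines)
  cop_at <- match("[COP]", lines)
  assert_that(!is.na(imu_at) && !is.na(cop_at) && imu_at < cop_at,
              sprintf("'%s' lacks the [IMU]/[COP] block structure", path),
              class = "trunkstrat_format_error")

  parse_block <- function(from, to, block) {
    body <- lines[seq(from, to)]
    header_cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
    rows <- strsplit(body[-1], ",", fixed = TRUE)
    bad_width <- which(lengths(rows) != length(header_cols))
    assert_that(length(bad_width) == 0,
                sprintf("%s block line %d has %d fields, expected %d",
                        block, from + bad_width[1],
                        lengths(rows)[bad_width[1]], length(header_cols)),
                class = "trunkstrat_format_error")
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(rows)), ncol = length(header_cols),
             byrow = TRUE))
    bad_num <- which(rowSums(is.na(vals)) > 0)
    assert_that(length(bad_num) == 0,
                sprintf("%s block line %d contains a non-numeric cell",
                        block, from + bad_num[1]),
                class = "trunkstrat_format_error")
    df <- tibble::as_tibble(as.data.frame(vals))
    names(df) <- header_cols
    df
  }
  imu <- parse_block(imu_at + 1, cop_at - 1, "IMU")
  cop <- parse_block(cop_at + 1, length(lines), "COP")

  need_imu <- c("time", CHANNELS_IMU)
  assert_that(setequal(names(imu), need_imu) &&
                length(names(imu)) == length(need_imu),
              sprintf("IMU block must have exactly columns %s",
                      paste(need_imu, collapse = ", ")),
              class = "trunkstrat_format_error")
  assert_that(setequal(names(cop), c("time", "cop_x", "cop_y")),
              "COP block must have exactly columns time, cop_x, cop_y",
              class = "trunkstrat_format_error")
  new_recording(subject_id = get_field("subject_id"),
                imu = imu[, need_imu],
                cop = cop[, c("time", "cop_x", "cop_y")],
                imu_rate = num_field("imu_rate_hz"),
                cop_rate = num_field("cop_rate_hz"),
                duration = num_field("duration_s"))
}

MANIFEST_COLS <- c("subject_id", "sbst_label", "hads_a", "hads_d", "tsk",
                   "age", "height", "weight")

#' Validate subject metadata
#'
#' Checks risk labels and questionnaire ranges: SBST label one of
#' low/medium/high (case-insensitive on read), HADS subscales in 0-21,
#' TSK in 17-68.
#'
#' @param meta Data frame with the manifest columns.
#' @return The validated tibble (labels normalized to lower case).
#' @export
validate_manifest <- function(meta) {
  missing <- setdiff(MANIFEST_COLS, names(meta))
  assert_that(length(missing) == 0,
              sprintf("manifest lacks column(s): %s",
                      paste(missing, collapse = ", ")),
              class = "trunkstrat_format_error")
  meta <- tibble::as_tibble(meta)
  meta$sbst_label <- tolower(as.character(meta$sbst_label))
  bad <- which(!meta$sbst_label %in% RISK_LEVELS)
  assert_that(length(bad) == 0,
              sprintf("row %d has unknown risk label '%s'",
                      bad[1], meta$sbst_label[bad[1]]),
              class = "trunkstrat_format_error")
  rng <- function(col, lo, hi) {
    bad <- which(meta[[col]] < lo | meta[[col]] > hi | is.na(meta[[col]]))
    assert_that(length(bad) == 0,
                sprintf("row %d: %s=%s outside [%d, %d]",
                        bad[1], col, meta[[col]][bad[1]], lo, hi),
                class = "trunkstrat_format_error")
  }
  rng("hads_a", 0, 21)
  rng("hads_d", 0, 21)
  rng("tsk", 17, 68)
  meta
}

#' Read / write a cohort manifest
#'
#' The manifest is a plain CSV with one row per subject: id, SBST risk
#' label, HADS-A, HADS-D, TSK, age, height, weight. Row order is
#' preserved.
#'
#' @param path CSV file path.
#' @return `read_manifest()`: validated tibble of subject metadata.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              class = "trunkstrat_io_error")
  validate_manifest(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest Data frame of subject metadata.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a whole cohort to a directory
#'
#' Writes `manifest.csv` plus one recording file per subject
#' (`<subject_id>.rec`).
#'
#' @param cohort A `trunk_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  for (s in cohort$subjects) {
    write_recording(s$recording,
                    file.path(dir, paste0(s$recording$subject_id, ".rec")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_recording(file.path(
      dir, paste0(manifest$subject_id[i], ".rec")))
    list(recording = rec, meta = manifest[i, ])
  })
  structure(list(subjects = subjects, manifest = manifest),
            class = "trunk_cohort")
}
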