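FEATURE_SETS <- c("FS", "FT16", "Wii", "ADT")

FT16_STATS <- c("max", "min", "range", "mean", "q1", "q2", "q3", "iqr",
                "iqr_over_median", "sd", "kurtosis", "skewness", "entropy",
                "power", "freq_max_power", "median_freq")

#' Sixteen summary statistics of one aggregated profile
#'
#' The per-channel summary feature set: max, min, range, mean, the three
#' quartiles (linear interpolation of order statistics), IQR,
#' IQR/median, standard deviation, kurtosis (Pearson, non-excess),
#' skewness, Shannon entropy of a 10-equal-width-bin amplitude
#' histogram (natural log, with 0 log 0 = 0), mean power (mean squared
#' value), and two spectral features from the periodogram of the
#' 100-point profile with the DC term excluded: the frequency at
#' maximum power and the median frequency (smallest frequency whose
#' cumulative power reaches half the total). Because the profile is
#' time-normalized, frequencies are in cycles per aggregated cycle.
#'
#' @param profile Numeric 100-point aggregated profile.
#' @param iqr_median_sentinel Value reported for IQR/median when the
#'   median is zero (with a warning).
#' @return Named numeric vector of the 16 statistics, in fixed order.
#' @export
compute_ft16 <- function(profile, iqr_median_sentinel = 0) {
  assert_that(is.numeric(profile) && length(profile) == 100,
              "`profile` must be a 100-point numeric vector",
              class = "trunkstrat_invalid_parameter")
  q <- unname(quantile(profile, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  if (q[2] == 0) {
    warn("median is zero; reporting IQR/median as the configured sentinel")
    iqr_med <- iqr_median_sentinel
  } else {
    iqr_med <- iqr / q[2]
  }
  m <- mean(profile)
  centered <- profile - m
  m2 <- mean(centered^2)
  # Degenerate (constant) profiles have no shape: define both
  # standardized moments as 0 rather than 0/0.
  kurt <- if (m2 > 0) mean(centered^4) / m2^2 else 0
  skew <- if (m2 > 0) mean(centered^3) / m2^1.5 else 0

  counts <- amplitude_histogram(profile, n_bins = 10)
  p <- counts[counts > 0] / length(profile)
  entropy <- -sum(p * log(p))

  spec <- profile_periodogram(profile)
  total <- sum(spec$power)
  if (total > 0) {
    f_max <- spec$freq[which.max(spec$power)]
    f_med <- spec$freq[which(cumsum(spec$power) >= total / 2)[1]]
  } else {
    f_max <- 0
    f_med <- 0
  }

  out <- c(max(profile), min(profile), max(profile) - min(profile), m,
           q[1], q[2], q[3], iqr, iqr_med, sd(profile), kurt, skew,
           entropy, mean(profile^2), f_max, f_med)
  names(out) <- FT16_STATS
  out
}

amplitude_histogram <- function(x, n_bins = 10) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(c(length(x), rep(0, n_bins - 1)))
  bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1, n_bins)
  tabulate(bin, nbins = n_bins)
}

# One-sided periodogram of a length-n series, DC excluded; frequencies
# in cycles per series length.
profile_periodogram <- function(x) {
  n <- length(x)
  xf <- fft(x)
  k <- seq_len(floor(n / 2))
  list(freq = k, power = Mod(xf[k + 1])^2 / n)
}

#' FT16 statistics for all nine channels
#'
#' Applies [compute_ft16()] to each of the nine aggregated channel
#' profiles (angular velocity, linear acceleration and angular
#' acceleration in X, Y and Z), giving 16 x 3 x 3 = 144
#' channel-qualified features.
#'
#' @param profiles Named list of nine 100-point profiles (from
#'   [preprocess_recording()]).
#' @param ... Passed to [compute_ft16()].
#' @return Named numeric vector of 144 values
#'   (`ft16_<channel>_<stat>`).
#' @export
compute_ft16_set <- function(profiles, ...) {
  missing <- setdiff(CHANNELS_ALL, names(profiles))
  assert_that(length(missing) == 0,
              sprintf("missing channel(s): %s",
                      paste(missing, collapse = ", ")),
              class = "trunkstrat_assembly_error")
  out <- lapply(CHANNELS_ALL, function(ch) {
    v <- compute_ft16(profiles[[ch]], ...)
    names(v) <- sprintf("ft16_%s_%s", ch, names(v))
    v
  })
  unlist(out)
}

#' Postural-sway features from the COP trajectory
#'
#' Computed over the whole trial: the COP displacement range along each
#' axis (cm), the path length (cm; sum of consecutive Euclidean steps),
#' and the area of the 95% prediction ellipse (cm^2), computed from the
#' eigenvalues of the 2x2 COP covariance as
#' `pi * 5.991 * sqrt(lambda1 * lambda2)` (5.991 is the 95% quantile of
#' a chi-squared distribution with 2 df). A degenerate, motionless
#' trajectory yields zeros.
#'
#' @param cop Tibble / data frame with columns `cop_x`, `cop_y` (cm).
#' @return Named numeric vector: `wii_range_x`, `wii_range_y`,
#'   `wii_path_length`, `wii_ellipse_area`.
#' @export
compute_cop_features <- function(cop) {
  assert_that(nrow(cop) >= 3, "need at least 3 COP samples",
              class = "trunkstrat_insufficient_data")
  x <- cop$cop_x
  y <- cop$cop_y
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  cv <- stats::cov(cbind(x, y))
  ev <- pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0)
  area <- pi * 5.991 * sqrt(ev[1] * ev[2])
  c(wii_range_x = diff(range(x)), wii_range_y = diff(range(y)),
    wii_path_length = path, wii_ellipse_area = area)
}

#' Psychosocial questionnaire features
#'
#' Passes through the subject's HADS-anxiety, HADS-depression and TSK
#' (kinesiophobia) scores after range validation (HADS subscales 0-21,
#' TSK 17-68).
#'
#' @param meta One row of subject metadata.
#' @return Named numeric vector: `adt_hads_a`, `adt_hads_d`, `adt_tsk`.
#' @export
compute_adt_features <- function(meta) {
  validate_manifest(meta)
  c(adt_hads_a = as.numeric(meta$hads_a[1]),
    adt_hads_d = as.numeric(meta$hads_d[1]),
    adt_tsk = as.numeric(meta$tsk[1]))
}

#' All features for one subject
#'
#' Runs preprocessing and assembles the requested feature sets into a
#' one-row tibble.
#'
#' @param recording A `trunk_recording`.
#' @param meta The subject's metadata row.
#' @param sets Subset of `c("FS", "FT16", "Wii", "ADT")`.
#' @param cutoff_hz Cycle-detection low-pass cutoff, Hz.
#' @return One-row tibble: `subject_id` plus one column per feature,
#'   with a `feature_set` attribute mapping columns to sets.
#' @export
subject_features <- function(recording, meta, sets = FEATURE_SETS,
                             cutoff_hz = 1) {
  sets <- match.arg(sets, FEATURE_SETS, several.ok = TRUE)
  needs_profiles <- any(c("FS", "FT16") %in% sets)
  prep <- if (needs_profiles) {
    preprocess_recording(recording, cutoff_hz = cutoff_hz)
  }
  vals <- c(
    if ("FS" %in% sets) prep$full_signal,
    if ("FT16" %in% sets) compute_ft16_set(prep$profiles),
    if ("Wii" %in% sets) compute_cop_features(recording$cop),
    if ("ADT" %in% sets) compute_adt_features(meta)
  )
  out <- tibble::as_tibble(as.list(vals))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = recording$subject_id), out)
  attr(out, "feature_set") <- feature_set_registry(names(out))
  out
}

# Map feature-column names to their set by prefix.
feature_set_registry <- function(cols) {
  cols <- setdiff(cols, "subject_id")
  set <- dplyr::case_when(
    startsWith(cols, "fs_") ~ "FS",
    startsWith(cols, "ft16_") ~ "FT16",
    startsWith(cols, "wii_") ~ "Wii",
    startsWith(cols, "adt_") ~ "ADT"
  )
  stats::setNames(set, cols)
}

#' Feature table for a whole cohort
#'
#' @param cohort A `trunk_cohort`.
#' @inheritParams subject_features
#' @return Tibble, one row per subject in cohort order, with the
#'   `feature_set` attribute.
#' @export
cohort_features <- function(cohort, sets = FEATURE_SETS, cutoff_hz = 1) {
  rows <- lapply(cohort$subjects, function(s) {
    subject_features(s$recording, s$meta, sets = sets,
                     cutoff_hz = cutoff_hz)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "feature_set") <- feature_set_registry(names(out))
  out
}

#' Select a factorial combination of feature sets
#'
#' Keeps the columns belonging to the selected sets, concatenated in
#' the fixed order FS, FT16, Wii, ADT. With all four sets this gives
#' 900 + 144 + 4 + 3 = 1051 columns.
#'
#' @param features A feature tibble from [cohort_features()].
#' @param selection Nonempty subset of `c("FS", "FT16", "Wii", "ADT")`.
#' @return Feature tibble restricted to the selection.
#' @export
assemble_feature_set <- function(features, selection) {
  assert_that(length(selection) >= 1, "selection must be nonempty",
              class = "trunkstrat_invalid_parameter")
  selection <- match.arg(selection, FEATURE_SETS, several.ok = TRUE)
  registry <- attr(features, "feature_set") %||%
    feature_set_registry(names(features))
  missing_sets <- setdiff(selection, unique(registry))
  assert_that(length(missing_sets) == 0,
              sprintf("feature table does not contain set(s): %s",
                      paste(missing_sets, collapse = ", ")),
              class = "trunkstrat_invalid_parameter")
  keep <- names(registry)[registry %in% selection]
  keep <- keep[order(match(registry[keep], FEATURE_SETS))]
  out <- features[, c("subject_id", keep)]
  attr(out, "feature_set") <- registry[keep]
  out
}

#' Standardize features across subjects
#'
#' Centres each feature at its cross-subject mean and scales it to unit
#' sample standard deviation (the z-score; population SD available via
#' `scale_type`), so heterogeneous feature types contribute on a common
#' scale before any learning. Zero-dispersion columns cannot be scaled
#' and are dropped with a warning; the returned statistics record them.
#'
#' @param features Feature tibble (subject_id + numeric columns).
#' @param scale_type `"sample"` (n-1 denominator) or `"population"`.
#' @return List with `features` (standardized tibble) and `stats`
#'   (tibble: feature, center, scale, dropped) for reuse on held-out
#'   subjects via [apply_normalization()].
#' @export
normalize_features <- function(features, scale_type = c("sample",
                                                        "population")) {
  scale_type <- match.arg(scale_type)
  assert_that(nrow(features) >= 2, "need at least 2 subjects",
              class = "trunkstrat_insufficient_data")
  cols <- feature_columns(features)
  x <- feature_matrix_values(features)
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  if (scale_type == "population") {
    n <- nrow(x)
    scale <- scale * sqrt((n - 1) / n)
  }
  dropped <- scale == 0
  if (any(dropped)) {
    warn(sprintf("dropping %d zero-dispersion feature(s): %s",
                 sum(dropped),
                 paste(head(cols[dropped], 5), collapse = ", ")))
  }
  stats <- tibble::tibble(feature = cols, center = unname(center),
                          scale = unname(scale), dropped = unname(dropped))
  keep <- cols[!dropped]
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
             scale[keep], "/")
  out <- dplyr::bind_cols(tibble::tibble(subject_id = features$subject_id),
                          tibble::as_tibble(z))
  registry <- attr(features, "feature_set")
  if (!is.null(registry)) attr(out, "feature_set") <- registry[keep]
  list(features = out, stats = stats)
}

#' Apply previously computed normalization statistics
#'
#' Standardizes new rows (e.g. a held-out subject) with centres and
#' scales estimated elsewhere (e.g. the training fold), dropping the
#' same zero-dispersion columns.
#'
#' @param features Feature tibble to transform.
#' @param stats The `stats` element of [normalize_features()].
#' @return Standardized tibble with the retained columns.
#' @export
apply_normalization <- function(features, stats) {
  keep <- stats$feature[!stats$dropped]
  assert_that(all(keep %in% names(features)),
              "features lack columns named in the normalization stats",
              class = "trunkstrat_invalid_parameter")
  x <- as.matrix(features[, keep, drop = FALSE])
  z <- sweep(sweep(x, 2, stats$center[!stats$dropped]), 2,
             stats$scale[!stats$dropped], "/")
  dplyr::bind_cols(tibble::tibble(subject_id = features$subject_id),
                   tibble::as_tibble(z))
}

#' Write / read a feature table as delimited text
#'
#' @param features Feature tibble.
#' @param path CSV path.
#' @return The path (write) or the tibble (read).
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
  attr(out, "feature_set") <- feature_set_registry(names(out))
  out
}
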