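test_that("the 16 summary statistics are exact on analytic profiles", {
  const <- rep(2, 100)
  f <- suppressWarnings(compute_ft16(const))
  expect_named(f, c("max", "min", "range", "mean", "q1", "q2", "q3",
                    "iqr", "iqr_over_median", "sd", "kurtosis",
                    "skewness", "entropy", "power", "freq_max_power",
                    "median_freq"))
  expect_equal(unname(f[c("max", "min", "mean")]), c(2, 2, 2))
  expect_equal(unname(f[c("range", "sd", "entropy")]), c(0, 0, 0))
  expect_equal(unname(f["power"]), 4)

  ramp <- as.numeric(1:100)
  g <- compute_ft16(ramp)
  expect_equal(unname(g["range"]), 99)
  expect_equal(unname(g["mean"]), 50.5)
  expect_equal(unname(g["q2"]), 50.5)
  expect_equal(unname(g["iqr"]), unname(g["q3"] - g["q1"]))

  # pure tone, 5 periods across the profile -> spectral peak at 5
  tone <- sin(2 * pi * 5 * (0:99) / 100)
  h <- compute_ft16(tone)
  expect_equal(unname(h["freq_max_power"]), 5)
  expect_equal(unname(h["median_freq"]), 5)

  expect_warning(compute_ft16(rep(c(-1, 1), each = 50)),
                 "median is zero")
  expect_error(compute_ft16(1:50),
               class = "trunkstrat_invalid_parameter")
})

test_that("order-statistics features agree with a sort-based oracle", {
  for (case in 1:25) {
    x <- withr::with_seed(case, rnorm(100))
    f <- compute_ft16(x)
    s <- sort(x)
    expect_equal(unname(f["max"]), s[100])
    expect_equal(unname(f["min"]), s[1])
    # type-7 quartiles by direct interpolation of order statistics
    interp <- function(p) {
      h <- (100 - 1) * p + 1
      s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
    }
    expect_equal(unname(f["q1"]), interp(0.25))
    expect_equal(unname(f["q3"]), interp(0.75))
  }
})

test_that("the per-channel summary set has 144 uniquely named features", {
  subj <- generate_subject(subject_sim_params(), seed = 8)
  prep <- preprocess_recording(subj$recording)
  v <- compute_ft16_set(prep$profiles)
  expect_length(v, 144)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_error(compute_ft16_set(prep$profiles[-1]),
               class = "trunkstrat_assembly_error")
})

test_that("postural-sway features follow their geometric definitions", {
  square <- tibble::tibble(cop_x = c(0, 1, 1, 0, 0),
                           cop_y = c(0, 0, 1, 1, 0))
  f <- compute_cop_features(square)
  expect_equal(unname(f[c("wii_range_x", "wii_range_y",
                          "wii_path_length")]), c(1, 1, 4))

  still <- tibble::tibble(cop_x = rep(0.3, 10), cop_y = rep(-0.1, 10))
  expect_equal(unname(compute_cop_features(still)), rep(0, 4))

  # isotropic Gaussian: 95% ellipse area ~ pi * 5.991 * sigma^2
  sigma <- 0.7
  cloud <- withr::with_seed(21, tibble::tibble(
    cop_x = rnorm(1e4, 0, sigma), cop_y = rnorm(1e4, 0, sigma)))
  area <- compute_cop_features(cloud)[["wii_ellipse_area"]]
  expect_equal(area, pi * 5.991 * sigma^2, tolerance = 0.05)

  # ellipse area is rotation-invariant, path length translation-invariant
  aniso <- withr::with_seed(22, tibble::tibble(
    cop_x = rnorm(500, 0, 1.5), cop_y = rnorm(500, 0, 0.4)))
  th <- 0.7
  rot <- tibble::tibble(
    cop_x = cos(th) * aniso$cop_x - sin(th) * aniso$cop_y,
    cop_y = sin(th) * aniso$cop_x + cos(th) * aniso$cop_y)
  expect_equal(compute_cop_features(rot)[["wii_ellipse_area"]],
               compute_cop_features(aniso)[["wii_ellipse_area"]],
               tolerance = 1e-8)
  shifted <- dplyr::mutate(aniso, cop_x = cop_x + 10, cop_y = cop_y - 3)
  expect_equal(compute_cop_features(shifted)[["wii_path_length"]],
               compute_cop_features(aniso)[["wii_path_length"]],
               tolerance = 1e-9)

  expect_error(compute_cop_features(square[1:2, ]),
               class = "trunkstrat_insufficient_data")
})

test_that("questionnaire features pass through validated scores", {
  meta <- tibble::tibble(subject_id = "S1", sbst_label = "low",
                         hads_a = 5, hads_d = 7, tsk = 30,
                         age = 40, height = 170, weight = 80)
  expect_equal(unname(compute_adt_features(meta)), c(5, 7, 30))
  bad <- dplyr::mutate(meta, hads_a = 25)
  expect_error(compute_adt_features(bad),
               class = "trunkstrat_format_error")
})

test_that("standardization yields zero-mean unit-SD columns and drops constants", {
  f <- tibble::tibble(subject_id = c("a", "b", "c"),
                      x = c(1, 2, 3), y = c(10, 30, 20),
                      z = c(5, 5, 5))
  expect_warning(normalize_features(f), "zero-dispersion")
  out <- suppressWarnings(normalize_features(f))
  expect_equal(out$features$x, c(-1, 0, 1))
  expect_false("z" %in% names(out$features))
  expect_true(out$stats$dropped[out$stats$feature == "z"])

  # idempotence on already-standardized data
  again <- normalize_features(out$features)$features
  expect_equal(again$x, out$features$x, tolerance = 1e-12)

  # property: many random matrices
  for (case in 1:10) {
    n <- sample(5:30, 1)
    m <- withr::with_seed(case, matrix(rnorm(n * 4) * 10, n, 4))
    ft <- dplyr::bind_cols(tibble::tibble(subject_id = as.character(1:n)),
                           tibble::as_tibble(as.data.frame(m)))
    z <- as.matrix(normalize_features(ft)$features[, -1])
    expect_lt(max(abs(colMeans(z))), 1e-10)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  }

  # held-out rows reuse training statistics
  stats <- normalize_features(f[, c("subject_id", "x", "y")])$stats
  held <- apply_normalization(
    tibble::tibble(subject_id = "d", x = 4, y = 20), stats)
  expect_equal(held$x, (4 - 2) / 1)
})

test_that("feature-set assembly follows the factorial registry", {
  cohort <- generate_cohort(tiny_cohort_config())
  features <- cohort_features(cohort)
  expect_equal(ncol(features) - 1, 1051)   # 900 + 144 + 4 + 3

  expect_equal(ncol(assemble_feature_set(features, "FS")) - 1, 900)
  expect_equal(ncol(assemble_feature_set(features, c("FT16", "Wii"))) - 1,
               148)
  expect_equal(
    ncol(assemble_feature_set(features, c("FS", "FT16", "Wii",
                                          "ADT"))) - 1, 1051)
  # fixed set order regardless of selection order
  sel <- assemble_feature_set(features, c("ADT", "FS"))
  expect_true(startsWith(names(sel)[2], "fs_"))
  expect_true(startsWith(names(sel)[ncol(sel)], "adt_"))
  expect_error(assemble_feature_set(features, character(0)),
               class = "trunkstrat_invalid_parameter")

  # delimited round trip preserves the registry
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(features, path)
  back <- read_features(path)
  expect_equal(ncol(assemble_feature_set(back, "FT16")) - 1, 144)
})
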