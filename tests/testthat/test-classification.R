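single_cell_grid <- function() default_svm_grid(costs = 1)[1, ]

test_that("risk labels map onto the four groupings", {
  labels <- c("low", "medium", "high", "high")
  g <- make_grouping(labels, "high_vs_lowmedium")
  expect_true(g$binary)
  expect_equal(g$positive, "high")
  expect_equal(as.character(g$y),
               c("low-medium", "low-medium", "high", "high"))

  g2 <- make_grouping(labels, "low_vs_mediumhigh")
  expect_equal(g2$positive, "low")
  expect_equal(as.character(g2$y)[1], "low")

  g3 <- make_grouping(labels, "three_class")
  expect_false(g3$binary)
  expect_null(g3$positive)
  expect_equal(levels(g3$y), c("low", "medium", "high"))
})

test_that("balanced subsampling keeps all minority and equalizes counts", {
  y <- rep(c("high", "low-medium"), c(28, 56))
  runs <- balanced_subsample_runs(y, n_runs = 10, seed = 4)
  expect_length(runs, 10)
  for (idx in runs) {
    expect_length(idx, 56)
    expect_equal(unname(table(y[idx])), c(28, 28), ignore_attr = TRUE)
    expect_true(all(which(y == "high") %in% idx))
  }
  # reproducible families, distinct runs
  runs2 <- balanced_subsample_runs(y, n_runs = 10, seed = 4)
  expect_identical(runs, runs2)
  expect_gt(length(unique(lapply(runs, paste, collapse = ","))), 1)

  balanced <- rep(c("a", "b"), each = 10)
  all_runs <- balanced_subsample_runs(balanced, n_runs = 3, seed = 1)
  expect_true(all(vapply(all_runs, length, integer(1)) == 20))

  expect_error(balanced_subsample_runs(c("a", "b", "c"), 2, 1),
               class = "trunkstrat_invalid_parameter")
})

test_that("LOPO SVM separates wide-margin classes and reports the best cell", {
  sep <- make_separable(n_per = 8, gap = 6)
  fit <- lopo_svm(sep$features, sep$labels)
  expect_equal(fit$accuracy, 100)
  expect_equal(nrow(fit$predictions), 16)
  expect_equal(nrow(fit$cell_accuracies), 15)
  expect_equal(max(fit$cell_accuracies$accuracy), fit$accuracy)

  expect_error(lopo_svm(sep$features, rep("one", 16)),
               class = "trunkstrat_degenerate_labels")
})

test_that("duplicated subjects with opposite labels defeat any classifier", {
  base <- make_separable(n_per = 6, gap = 4)$features
  doubled <- dplyr::bind_rows(base, base)
  doubled$subject_id <- sprintf("D%03d", 1:24)
  y <- rep(c("a", "b"), each = 12)
  # each held-out row has an identical twin with the opposite label in
  # training, so a classifier cannot beat chance on this construction
  # (leave-one-out twin bias can push it well below)
  fit <- lopo_svm(doubled, y, grid = single_cell_grid())
  expect_lte(fit$accuracy, 55)
})

test_that("label permutation drives LOPO accuracy to chance", {
  # no-signal features; 20 permutations with a fixed single-cell grid;
  # mean accuracy must land inside the 95% binomial band around 50%
  feats <- withr::with_seed(31, tibble::tibble(
    subject_id = sprintf("P%02d", 1:16),
    f1 = rnorm(16), f2 = rnorm(16), f3 = rnorm(16)))
  accs <- vapply(1:20, function(p) {
    y <- withr::with_seed(400 + p, sample(rep(c("a", "b"), each = 8)))
    lopo_svm(feats, y, grid = single_cell_grid())$accuracy
  }, numeric(1))
  half_width <- 1.96 * sqrt(0.25 / (16 * 20)) * 100
  expect_lt(abs(mean(accs) - 50), half_width + 15)
})

test_that("fold-wise normalization never sees the held-out subject", {
  feats <- withr::with_seed(17, tibble::tibble(
    subject_id = sprintf("P%02d", 1:10), f1 = rnorm(10),
    f2 = rnorm(10)))
  folds <- trunkstrat:::prepare_lopo_folds
  a <- folds(feats, normalize = "fold")
  # corrupt subject 1's row: every other fold changes, fold 1's
  # training matrix must not
  feats2 <- feats
  feats2$f1[1] <- feats2$f1[1] + 100
  b <- folds(feats2, normalize = "fold")
  expect_identical(a[[1]]$x_train, b[[1]]$x_train)
  expect_false(identical(a[[2]]$x_train, b[[2]]$x_train))
})

test_that("binary experiments report mean/sd over balanced runs", {
  cohort <- generate_cohort(cohort_config(
    group_sizes = c(low = 5, medium = 5, high = 6), seed = 12))
  features <- cohort_features(cohort, sets = c("Wii", "ADT"))
  exp <- run_experiment(features, cohort$manifest,
                        grouping = "high_vs_lowmedium",
                        classifier = "svm",
                        svm_grid = single_cell_grid(),
                        n_balance_runs = 4, seed = 2)
  expect_s3_class(exp, "risk_experiment")
  expect_equal(nrow(exp$runs), 4)
  expect_true(all(c("accuracy", "g_index") %in% names(exp$runs)))
  expect_equal(nrow(exp$summary), 6)
  expect_match(exp$summary$formatted[1], "^\\d+\\.\\d \\(\\d+\\.\\d\\)$")
  # determinism
  exp2 <- run_experiment(features, cohort$manifest,
                         grouping = "high_vs_lowmedium",
                         classifier = "svm",
                         svm_grid = single_cell_grid(),
                         n_balance_runs = 4, seed = 2)
  expect_equal(exp$runs, exp2$runs)
  # broom-style accessors
  expect_equal(nrow(tidy(exp)), 4)
  expect_equal(glance(exp)$n_runs, 4)
})

test_that("the three-class task reports accuracy and per-class recalls only", {
  cohort <- generate_cohort(cohort_config(
    group_sizes = c(low = 4, medium = 4, high = 4), seed = 13))
  features <- cohort_features(cohort, sets = c("Wii", "ADT"))
  exp <- run_experiment(features, cohort$manifest,
                        grouping = "three_class", classifier = "svm",
                        svm_grid = single_cell_grid(), seed = 2)
  expect_equal(nrow(exp$runs), 1)
  expect_false("g_index" %in% names(exp$runs))
  expect_equal(exp$per_class_recall$class, c("low", "medium", "high"))
  expect_true(all(exp$per_class_recall$recall >= 0 &
                    exp$per_class_recall$recall <= 100))
})

test_that("the factorial sweep covers all 15 combinations in set order", {
  combos <- trunkstrat:::feature_set_combinations()
  expect_length(combos, 15)
  labels <- vapply(combos, paste, character(1), collapse = "+")
  expect_equal(labels[1:4], c("FS", "FT16", "Wii", "ADT"))
  expect_equal(labels[15], "FS+FT16+Wii+ADT")
  expect_false(anyDuplicated(labels) > 0)
})
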