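test_that("confusion counts partition the evaluated subjects", {
  truth <- rep(c("pos", "neg"), c(6, 4))
  cc <- confusion_counts(truth, truth, positive = "pos")
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(6, 4, 0, 0))

  all_pos <- confusion_counts(truth, rep("pos", 10), positive = "pos")
  expect_equal(c(all_pos$tp, all_pos$fp, all_pos$tn, all_pos$fn),
               c(6, 4, 0, 0))

  for (case in 1:20) {
    pred <- withr::with_seed(case, sample(c("pos", "neg"), 10,
                                          replace = TRUE))
    cc <- confusion_counts(truth, pred, positive = "pos")
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 10)
  }
  expect_error(confusion_counts(truth, truth[1:5], "pos"),
               class = "trunkstrat_invalid_parameter")
  expect_error(confusion_counts(c("a", "b", "c"), c("a", "b", "c"), "a"),
               class = "trunkstrat_invalid_parameter")
})

test_that("the metric suite evaluates its defining formulas", {
  cc <- structure(list(tp = 8, fn = 2, tn = 6, fp = 4,
                       positive_class = "pos"),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, 70)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 60)
  expect_equal(m$precision, 100 * 8 / 12, tolerance = 1e-10)
  expect_equal(m$f1, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3),
               tolerance = 1e-10)   # 0.7273
  expect_equal(m$g_index, sqrt((1 - 0.8)^2 + (1 - 2 / 3)^2),
               tolerance = 1e-10)   # 0.3887
  expect_equal(m$g_category, "good")

  perfect <- confusion_counts(c("p", "p", "n"), c("p", "p", "n"), "p")
  pm <- compute_metrics(perfect)
  expect_equal(pm$accuracy, 100)
  expect_equal(pm$f1, 1)
  expect_equal(pm$g_index, 0)
  expect_equal(pm$g_category, "optimum")

  # sensitivity = precision = 0.5 -> G = sqrt(0.5), the "random" anchor
  half <- structure(list(tp = 5, fn = 5, fp = 5, tn = 5,
                         positive_class = "pos"),
                    class = "confusion_counts")
  hm <- compute_metrics(half)
  expect_equal(hm$g_index, sqrt(0.5), tolerance = 1e-12)
  expect_equal(hm$g_category, "random")
})

test_that("G-index categorization follows the published bands", {
  expect_equal(categorize_g(0.10), "optimum")
  expect_equal(categorize_g(0.25), "optimum")
  expect_equal(categorize_g(0.50), "good")
  expect_equal(categorize_g(0.699), "good")
  expect_equal(categorize_g(0.7071), "random")
  expect_equal(categorize_g(0.90), "bad")
  expect_error(categorize_g(-0.1),
               class = "trunkstrat_invalid_parameter")
})

test_that("balanced classes tie accuracy to (Se + Sp) / 2 exactly", {
  for (case in 1:20) {
    n <- 14
    truth <- rep(c("pos", "neg"), each = n)
    pred <- withr::with_seed(100 + case,
                             sample(c("pos", "neg"), 2 * n,
                                    replace = TRUE))
    m <- compute_metrics(confusion_counts(truth, pred, "pos"))
    if (!anyNA(c(m$sensitivity, m$specificity))) {
      expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2,
                   tolerance = 1e-12)
    }
  }
})

test_that("G = 0 exactly when sensitivity and precision are both 1", {
  for (case in 1:30) {
    cc <- withr::with_seed(200 + case, {
      structure(list(tp = sample(0:8, 1), fn = sample(0:4, 1),
                     fp = sample(0:4, 1), tn = sample(0:8, 1),
                     positive_class = "pos"),
                class = "confusion_counts")
    })
    if (cc$tp + cc$fn == 0 || cc$tp + cc$fp == 0) next
    m <- compute_metrics(cc)
    expect_equal(m$g_index == 0,
                 m$sensitivity == 100 && m$precision == 100)
  }
})

test_that("metrics respect positive-class relabelling symmetry", {
  # Relabelling the positive class swaps TP<->TN and FP<->FN; the
  # oracle recomputes every metric from scratch on the flipped labels.
  truth <- rep(c("h", "lm"), c(9, 11))
  for (case in 1:15) {
    pred <- withr::with_seed(300 + case,
                             sample(c("h", "lm"), 20, replace = TRUE))
    m_h <- compute_metrics(confusion_counts(truth, pred, "h"))
    m_lm <- compute_metrics(confusion_counts(truth, pred, "lm"))
    expect_equal(m_h$accuracy, m_lm$accuracy)
    expect_equal(m_h$sensitivity, m_lm$specificity)
    expect_equal(m_h$specificity, m_lm$sensitivity)
  }
})

test_that("undefined denominators are flagged and excluded from summaries", {
  # no true positives predicted: precision undefined
  cc <- confusion_counts(rep(c("p", "n"), c(3, 3)), rep("n", 6), "p")
  m <- compute_metrics(cc)
  expect_true(is.na(m$precision))
  expect_match(m$undefined, "precision")

  runs <- dplyr::bind_rows(m, m, compute_metrics(
    confusion_counts(rep(c("p", "n"), c(3, 3)),
                     rep(c("p", "n"), c(3, 3)), "p")))
  s <- summarize_metric_runs(runs)
  expect_equal(s$n_excluded[s$metric == "precision"], 2)
  expect_equal(s$mean[s$metric == "precision"], 100)
})

test_that("run summaries use mean (sd) formatting with sd 0 for identical runs", {
  one <- compute_metrics(confusion_counts(
    rep(c("p", "n"), c(5, 5)), rep(c("p", "n"), c(4, 6))[c(1:5, 6:10)],
    "p"))
  runs <- dplyr::bind_rows(one, one, one)
  s <- summarize_metric_runs(runs)
  expect_true(all(s$sd == 0))
  expect_match(s$formatted[s$metric == "accuracy"],
               "^\\d+\\.\\d \\(0\\.0\\)$")
})
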