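#' Binary confusion counts
#'
#' For the high vs low-medium task, TP counts subjects correctly
#' labelled high risk, TN subjects correctly labelled low-medium, FP
#' subjects labelled high incorrectly and FN subjects labelled
#' low-medium incorrectly; the four counts partition the evaluated
#' subjects.
#'
#' @param truth,predicted Equal-length label vectors of a binary task.
#' @param positive The positive class label.
#' @return List of class `confusion_counts`: `tp`, `tn`, `fp`, `fn`,
#'   `positive_class`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  assert_that(length(truth) == length(predicted),
              "truth and predicted must have equal length",
              class = "trunkstrat_invalid_parameter")
  classes <- unique(c(truth, predicted))
  assert_that(length(classes) <= 2,
              "confusion counts are defined for binary tasks only",
              class = "trunkstrat_invalid_parameter")
  assert_that(positive %in% classes,
              "`positive` must be one of the observed labels",
              class = "trunkstrat_invalid_parameter")
  t_pos <- truth == positive
  p_pos <- predicted == positive
  structure(
    list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
         fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos),
         positive_class = positive),
    class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+FP+TN+FN) x 100%`, sensitivity
#' (recall) `TP/(TP+FN) x 100%`, specificity `TN/(TN+FP) x 100%`,
#' precision `TP/(TP+FP) x 100%`, the F1 score and the G-index, plus
#' the G-index quality category. F1 is the harmonic mean of
#' sensitivity and precision, `2 Se Pr / (Se + Pr)` on the 0-1 scale
#' (`f1_form = "sens_spec_denominator"` reproduces the alternative
#' form with Se + Sp in the denominator). The G-index is the Euclidean
#' distance from the ideal classifier in (sensitivity, precision)
#' space: `sqrt((1-Se)^2 + (1-Pr)^2)`, 0 for a perfect classifier and
#' `sqrt(0.5) ~ 0.70` for a coin-flip one.
#'
#' Metrics with a zero denominator are reported as `NA` and flagged in
#' `undefined`.
#'
#' @param counts A `confusion_counts` object.
#' @param f1_form `"harmonic"` (default) or `"sens_spec_denominator"`.
#' @return One-row tibble: accuracy, sensitivity, specificity,
#'   precision (percent), f1, g_index, g_category, undefined (comma
#'   string of any undefined metrics).
#' @export
compute_metrics <- function(counts, f1_form = c("harmonic",
                                                "sens_spec_denominator")) {
  f1_form <- match.arg(f1_form)
  assert_that(inherits(counts, "confusion_counts"),
              "`counts` must come from confusion_counts()",
              class = "trunkstrat_invalid_parameter")
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- ratio(tp + tn, tp + fp + tn + fn) * 100
  se <- ratio(tp, tp + fn) * 100
  sp <- ratio(tn, tn + fp) * 100
  pr <- ratio(tp, tp + fp) * 100
  se1 <- se / 100; sp1 <- sp / 100; pr1 <- pr / 100
  f1 <- if (anyNA(c(se1, pr1))) {
    NA_real_
  } else if (f1_form == "harmonic") {
    if (se1 + pr1 == 0) NA_real_ else 2 * se1 * pr1 / (se1 + pr1)
  } else {
    if (is.na(sp1) || se1 + sp1 == 0) NA_real_ else
      2 * se1 * pr1 / (se1 + sp1)
  }
  g <- if (anyNA(c(se1, pr1))) NA_real_ else
    sqrt((1 - se1)^2 + (1 - pr1)^2)
  undef <- c("sensitivity", "specificity", "precision", "f1",
             "g_index")[is.na(c(se, sp, pr, f1, g))]
  tibble::tibble(
    accuracy = acc, sensitivity = se, specificity = sp, precision = pr,
    f1 = f1, g_index = g,
    g_category = if (is.na(g)) NA_character_ else categorize_g(g),
    undefined = paste(undef, collapse = ","))
}

#' Categorize a G-index value
#'
#' Quality bands: `optimum` for G <= 0.25, `good` for 0.25 < G < 0.70,
#' `random` for G in [0.70, 0.71) (the band absorbs the rounding of
#' `sqrt(0.5) = 0.7071...` to the published 0.70 anchor), `bad`
#' otherwise.
#'
#' @param g Non-negative G-index value.
#' @return One of `"optimum"`, `"good"`, `"random"`, `"bad"`.
#' @export
categorize_g <- function(g) {
  assert_that(is.numeric(g) && length(g) == 1 && !is.na(g) && g >= 0,
              "`g` must be a single non-negative number",
              class = "trunkstrat_invalid_parameter")
  if (g <= 0.25) "optimum"
  else if (g < 0.70) "good"
  else if (g < 0.71) "random"
  else "bad"
}

#' Mean (sd) summary of per-run metrics
#'
#' Aggregates a tibble of per-run metric rows into the `mean (sd)`
#' presentation used for repeated balanced runs. Undefined (`NA`) runs
#' are excluded per metric, with the exclusion count reported.
#'
#' @param runs Tibble of per-run metric rows ([compute_metrics()]
#'   output, stacked).
#' @param digits Decimals in the formatted strings.
#' @return Tibble: metric, mean, sd, n_excluded, formatted.
#' @export
summarize_metric_runs <- function(runs, digits = 1) {
  metrics <- c("accuracy", "sensitivity", "specificity", "precision",
               "f1", "g_index")
  metrics <- intersect(metrics, names(runs))
  purrr::map_dfr(metrics, function(mname) {
    v <- runs[[mname]]
    d <- if (mname %in% c("f1", "g_index")) digits + 1 else digits
    tibble::tibble(
      metric = mname,
      mean = mean(v, na.rm = TRUE),
      sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0,
      n_excluded = sum(is.na(v)),
      formatted = sprintf("%.*f (%.*f)", d, mean(v, na.rm = TRUE), d,
                          if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE)
                          else 0))
  })
}
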