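GROUPINGS <- c("high_vs_lowmedium", "medium_vs_lowhigh",
               "low_vs_mediumhigh", "three_class")

#' Map three risk classes onto a classification task
#'
#' The three SBST risk classes support four tasks: each one-vs-rest
#' binary grouping (the singleton class is the positive one, the other
#' two are merged) and the full three-class task.
#'
#' @param labels Character vector of risk labels (low/medium/high).
#' @param grouping One of `"high_vs_lowmedium"`, `"medium_vs_lowhigh"`,
#'   `"low_vs_mediumhigh"`, `"three_class"`.
#' @return List: `y` (factor of task labels), `positive` (positive
#'   class, `NULL` for three_class), `binary` (logical).
#' @export
make_grouping <- function(labels, grouping = GROUPINGS) {
  grouping <- match.arg(grouping)
  labels <- tolower(as.character(labels))
  assert_that(all(labels %in% RISK_LEVELS),
              "labels must be low/medium/high",
              class = "trunkstrat_invalid_parameter")
  if (grouping == "three_class") {
    return(list(y = factor(labels, levels = RISK_LEVELS),
                positive = NULL, binary = FALSE))
  }
  pos <- sub("_vs_.*$", "", grouping)
  rest <- setdiff(RISK_LEVELS, pos)
  neg <- paste(rest, collapse = "-")
  y <- ifelse(labels == pos, pos, neg)
  list(y = factor(y, levels = c(neg, pos)), positive = pos,
       binary = TRUE)
}

#' The SVM hyperparameter grid
#'
#' Linear, 2nd-degree polynomial and Gaussian RBF kernels; three
#' regularization constants C (0.1, 1, 10) for every kernel; three RBF
#' kernel scales (0.1, 0.5, 1) crossed with C for the RBF kernel only.
#' 3 + 3 + 9 = 15 grid cells.
#'
#' @param costs Regularization constants.
#' @param rbf_scales RBF kernel scale (gamma) values.
#' @param poly_degree Polynomial degree.
#' @return Tibble with columns kernel, cost, degree, gamma.
#' @export
default_svm_grid <- function(costs = c(0.1, 1, 10),
                             rbf_scales = c(0.1, 0.5, 1),
                             poly_degree = 2) {
  dplyr::bind_rows(
    tibble::tibble(kernel = "linear", cost = costs, degree = NA_real_,
                   gamma = NA_real_),
    tibble::tibble(kernel = "polynomial", cost = costs,
                   degree = poly_degree, gamma = NA_real_),
    tidyr::expand_grid(kernel = "radial", cost = costs,
                       degree = NA_real_, gamma = rbf_scales)
  )
}

# Precompute leave-one-participant-out folds. With normalize = "fold"
# the standardization statistics are re-estimated on each training
# fold and applied to the held-out subject, so the held-out row never
# leaks into its own preprocessing; "global" reproduces
# normalize-then-split; "none" passes features through.
prepare_lopo_folds <- function(features, normalize = c("fold", "global",
                                                       "none")) {
  normalize <- match.arg(normalize)
  n <- nrow(features)
  if (normalize == "global") {
    features <- suppressWarnings(normalize_features(features)$features)
  }
  lapply(seq_len(n), function(i) {
    train <- features[-i, , drop = FALSE]
    test <- features[i, , drop = FALSE]
    if (normalize == "fold") {
      norm <- suppressWarnings(normalize_features(train))
      train <- norm$features
      test <- apply_normalization(test, norm$stats)
    }
    list(x_train = feature_matrix_values(train),
         x_test = feature_matrix_values(test))
  })
}

lopo_generic <- function(features, labels, fit_predict,
                         normalize = "fold") {
  y <- as.factor(labels)
  assert_that(nlevels(droplevels(y)) >= 2 &&
                all(table(droplevels(y)) >= 2),
              "need at least 2 subjects in each class",
              class = "trunkstrat_degenerate_labels")
  folds <- prepare_lopo_folds(features, normalize)
  predicted <- character(length(y))
  for (i in seq_along(folds)) {
    predicted[i] <- as.character(
      fit_predict(folds[[i]]$x_train, y[-i], folds[[i]]$x_test, i))
  }
  tibble::tibble(subject_id = features$subject_id,
                 truth = as.character(y), predicted = predicted)
}

#' Leave-one-participant-out SVM with hyperparameter grid
#'
#' For every cell of the kernel/C/scale grid, each subject is
#' predicted by an SVM trained on all remaining subjects
#' ([e1071::svm()]; multiclass tasks use its built-in one-vs-one
#' voting). The reported configuration is the grid cell with the
#' highest LOPO accuracy — the selection reuses the same LOPO loop, so
#' its accuracy has optimistic-selection semantics (no nested CV), as
#' in the study design this mirrors.
#'
#' @param features Feature tibble (subject_id + numeric columns).
#' @param labels Class labels, one per row of `features`.
#' @param grid Hyperparameter grid from [default_svm_grid()].
#' @param normalize `"fold"` (re-estimate standardization inside every
#'   training fold; default), `"global"`, or `"none"`.
#' @return Object of class `lopo_cv`: `predictions` (tibble
#'   subject_id, truth, predicted for the best cell), `accuracy`
#'   (percent), `best_params` (one grid row), `cell_accuracies` (grid
#'   with an accuracy column), `classifier = "svm"`.
#' @export
lopo_svm <- function(features, labels, grid = default_svm_grid(),
                     normalize = "fold") {
  assert_that(nrow(grid) >= 1, "empty hyperparameter grid",
              class = "trunkstrat_invalid_parameter")
  y <- as.factor(labels)
  assert_that(nlevels(droplevels(y)) >= 2 &&
                all(table(droplevels(y)) >= 2),
              "need at least 2 subjects in each class",
              class = "trunkstrat_degenerate_labels")
  folds <- prepare_lopo_folds(features, normalize)
  n <- length(folds)
  cell_preds <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    predicted <- character(n)
    for (i in seq_len(n)) {
      args <- list(x = folds[[i]]$x_train, y = droplevels(y[-i]),
                   kernel = cell$kernel, cost = cell$cost,
                   scale = FALSE)
      if (cell$kernel == "polynomial") {
        args$degree <- cell$degree
        args$coef0 <- 1
      }
      if (cell$kernel == "radial") args$gamma <- cell$gamma
      fit <- do.call(e1071::svm, args)
      predicted[i] <- as.character(predict(fit, folds[[i]]$x_test))
    }
    cell_preds[[g]] <- predicted
  }
  acc <- vapply(cell_preds, function(p) mean(p == as.character(y)),
                numeric(1))
  best <- which.max(acc)
  structure(
    list(predictions = tibble::tibble(subject_id = features$subject_id,
                                      truth = as.character(y),
                                      predicted = cell_preds[[best]]),
         accuracy = 100 * acc[best],
         best_params = grid[best, ],
         cell_accuracies = dplyr::mutate(grid, accuracy = 100 * acc),
         classifier = "svm"),
    class = "lopo_cv")
}

#' Leave-one-participant-out multilayer perceptron
#'
#' Each subject is predicted by an MLP (see [fit_mlp()]) trained on
#' all remaining subjects, with a fixed architecture: the input width
#' is the feature count, the hidden stack defaults to the
#' 700-500-300-100-50-15-10-5 design, and the output width is the
#' class count. Weight initialization is seeded per fold, so the whole
#' procedure is reproducible.
#'
#' @inheritParams lopo_svm
#' @param hidden Hidden-layer widths.
#' @param seed Integer seed.
#' @param ... Passed to [fit_mlp()] (epochs, learning rate, ...).
#' @return Object of class `lopo_cv` (as for [lopo_svm()], with
#'   `classifier = "mlp"` and the architecture in `best_params`).
#' @export
lopo_mlp <- function(features, labels,
                     hidden = c(700, 500, 300, 100, 50, 15, 10, 5),
                     seed = 1L, normalize = "fold", ...) {
  preds <- lopo_generic(
    features, labels,
    fit_predict = function(x_train, y_train, x_test, i) {
      fit <- fit_mlp(x_train, droplevels(y_train), hidden = hidden,
                     seed = derive_seed(seed, i), ...)
      predict(fit, x_test)
    },
    normalize = normalize)
  structure(
    list(predictions = preds,
         accuracy = 100 * mean(preds$predicted == preds$truth),
         best_params = tibble::tibble(
           hidden = paste(hidden, collapse = "-")),
         cell_accuracies = NULL,
         classifier = "mlp"),
    class = "lopo_cv")
}

#' @export
print.lopo_cv <- function(x, ...) {
  cat(sprintf("<lopo_cv> %s, %d subjects, accuracy %.1f%%\n",
              x$classifier, nrow(x$predictions), x$accuracy))
  invisible(x)
}

#' Repeated balanced subsampling for a two-class task
#'
#' Class imbalance biases distance-based classifiers, so each run
#' keeps every subject of the smaller class and draws an equally sized
#' uniform sample (without replacement) from the larger class. With 28
#' high-risk versus 56 low-medium subjects each run holds 56 subjects,
#' 28 per class. Runs get seeds derived from `seed`, so the family of
#' index sets is reproducible.
#'
#' @param y Binary label vector/factor.
#' @param n_runs Number of balanced runs.
#' @param seed Integer seed.
#' @return List of `n_runs` sorted integer index vectors.
#' @export
balanced_subsample_runs <- function(y, n_runs = 10, seed = 1L) {
  y <- as.character(y)
  classes <- unique(y)
  assert_that(length(classes) == 2,
              "balanced subsampling is defined for two-class tasks",
              class = "trunkstrat_invalid_parameter")
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(classes, minority)
  idx_min <- which(y == minority)
  idx_maj <- which(y == majority)
  lapply(seq_len(n_runs), function(r) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, r))
    sort(c(idx_min, sample(idx_maj, length(idx_min))))
  })
}

#' Run one classification experiment
#'
#' The full supervised protocol for one task: map risk labels onto the
#' requested grouping; for a binary grouping, repeat `n_balance_runs`
#' balanced subsamples and run leave-one-participant-out
#' cross-validation on each, scoring every run with the full metric
#' suite and reporting mean and SD over runs; for the three-class
#' task, run a single LOPO pass and report overall accuracy with
#' per-class recalls (no binary G-index is defined there).
#'
#' @param features Feature tibble (subject_id + numeric columns).
#' @param manifest Subject metadata tibble with `sbst_label`, rows
#'   aligned with `features`.
#' @param grouping Task, see [make_grouping()].
#' @param classifier `"svm"` or `"mlp"`.
#' @param svm_grid Grid for [lopo_svm()].
#' @param mlp_hidden Architecture for [lopo_mlp()].
#' @param n_balance_runs Balanced subsample repetitions (binary only).
#' @param seed Integer seed.
#' @param normalize Normalization placement, see [lopo_svm()].
#' @param ... Passed to the classifier backend.
#' @return Object of class `risk_experiment`: `grouping`,
#'   `classifier`, `runs` (per-run metric rows), `summary`
#'   (mean (sd) table), `per_class_recall` (three-class only), `fits`
#'   (list of `lopo_cv`), `config`.
#' @export
run_experiment <- function(features, manifest,
                           grouping = "high_vs_lowmedium",
                           classifier = c("svm", "mlp"),
                           svm_grid = default_svm_grid(),
                           mlp_hidden = c(700, 500, 300, 100, 50, 15, 10,
                                          5),
                           n_balance_runs = 10, seed = 1L,
                           normalize = "fold", ...) {
  classifier <- match.arg(classifier)
  assert_that(nrow(features) == nrow(manifest) &&
                all(features$subject_id == manifest$subject_id),
              "features and manifest must align row-by-row",
              class = "trunkstrat_invalid_parameter")
  task <- make_grouping(manifest$sbst_label, grouping)

  run_lopo <- function(feats, y, run_seed) {
    if (classifier == "svm") {
      lopo_svm(feats, y, grid = svm_grid, normalize = normalize, ...)
    } else {
      lopo_mlp(feats, y, hidden = mlp_hidden, seed = run_seed,
               normalize = normalize, ...)
    }
  }

  if (task$binary) {
    run_sets <- balanced_subsample_runs(task$y, n_runs = n_balance_runs,
                                        seed = seed)
    fits <- vector("list", n_balance_runs)
    runs <- vector("list", n_balance_runs)
    for (r in seq_len(n_balance_runs)) {
      idx <- run_sets[[r]]
      fit <- run_lopo(features[idx, , drop = FALSE], task$y[idx],
                      derive_seed(seed, 1000L + r))
      counts <- confusion_counts(fit$predictions$truth,
                                 fit$predictions$predicted,
                                 positive = task$positive)
      runs[[r]] <- dplyr::mutate(compute_metrics(counts), run = r,
                                 .before = 1)
      fits[[r]] <- fit
    }
    runs <- dplyr::bind_rows(runs)
    out <- list(grouping = grouping, classifier = classifier,
                positive = task$positive, runs = runs,
                summary = summarize_metric_runs(runs),
                per_class_recall = NULL, fits = fits,
                config = list(n_balance_runs = n_balance_runs,
                              seed = seed, normalize = normalize))
  } else {
    fit <- run_lopo(features, task$y, derive_seed(seed, 1000L))
    preds <- fit$predictions
    recalls <- vapply(RISK_LEVELS, function(cl) {
      100 * mean(preds$predicted[preds$truth == cl] == cl)
    }, numeric(1))
    runs <- tibble::tibble(run = 1L,
                           accuracy = 100 * mean(preds$predicted ==
                                                   preds$truth))
    out <- list(grouping = grouping, classifier = classifier,
                positive = NULL, runs = runs,
                summary = summarize_metric_runs(runs),
                per_class_recall = tibble::tibble(
                  class = RISK_LEVELS, recall = unname(recalls)),
                fits = list(fit),
                config = list(seed = seed, normalize = normalize))
  }
  structure(out, class = "risk_experiment")
}

#' @export
print.risk_experiment <- function(x, ...) {
  cat(sprintf("<risk_experiment> %s, %s\n", x$grouping, x$classifier))
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("  accuracy: %s over %d run(s)\n", acc$formatted,
              nrow(x$runs)))
  invisible(x)
}

#' @export
#' @method tidy risk_experiment
tidy.risk_experiment <- function(x, ...) x$runs

#' @export
#' @method glance risk_experiment
glance.risk_experiment <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean),
                          paste0(x$summary$metric, "_mean"))
  dplyr::bind_cols(
    tibble::tibble(grouping = x$grouping, classifier = x$classifier,
                   n_runs = nrow(x$runs)),
    tibble::as_tibble(wide))
}

#' Plot per-run metrics of an experiment
#'
#' @param object A `risk_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot risk_experiment
autoplot.risk_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$runs,
    cols = dplyr::any_of(c("accuracy", "sensitivity", "specificity",
                           "precision")),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric,
                                     y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("%s / %s over %d balanced runs",
                                  object$grouping, object$classifier,
                                  nrow(object$runs))) +
    ggplot2::theme_minimal()
}

# The 15 nonempty feature-set combinations, singletons first, then
# pairs, triples and the full set, each in FS/FT16/Wii/ADT order.
feature_set_combinations <- function() {
  combos <- unlist(lapply(1:4, function(m) {
    asplit(utils::combn(FEATURE_SETS, m), 2)
  }), recursive = FALSE)
  lapply(combos, function(sel) FEATURE_SETS[FEATURE_SETS %in% sel])
}

#' Full factorial sweep of the feature-set combinations
#'
#' Runs [run_experiment()] for every nonempty combination of the four
#' feature sets (2^4 - 1 = 15 cases) on one grouping/classifier, and
#' tabulates the metric suite as `mean (sd)` strings, one row per
#' combination.
#'
#' @inheritParams run_experiment
#' @param features Feature tibble containing all four sets
#'   ([cohort_features()] with the default `sets`).
#' @return Object of class `factorial_result`: `table` (15-row tibble:
#'   combination, then one formatted column per metric), `experiments`
#'   (named list of `risk_experiment`).
#' @export
run_full_factorial <- function(features, manifest,
                               grouping = "high_vs_lowmedium",
                               classifier = "svm",
                               svm_grid = default_svm_grid(),
                               n_balance_runs = 10, seed = 1L,
                               normalize = "fold", ...) {
  combos <- feature_set_combinations()
  experiments <- vector("list", length(combos))
  rows <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    sel <- combos[[i]]
    label <- paste(sel, collapse = "+")
    exp_i <- run_experiment(assemble_feature_set(features, sel),
                            manifest, grouping = grouping,
                            classifier = classifier,
                            svm_grid = svm_grid,
                            n_balance_runs = n_balance_runs,
                            seed = seed, normalize = normalize, ...)
    experiments[[i]] <- exp_i
    wide <- stats::setNames(as.list(exp_i$summary$formatted),
                            exp_i$summary$metric)
    rows[[i]] <- dplyr::bind_cols(tibble::tibble(combination = label),
                                  tibble::as_tibble(wide))
    names(experiments)[i] <- label
  }
  structure(list(table = dplyr::bind_rows(rows),
                 experiments = experiments),
            class = "factorial_result")
}

#' @export
print.factorial_result <- function(x, ...) {
  cat("<factorial_result>\n")
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @export
#' @method tidy factorial_result
tidy.factorial_result <- function(x, ...) {
  purrr::map_dfr(names(x$experiments), function(lbl) {
    dplyr::mutate(glance(x$experiments[[lbl]]), combination = lbl,
                  .before = 1)
  })
}
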