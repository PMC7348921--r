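#' End-to-end pipeline configuration
#'
#' Collects every knob of an end-to-end run — cohort source, stage
#' switches, cluster-number range, classification experiment matrix,
#' grids, seeds — in one explicit object, so a run is reproducible
#' from its configuration alone.
#'
#' @param cohort A [cohort_config()] to simulate from, or a directory
#'   path holding a written cohort (manifest.csv + `*.rec` files).
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed for every stage.
#' @param do_clustering,do_classification,do_factorial Stage switches.
#' @param k_range Cluster counts scanned by the Calinski-Harabasz
#'   criterion.
#' @param groupings Character vector of classification tasks (see
#'   [make_grouping()]).
#' @param classifiers Character vector, subset of `c("svm", "mlp")`.
#' @param svm_grid Hyperparameter grid for SVM experiments.
#' @param mlp_hidden MLP hidden-layer widths.
#' @param n_balance_runs Balanced subsample repetitions.
#' @param normalize Normalization placement (see [lopo_svm()]).
#' @param cutoff_hz Cycle-detection low-pass cutoff, Hz.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            out_dir = tempfile("trunkstrat_run_"),
                            seed = 1L,
                            do_clustering = TRUE,
                            do_classification = TRUE,
                            do_factorial = FALSE,
                            k_range = 2:6,
                            groupings = "high_vs_lowmedium",
                            classifiers = "svm",
                            svm_grid = default_svm_grid(),
                            mlp_hidden = c(700, 500, 300, 100, 50, 15,
                                           10, 5),
                            n_balance_runs = 10,
                            normalize = "fold",
                            cutoff_hz = 1) {
  assert_that(do_clustering || do_classification || do_factorial,
              "at least one stage must be enabled",
              class = "trunkstrat_config_error")
  assert_that(is_count(seed), "`seed` must be a single integer",
              class = "trunkstrat_config_error")
  classifiers <- match.arg(classifiers, c("svm", "mlp"),
                           several.ok = TRUE)
  structure(
    list(cohort = cohort, out_dir = out_dir, seed = as.integer(seed),
         do_clustering = do_clustering,
         do_classification = do_classification,
         do_factorial = do_factorial,
         k_range = k_range, groupings = groupings,
         classifiers = classifiers, svm_grid = svm_grid,
         mlp_hidden = mlp_hidden, n_balance_runs = n_balance_runs,
         normalize = normalize, cutoff_hz = cutoff_hz),
    class = "pipeline_config")
}

# Scan the cluster number over the standard kinematic feature groups:
# angular velocity alone, linear acceleration alone, and the combined
# full signal.
cluster_stage <- function(features, manifest, k_range, seed) {
  groups <- list(
    angular_velocity = "^fs_gyro_",
    linear_acceleration = "^fs_accel_",
    combination = "^fs_")
  scans <- purrr::imap(groups, function(pattern, name) {
    cols <- grep(pattern, names(features), value = TRUE)
    sub <- features[, c("subject_id", cols)]
    norm <- suppressWarnings(normalize_features(sub)$features)
    scan_cluster_number(norm, k_range = k_range, seed = seed)
  })
  index_table <- purrr::imap_dfr(scans, function(s, name) {
    dplyr::mutate(s$table, feature_group = name, .before = 1)
  })
  best <- scans$combination
  eval_best <- majority_label_clusters(
    best$solutions[[as.character(best$best_k)]], manifest$sbst_label)
  list(index_table = index_table, scans = scans, eval = eval_best)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the cohort, preprocesses every recording,
#' builds the full feature table, then runs the enabled stages:
#' cluster-number scan with majority-label evaluation, the configured
#' classification experiments, and optionally the 15-combination
#' feature-set factorial. All results are written to `out_dir` as
#' delimited text, and the run is fully determined by
#' `(config, config$seed)`.
#'
#' Bundle files: `manifest.csv`, `features.csv`, `ch_index_by_k.csv`
#' (index-vs-k per feature group), `cluster_assignments.csv`,
#' `classification_results.csv` (grouping x classifier x metric, mean,
#' sd and `mean (sd)`), `feature_combinations.csv` (15 rows when the
#' factorial stage is on) and `run_manifest.txt` (config echo).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with the in-memory results
#'   (`cohort`, `features`, `clustering`, `experiments`, `factorial`,
#'   `files`), invisibly writable pieces already on disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must be built with pipeline_config()",
              class = "trunkstrat_config_error")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "trunkstrat_pipeline_error")
    })
  }

  cohort <- stage("cohort", {
    if (is.character(config$cohort)) read_cohort(config$cohort)
    else generate_cohort(config$cohort)
  })
  write_manifest(cohort$manifest, file.path(out, "manifest.csv"))

  features <- stage("features",
                    cohort_features(cohort, cutoff_hz = config$cutoff_hz))
  write_features(features, file.path(out, "features.csv"))

  clustering <- NULL
  if (config$do_clustering) {
    clustering <- stage("clustering", cluster_stage(
      features, cohort$manifest, config$k_range,
      derive_seed(config$seed, 11L)))
    write.csv(clustering$index_table,
              file.path(out, "ch_index_by_k.csv"), row.names = FALSE)
    best <- clustering$scans$combination
    assign_tbl <- dplyr::mutate(
      best$solutions[[as.character(best$best_k)]]$assignments,
      cluster_label = clustering$eval$predicted,
      truth = cohort$manifest$sbst_label)
    write.csv(assign_tbl, file.path(out, "cluster_assignments.csv"),
              row.names = FALSE)
  }

  experiments <- NULL
  if (config$do_classification) {
    experiments <- stage("classification", {
      grid <- tidyr::expand_grid(grouping = config$groupings,
                                 classifier = config$classifiers)
      purrr::pmap(grid, function(grouping, classifier) {
        run_experiment(features, cohort$manifest, grouping = grouping,
                       classifier = classifier,
                       svm_grid = config$svm_grid,
                       mlp_hidden = config$mlp_hidden,
                       n_balance_runs = config$n_balance_runs,
                       seed = derive_seed(config$seed, 13L),
                       normalize = config$normalize)
      })
    })
    results <- purrr::map_dfr(experiments, function(e) {
      dplyr::mutate(e$summary, grouping = e$grouping,
                    classifier = e$classifier, .before = 1)
    })
    write.csv(results, file.path(out, "classification_results.csv"),
              row.names = FALSE)
  }

  factorial <- NULL
  if (config$do_factorial) {
    factorial <- stage("factorial", run_full_factorial(
      features, cohort$manifest, grouping = config$groupings[1],
      classifier = config$classifiers[1], svm_grid = config$svm_grid,
      n_balance_runs = config$n_balance_runs,
      seed = derive_seed(config$seed, 17L),
      normalize = config$normalize))
    write.csv(factorial$table,
              file.path(out, "feature_combinations.csv"),
              row.names = FALSE)
  }

  manifest_lines <- c(
    "trunkstrat run manifest",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("trunkstrat"))),
    sprintf("seed: %d", config$seed),
    sprintf("subjects: %d", nrow(cohort$manifest)),
    sprintf("stages: %s", paste(
      c("clustering", "classification",
        "factorial")[c(config$do_clustering, config$do_classification,
                       config$do_factorial)], collapse = ", ")),
    sprintf("groupings: %s", paste(config$groupings, collapse = ", ")),
    sprintf("classifiers: %s", paste(config$classifiers,
                                     collapse = ", ")),
    sprintf("n_balance_runs: %d", config$n_balance_runs),
    sprintf("normalize: %s", config$normalize),
    sprintf("cutoff_hz: %g", config$cutoff_hz))
  writeLines(manifest_lines, file.path(out, "run_manifest.txt"))

  structure(list(cohort = cohort, features = features,
                 clustering = clustering, experiments = experiments,
                 factorial = factorial, out_dir = out,
                 files = list.files(out)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects; bundle in %s\n",
              nrow(x$cohort$manifest), x$out_dir))
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  invisible(x)
}

#' Score a saved predictions table
#'
#' Recomputes the binary metric suite from a table of per-subject true
#' and predicted labels (e.g. re-read from a bundle on disk).
#'
#' @param predictions Data frame with columns `truth` and `predicted`.
#' @param positive Positive class label.
#' @return One-row metrics tibble (see [compute_metrics()]).
#' @export
evaluate_predictions <- function(predictions, positive) {
  compute_metrics(confusion_counts(predictions$truth,
                                   predictions$predicted, positive))
}
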