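# k-means++ seeding: first centre uniform, each next centre sampled
# with probability proportional to squared distance to the nearest
# centre already chosen.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' K-means clustering of a feature table
#'
#' Lloyd's algorithm (squared-Euclidean assignment,
#' [stats::kmeans()]) started from k-means++ seeds, repeated
#' `n_restarts` times; the solution with the smallest total
#' within-cluster sum of squares is kept. Deterministic given `seed`.
#'
#' @param features Feature tibble (subject_id + numeric columns),
#'   typically standardized first.
#' @param k Number of clusters (2 <= k < number of subjects).
#' @param seed Integer seed.
#' @param n_restarts Independent k-means++ restarts.
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return Object of class `cluster_solution`: `k`, `assignments`
#'   (tibble subject_id, cluster), `centroids`, `ssb`, `ssw`, `n`,
#'   `ch_index`.
#' @export
kmeans_cluster <- function(features, k, seed = 1L, n_restarts = 10,
                           iter_max = 100) {
  x <- feature_matrix_values(features)
  n <- nrow(x)
  assert_that(is_count(k) && k >= 2, "`k` must be an integer >= 2",
              class = "trunkstrat_invalid_parameter")
  assert_that(k < n, "`k` must be smaller than the number of subjects",
              class = "trunkstrat_invalid_parameter")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(x, centers = centers, iter.max = iter_max,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  assert_that(!is.null(best), "k-means failed on every restart",
              class = "trunkstrat_cluster_error")
  solution <- structure(
    list(k = as.integer(k),
         assignments = tibble::tibble(subject_id = features$subject_id,
                                      cluster = as.integer(best$cluster)),
         centroids = best$centers,
         ssb = best$betweenss,
         ssw = best$tot.withinss,
         n = n,
         ch_index = NA_real_),
    class = "cluster_solution")
  solution$ch_index <- calinski_harabasz(solution)
  solution
}

#' Calinski-Harabasz cluster-validity index
#'
#' `CH = (SSB / SSW) * ((N - k) / (k - 1))`, where SSB is the
#' between-cluster sum of squares (cluster sizes times squared distance
#' of each centroid to the grand mean), SSW the total within-cluster
#' sum of squares, N the number of observations and k the number of
#' clusters. Larger is better: compact clusters far apart. The index
#' is invariant under uniform rescaling of the coordinates (both sums
#' scale identically).
#'
#' @param solution A `cluster_solution`, or a list with numeric
#'   elements `ssb`, `ssw`, `n`, `k`.
#' @return The index value; `Inf` (with a warning) when `SSW = 0`.
#' @export
calinski_harabasz <- function(solution) {
  ssb <- solution$ssb
  ssw <- solution$ssw
  n <- solution$n
  k <- solution$k
  assert_that(is.numeric(ssb) && is.numeric(ssw) && ssb >= 0 && ssw >= 0,
              "SSB and SSW must be non-negative numbers",
              class = "trunkstrat_invalid_parameter")
  assert_that(k > 1 && k < n, "need 1 < k < N",
              class = "trunkstrat_invalid_parameter")
  if (ssw == 0) {
    warn("SSW is zero; Calinski-Harabasz index is infinite")
    return(Inf)
  }
  (ssb / ssw) * ((n - k) / (k - 1))
}

#' Choose the number of clusters by the Calinski-Harabasz criterion
#'
#' Runs [kmeans_cluster()] for every k in `k_range` and picks the k
#' whose index is largest.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate cluster counts (all < number of subjects).
#' @return Object of class `ch_scan`: `best_k`, `table` (tibble k,
#'   ch_index, ssb, ssw) and `solutions` (list keyed by k).
#' @export
scan_cluster_number <- function(features, k_range = 2:6, seed = 1L,
                                n_restarts = 10) {
  assert_that(length(k_range) >= 1, "`k_range` must be nonempty",
              class = "trunkstrat_invalid_parameter")
  n <- nrow(features)
  assert_that(max(k_range) < n, "max(k_range) must be < number of subjects",
              class = "trunkstrat_invalid_parameter")
  solutions <- lapply(seq_along(k_range), function(i) {
    kmeans_cluster(features, k_range[i],
                   seed = derive_seed(seed, i), n_restarts = n_restarts)
  })
  names(solutions) <- as.character(k_range)
  tbl <- tibble::tibble(
    k = as.integer(k_range),
    ch_index = vapply(solutions, `[[`, numeric(1), "ch_index"),
    ssb = vapply(solutions, `[[`, numeric(1), "ssb"),
    ssw = vapply(solutions, `[[`, numeric(1), "ssw"))
  structure(list(best_k = tbl$k[which.max(tbl$ch_index)],
                 table = tbl, solutions = solutions),
            class = "ch_scan")
}

#' @export
#' @method tidy ch_scan
tidy.ch_scan <- function(x, ...) x$table

#' @export
#' @method glance ch_scan
glance.ch_scan <- function(x, ...) {
  tibble::tibble(best_k = x$best_k,
                 best_ch_index = max(x$table$ch_index))
}

#' Plot the index-versus-k curve of a cluster-number scan
#'
#' @param object A `ch_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ch_scan
autoplot.ch_scan <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$k, y = .data$ch_index)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = object$table[
      object$table$k == object$best_k, ],
      colour = "firebrick", size = 3) +
    ggplot2::labs(x = "number of clusters k",
                  y = "Calinski-Harabasz index") +
    ggplot2::theme_minimal()
}

#' Label clusters by their modal risk class
#'
#' Each cluster is labelled with the risk class held by the largest
#' share of its members (ties broken toward the lexicographically
#' smaller label, with a warning); every member then inherits the
#' cluster label, and the induced labelling is scored against the
#' truth.
#'
#' @param solution A `cluster_solution`.
#' @param true_labels Character vector of risk labels, one per subject
#'   in the order of `solution$assignments`.
#' @return List: `cluster_labels` (tibble cluster, label), `predicted`
#'   (per-subject labels), `accuracy` (percent), `confusion`
#'   (contingency table of truth vs predicted).
#' @export
majority_label_clusters <- function(solution, true_labels) {
  assign <- solution$assignments
  assert_that(length(true_labels) == nrow(assign),
              "need one true label per clustered subject",
              class = "trunkstrat_invalid_parameter")
  labels_by_cluster <- split(as.character(true_labels), assign$cluster)
  modal <- vapply(labels_by_cluster, function(lb) {
    counts <- sort(table(lb), decreasing = TRUE)
    winners <- names(counts)[counts == counts[1]]
    if (length(winners) > 1) {
      warn("modal-label tie; taking the lexicographically smaller label")
    }
    sort(winners)[1]
  }, character(1))
  predicted <- unname(modal[as.character(assign$cluster)])
  list(
    cluster_labels = tibble::tibble(cluster = as.integer(names(modal)),
                                    label = unname(modal)),
    predicted = predicted,
    accuracy = 100 * mean(predicted == as.character(true_labels)),
    confusion = table(truth = as.character(true_labels),
                      predicted = predicted)
  )
}
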