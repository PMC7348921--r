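# Shared fixtures, all built in code at test time.

# Gaussian blobs with known generative cluster structure.
make_blobs <- function(n_per = 10, centers = rbind(c(0, 0), c(8, 8)),
                       sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(rnorm(n_per, centers[i, 1], sd),
            rnorm(n_per, centers[i, 2], sd))
    }))
  })
  tibble::tibble(subject_id = sprintf("B%03d", seq_len(nrow(x))),
                 f1 = x[, 1], f2 = x[, 2])
}

# A small feature table with a linearly separable two-class signal.
make_separable <- function(n_per = 8, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    x1 <- cbind(rnorm(n_per, 0, 0.5), rnorm(n_per, 0, 0.5))
    x2 <- cbind(rnorm(n_per, gap, 0.5), rnorm(n_per, gap, 0.5))
  })
  list(
    features = tibble::tibble(
      subject_id = sprintf("P%03d", seq_len(2 * n_per)),
      f1 = c(x1[, 1], x2[, 1]), f2 = c(x1[, 2], x2[, 2])),
    labels = rep(c("neg", "pos"), each = n_per)
  )
}

# A random cycle stack (n_cycles x 101) for aggregation oracles.
rand_stack <- function(n_cycles, seed) {
  withr::with_seed(seed,
    matrix(runif(n_cycles * 101, -5, 5), n_cycles, 101))
}

# Naive loop implementation of the RMS cycle aggregation (the oracle;
# deliberately written index-by-index, independent of the vectorized
# implementation).
naive_rms_aggregate <- function(stack) {
  n <- nrow(stack)
  out <- numeric(100)
  for (i in 2:101) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + stack[j, i]^2
    out[i - 1] <- sqrt(acc / n)
  }
  out
}

# Naive double-loop SSB/SSW from raw points and assignments (the
# Calinski-Harabasz oracle).
naive_ssb_ssw <- function(x, cluster) {
  grand <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (cl in unique(cluster)) {
    rows <- which(cluster == cl)
    cen <- colMeans(x[rows, , drop = FALSE])
    ssb <- ssb + length(rows) * sum((cen - grand)^2)
    for (r in rows) ssw <- ssw + sum((x[r, ] - cen)^2)
  }
  list(ssb = ssb, ssw = ssw)
}

# A tiny noise-free subject for deterministic kinematics checks.
noise_free_params <- function(period = 2, rom = 50, vs = 1,
                              duration = 14) {
  subject_sim_params(cycle_period_mean = period, cycle_period_cv = 0,
                     rom_amplitude = rom, velocity_scale = vs,
                     imu_noise_sd = 0, cop_noise_sd = 0,
                     task_duration = duration)
}

# Small cohort config for fast end-to-end runs.
tiny_cohort_config <- function(n = c(low = 3, medium = 3, high = 3),
                               seed = 5) {
  cohort_config(group_sizes = n, seed = seed)
}
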