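# Feedforward multilayer perceptron with sigmoid hidden layers and a
# softmax output, trained by full-batch Adam on the cross-entropy loss.
# Written in plain matrix algebra: the architecture (an arbitrary stack
# of hidden layers) is part of the experiment design, so the engine is
# kept transparent and dependency-free.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit a multilayer perceptron classifier
#'
#' @param x Numeric matrix, observations x features.
#' @param y Factor of class labels (its level order fixes the output
#'   units and the tie-break order at prediction time).
#' @param hidden Integer vector of hidden-layer widths.
#' @param seed Integer seed for the weight initialization.
#' @param max_epochs Maximum full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param tol Early-stopping threshold: training stops once the
#'   absolute epoch-to-epoch change in training loss stays below `tol`
#'   for `patience` consecutive epochs (a loss plateau).
#' @param patience Plateau length for early stopping.
#' @return Object of class `mlp_fit` (weights, biases, levels, loss
#'   trace).
#' @export
fit_mlp <- function(x, y, hidden = c(700, 500, 300, 100, 50, 15, 10, 5),
                    seed = 1L, max_epochs = 500, learning_rate = 1e-3,
                    tol = 1e-6, patience = 10) {
  y <- as.factor(y)
  assert_that(nlevels(y) >= 2, "need at least 2 classes",
              class = "trunkstrat_degenerate_labels")
  assert_that(all(table(y) >= 1), "every class needs an observation",
              class = "trunkstrat_degenerate_labels")
  x <- as.matrix(x)
  n <- nrow(x)
  sizes <- c(ncol(x), hidden, nlevels(y))
  n_layers <- length(sizes) - 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    # Glorot-scaled init keeps sigmoid activations out of saturation.
    s <- sqrt(2 / (sizes[l] + sizes[l + 1]))
    w[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, s),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  y_onehot <- matrix(0, n, nlevels(y))
  y_onehot[cbind(seq_len(n), as.integer(y))] <- 1

  adam_m_w <- lapply(w, function(m) m * 0)
  adam_v_w <- lapply(w, function(m) m * 0)
  adam_m_b <- lapply(b, function(v) v * 0)
  adam_v_b <- lapply(b, function(v) v * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0

  loss_trace <- numeric(0)
  prev_loss <- Inf
  plateau <- 0
  for (epoch in seq_len(max_epochs)) {
    a <- vector("list", n_layers + 1)
    a[[1]] <- x
    for (l in seq_len(n_layers - 1)) {
      a[[l + 1]] <- sigmoid(sweep(a[[l]] %*% w[[l]], 2, b[[l]], "+"))
    }
    p <- softmax_rows(sweep(a[[n_layers]] %*% w[[n_layers]], 2,
                            b[[n_layers]], "+"))
    a[[n_layers + 1]] <- p
    loss <- -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
    loss_trace <- c(loss_trace, loss)

    delta <- (p - y_onehot) / n
    step <- step + 1
    for (l in rev(seq_len(n_layers))) {
      gw <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(w[[l]])) * a[[l]] * (1 - a[[l]])
      }
      adam_m_w[[l]] <- beta1 * adam_m_w[[l]] + (1 - beta1) * gw
      adam_v_w[[l]] <- beta2 * adam_v_w[[l]] + (1 - beta2) * gw^2
      adam_m_b[[l]] <- beta1 * adam_m_b[[l]] + (1 - beta1) * gb
      adam_v_b[[l]] <- beta2 * adam_v_b[[l]] + (1 - beta2) * gb^2
      mw_hat <- adam_m_w[[l]] / (1 - beta1^step)
      vw_hat <- adam_v_w[[l]] / (1 - beta2^step)
      mb_hat <- adam_m_b[[l]] / (1 - beta1^step)
      vb_hat <- adam_v_b[[l]] / (1 - beta2^step)
      w[[l]] <- w[[l]] - learning_rate * mw_hat / (sqrt(vw_hat) + eps)
      b[[l]] <- b[[l]] - learning_rate * mb_hat / (sqrt(vb_hat) + eps)
    }

    if (abs(prev_loss - loss) < tol) {
      plateau <- plateau + 1
      if (plateau >= patience) break
    } else {
      plateau <- 0
    }
    prev_loss <- loss
  }

  structure(list(weights = w, biases = b, levels = levels(y),
                 loss_trace = loss_trace),
            class = "mlp_fit")
}

#' @rdname fit_mlp
#' @param object An `mlp_fit`.
#' @param newdata Numeric matrix of observations to classify.
#' @param ... Unused.
#' @return Factor of predicted labels (vote ties go to the lowest
#'   class index).
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  a <- as.matrix(newdata)
  n_layers <- length(object$weights)
  for (l in seq_len(n_layers - 1)) {
    a <- sigmoid(sweep(a %*% object$weights[[l]], 2, object$biases[[l]],
                       "+"))
  }
  p <- softmax_rows(sweep(a %*% object$weights[[n_layers]], 2,
                          object$biases[[n_layers]], "+"))
  # max.col with ties.method = "first" -> lowest class index on ties
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}
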