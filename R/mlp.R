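# Feed-forward multilayer perceptron for binary classification.
#
# Small, dependency-free implementation: ReLU hidden layers, sigmoid output,
# binary cross-entropy loss with an L2 penalty alpha * ||W||^2 / (2n), and
# minibatch Adam updates. Sized for profile matrices (hundreds of features,
# thousands of samples), where full deep-learning frameworks are overkill.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fit a feed-forward neural network (MLP) for binary classification
#'
#' ReLU hidden layers, sigmoid output, binary cross-entropy plus L2 weight
#' penalty, trained with minibatch Adam. Weights use He initialization under
#' a fixed seed, so training is reproducible run-to-run.
#'
#' @param x Numeric matrix, samples x features (no missing values).
#' @param y 0/1 labels, one per sample.
#' @param hidden Hidden-layer sizes (default `c(180, 90, 40)`).
#' @param learning_rate Initial Adam step size (default 1e-4).
#' @param alpha L2 regularization coefficient (default 0.1); the penalty is
#'   `alpha/(2n) * sum(W^2)` over weight matrices (biases unpenalized).
#' @param max_iter Maximum training epochs (default 1000).
#' @param batch_size Minibatch size (default 200, capped at n).
#' @param tol Stop when the best epoch loss fails to improve by more than
#'   `tol` for `n_iter_no_change` consecutive epochs (default 1e-5).
#' @param n_iter_no_change Patience for the stopping rule (default 10).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return `pp_mlp` object (weights, biases, training loss trace).
#' @export
mlp_fit <- function(x, y, hidden = c(180, 90, 40), learning_rate = 1e-4,
                    alpha = 0.1, max_iter = 1000, batch_size = 200,
                    tol = 1e-5, n_iter_no_change = 10, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  n <- nrow(x); d <- ncol(x)
  sizes <- c(d, hidden, 1L)
  L <- length(sizes) - 1L

  set.seed(as.integer(seed))
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb

  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  batch_size <- min(batch_size, n)
  loss_trace <- numeric(0)
  best <- Inf; stall <- 0L

  for (epoch in seq_len(max_iter)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]; yb <- y[idx]
      m <- length(idx)

      # forward
      a <- vector("list", L + 1); a[[1]] <- xb
      for (l in seq_len(L)) {
        z <- a[[l]] %*% W[[l]]
        z <- sweep(z, 2, b[[l]], "+")
        a[[l + 1]] <- if (l < L) relu(z) else sigmoid(z)
      }
      p <- pmin(pmax(a[[L + 1]][, 1], 1e-12), 1 - 1e-12)
      epoch_loss <- epoch_loss +
        sum(-(yb * log(p) + (1 - yb) * log(1 - p)))

      # backward
      delta <- matrix((p - yb) / m, ncol = 1)
      t_step <- t_step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta) + (alpha / n) * W[[l]]
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^t_step)
        vhW <- vW[[l]] / (1 - beta2^t_step)
        mhb <- mb[[l]] / (1 - beta1^t_step)
        vhb <- vb[[l]] / (1 - beta2^t_step)
        W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
      }
    }
    epoch_loss <- epoch_loss / n +
      alpha / (2 * n) * sum(vapply(W, function(w) sum(w^2), 0))
    loss_trace <- c(loss_trace, epoch_loss)
    if (epoch_loss < best - tol) {
      best <- epoch_loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= n_iter_no_change) break
    }
  }
  structure(list(W = W, b = b, hidden = hidden, loss = loss_trace,
                 features = colnames(x)),
            class = "pp_mlp")
}

#' Predict positive-class probabilities from a fitted MLP
#'
#' @param model A `pp_mlp` from [mlp_fit()].
#' @param x Numeric matrix with the same feature columns used for fitting.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
mlp_predict <- function(model, x) {
  stopifnot(inherits(model, "pp_mlp"), is.matrix(x))
  a <- x
  L <- length(model$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < L) relu(z) else sigmoid(z)
  }
  a[, 1]
}

#' @export
print.pp_mlp <- function(x, ...) {
  cat(sprintf("<pp_mlp> layers %s, %d epoch(s), final loss %.5f\n",
              paste(x$hidden, collapse = "-"), length(x$loss),
              utils::tail(x$loss, 1)))
  invisible(x)
}
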