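#' Plain RBF network baseline (no metaheuristic search)
#'
#' The conventional RBF recipe: centres chosen by seeded farthest-point
#' sampling from the training inputs, a shared width equal to the mean
#' nearest-centre distance, and the linear output layer fitted by least
#' squares ([fit_rbf_output()]). Deterministic per seed.
#'
#' @param X Training inputs (`n x d`, standardized units recommended).
#' @param y Training targets.
#' @param K Number of hidden units, at most `n`.
#' @param seed Integer seed (selects the first centre).
#' @return An [rbf_network()].
#' @export
train_plain_rbf <- function(X, y, K = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (K > n) stop("K must not exceed the number of training records",
                  call. = FALSE)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  centers_idx <- integer(K)
  centers_idx[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[centers_idx[1L], ])^2)
    for (k in seq(2L, K)) {
      centers_idx[k] <- which.max(d2)  # farthest from the chosen set
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers_idx[k], ])^2))
    }
  }
  centers <- X[centers_idx, , drop = FALSE]
  if (K > 1L) {
    cd <- as.matrix(stats::dist(centers))
    diag(cd) <- Inf
    sigma <- mean(apply(cd, 1L, min))
  } else {
    sigma <- mean(sqrt(rowSums(sweep(X, 2L, centers[1L, ])^2)))
  }
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  out <- fit_rbf_output(centers, rep(sigma, K), X, y)
  rbf_network(centers, rep(sigma, K), out$weights, out$bias)
}

#' Configuration of the backpropagation network baseline
#'
#' One hidden layer of logistic-sigmoid units and a linear output, trained
#' by seeded mini-batch gradient descent with the per-epoch learning-rate
#' schedule `lr_e = lr / (1 + decay * e)`. The defaults are the reference
#' comparison settings: batch 6, 100 epochs, initial rate 0.01, decay
#' 0.001. The hidden-layer size is not part of those settings; the package
#' default is 10 units.
#'
#' @param hidden Hidden units (>= 1).
#' @param batch Mini-batch size (>= 1).
#' @param epochs Training epochs (>= 0).
#' @param lr Initial learning rate (> 0).
#' @param decay Learning-rate decay constant (>= 0).
#' @param seed Integer seed (initialization and shuffling).
#' @return A list of class `bpnn_config`.
#' @export
bpnn_config <- function(hidden = 10L, batch = 6L, epochs = 100L,
                        lr = 0.01, decay = 0.001, seed = 1L) {
  stopifnot(hidden >= 1L, batch >= 1L, epochs >= 0L, lr > 0, decay >= 0)
  structure(list(hidden = as.integer(hidden), batch = as.integer(batch),
                 epochs = as.integer(epochs), lr = lr, decay = decay,
                 seed = as.integer(seed)), class = "bpnn_config")
}

bpnn_sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass; returns hidden activations and output.
bpnn_forward <- function(w, X) {
  H <- bpnn_sigmoid(sweep(X %*% w$W1, 2L, w$b1, "+"))
  list(H = H, yhat = drop(H %*% w$w2) + w$b2)
}

# Mean-squared-error gradient of a sigmoid-hidden / linear-output net.
bpnn_gradient <- function(w, X, y) {
  fw <- bpnn_forward(w, X)
  n <- nrow(X)
  r <- fw$yhat - y
  g_w2 <- drop(crossprod(fw$H, r)) * 2 / n
  g_b2 <- 2 * mean(r)
  delta <- (r %o% w$w2) * fw$H * (1 - fw$H)   # n x hidden
  g_W1 <- crossprod(X, delta) * 2 / n
  g_b1 <- colSums(delta) * 2 / n
  list(W1 = g_W1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
}

#' Train the backpropagation network baseline
#'
#' Standardized inputs *and* targets are recommended (raw yields make the
#' fixed learning rate unstable); [fit_soil_model()] handles both
#' transforms automatically.
#'
#' @param X Training inputs (`n x d`).
#' @param y Training targets.
#' @param config A [bpnn_config()].
#' @return Object of class `bpnn` with the weight matrices, the per-epoch
#'   training-loss trace and the config.
#' @export
train_bpnn <- function(X, y, config = bpnn_config()) {
  stopifnot(inherits(config, "bpnn_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n == length(y), n >= 1L)
  d <- ncol(X)
  h <- config$hidden
  set.seed(config$seed)
  w <- list(W1 = matrix(stats::runif(d * h, -0.5, 0.5), d, h),
            b1 = stats::runif(h, -0.5, 0.5),
            w2 = stats::runif(h, -0.5, 0.5),
            b2 = stats::runif(1L, -0.5, 0.5))
  loss_trace <- numeric(config$epochs)
  if (config$epochs > 0L) {
    for (e in seq_len(config$epochs)) {
      lr_e <- config$lr / (1 + config$decay * (e - 1L))
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch)
      for (s in starts) {
        b <- idx[seq(s, min(s + config$batch - 1L, n))]
        g <- bpnn_gradient(w, X[b, , drop = FALSE], y[b])
        w$W1 <- w$W1 - lr_e * g$W1
        w$b1 <- w$b1 - lr_e * g$b1
        w$w2 <- w$w2 - lr_e * g$w2
        w$b2 <- w$b2 - lr_e * g$b2
      }
      loss <- mean((bpnn_forward(w, X)$yhat - y)^2)
      if (!is.finite(loss)) {
        stop("BPNN training loss diverged (non-finite); try a smaller lr",
             call. = FALSE)
      }
      loss_trace[e] <- loss
    }
  }
  structure(list(weights = w, trace = loss_trace, config = config, d = d),
            class = "bpnn")
}

#' @export
predict.bpnn <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$d) {
    stop("input has ", ncol(X), " columns but network expects ", object$d,
         call. = FALSE)
  }
  bpnn_forward(object$weights, X)$yhat
}

#' @export
print.bpnn <- function(x, ...) {
  cat("Backpropagation network:", x$d, "->", x$config$hidden,
      "sigmoid -> 1 linear\n")
  if (length(x$trace) > 0) {
    cat("  final training MSE:", format(utils::tail(x$trace, 1),
                                        digits = 4), "\n")
  }
  invisible(x)
}
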