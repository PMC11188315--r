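#' Gaussian radial basis function regression network
#'
#' A single-hidden-layer network: hidden unit `s` responds to the squared
#' Euclidean distance between the input and its centre,
#' `G_s(x) = exp(-||x - o_s||^2 / (2 * sigma_s^2))`, and a linear output
#' layer combines the unit activations,
#' `yhat = sum_s w_s * G_s(x) + bias`.
#'
#' @param centers `K x d` numeric matrix of unit centres (standardized
#'   input units).
#' @param widths Length-`K` vector of positive widths `sigma_s`.
#' @param weights Length-`K` vector of output weights.
#' @param bias Scalar output bias (threshold).
#' @return An object of class `rbf_network`.
#' @export
#' @examples
#' net <- rbf_network(matrix(0, 1, 1), 1, 3, 0.5)
#' predict(net, matrix(0, 1, 1))  # 3.5 at the centre
rbf_network <- function(centers, widths, weights, bias) {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  widths <- as.numeric(widths)
  weights <- as.numeric(weights)
  bias <- as.numeric(bias)
  K <- nrow(centers)
  stopifnot(K >= 1L, length(widths) == K, length(weights) == K,
            length(bias) == 1L)
  if (any(!is.finite(centers)) || any(!is.finite(widths)) ||
      any(!is.finite(weights)) || !is.finite(bias)) {
    stop("rbf_network parameters must be finite", call. = FALSE)
  }
  if (any(widths <= 0)) stop("widths must be strictly positive", call. = FALSE)
  structure(list(centers = centers, widths = widths, weights = weights,
                 bias = bias, K = K, d = ncol(centers)),
            class = "rbf_network")
}

#' Gaussian basis activation
#'
#' `exp(-||x - center||^2 / (2 * sigma^2))`: 1 exactly at the centre,
#' strictly decreasing in the distance, always in (0, 1].
#'
#' @param x Input vector, or a matrix with one input per row.
#' @param center Centre vector.
#' @param sigma Positive width.
#' @return Activation(s) in (0, 1].
#' @export
gaussian_basis <- function(x, center, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (is.matrix(x)) {
    d2 <- rowSums(sweep(x, 2L, center)^2)
  } else {
    if (length(x) != length(center)) {
      stop("dimension mismatch between x and center", call. = FALSE)
    }
    d2 <- sum((x - center)^2)
  }
  exp(-d2 / (2 * sigma^2))
}

# n x K activation matrix: column s holds G_s over all rows of X.
rbf_design <- function(centers, widths, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(centers)) {
    stop("input has ", ncol(X), " columns but network expects ",
         ncol(centers), call. = FALSE)
  }
  # squared distances via the expansion ||x||^2 - 2 x.o + ||o||^2
  xx <- rowSums(X^2)
  oo <- rowSums(centers^2)
  d2 <- outer(xx, oo, "+") - 2 * X %*% t(centers)
  d2[d2 < 0] <- 0
  exp(sweep(d2, 2L, -2 * widths^2, "/"))
}

#' Predict from an RBF network
#'
#' @param object An `rbf_network`.
#' @param newdata Numeric matrix (or data frame) with `d` columns, one
#'   input per row.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rbf_network <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  G <- rbf_design(object$centers, object$widths, X)
  drop(G %*% object$weights) + object$bias
}

#' Least-squares fit of the linear output layer
#'
#' With centres and widths held fixed, the output weights and bias that
#' minimize squared training error solve an ordinary linear least-squares
#' problem in the activation matrix. The minimum-norm solution (via SVD
#' pseudoinverse) is returned when the system is underdetermined, e.g.
#' the interpolation regime `K = n`.
#'
#' @param centers `K x d` centre matrix.
#' @param widths Length-`K` positive widths.
#' @param X Training inputs (`n x d`).
#' @param y Training targets (length `n`).
#' @return A list with `weights` (length `K`) and `bias`.
#' @export
fit_rbf_output <- function(centers, widths, X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L)
  if (any(widths <= 0)) stop("widths must be strictly positive", call. = FALSE)
  G <- cbind(rbf_design(centers, widths, X), 1)
  if (any(!is.finite(G)) || any(!is.finite(y))) {
    stop("non-finite entries in the least-squares design", call. = FALSE)
  }
  sv <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * sv$d[1L]
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  K <- nrow(as.matrix(centers))
  list(weights = coef[seq_len(K)], bias = coef[K + 1L])
}

#' Flatten an RBF network to a parameter vector
#'
#' Layout: `[centers row-major | log-widths | output weights | bias]`,
#' total length `K*d + 2K + 1`. Widths are carried in log-space so any
#' real-valued vector decodes to a network with strictly positive widths
#' -- the property the box-constrained optimizer relies on.
#'
#' @param net An `rbf_network`.
#' @return Numeric parameter vector.
#' @export
encode_rbf <- function(net) {
  stopifnot(inherits(net, "rbf_network"))
  c(as.vector(t(net$centers)), log(net$widths), net$weights, net$bias)
}

#' Rebuild an RBF network from a parameter vector
#'
#' Inverse of [encode_rbf()].
#'
#' @param vec Numeric vector of length `K*d + 2K + 1`, all finite.
#' @param K Hidden-unit count.
#' @param d Input dimension.
#' @return An `rbf_network`.
#' @export
decode_rbf <- function(vec, K, d) {
  expected <- K * d + 2L * K + 1L
  if (length(vec) != expected) {
    stop("parameter vector has length ", length(vec), ", expected ",
         expected, " for K = ", K, ", d = ", d, call. = FALSE)
  }
  if (any(!is.finite(vec))) {
    stop("parameter vector contains non-finite values", call. = FALSE)
  }
  centers <- matrix(vec[seq_len(K * d)], K, d, byrow = TRUE)
  widths <- exp(vec[K * d + seq_len(K)])
  weights <- vec[K * d + K + seq_len(K)]
  bias <- vec[K * d + 2L * K + 1L]
  rbf_network(centers, widths, weights, bias)
}

#' @export
print.rbf_network <- function(x, ...) {
  cat("Gaussian RBF network: K =", x$K, "hidden units, d =", x$d,
      "inputs\n")
  cat("  widths:", paste(format(x$widths, digits = 3), collapse = " "), "\n")
  cat("  bias:", format(x$bias, digits = 4), "\n")
  invisible(x)
}
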