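#' Training configuration for the grey-wolf-optimised RBF network
#'
#' Collects every tunable of [train_gwo_rbf()]. Defaults are the package's
#' standard study conditions: a pack of 30 wolves run for 100 iterations
#' over a `K = 10`-unit network, followed by a gradient polish.
#'
#' @param K Hidden-unit count (>= 1).
#' @param n_wolves Pack size (>= 3).
#' @param k_max Optimizer iteration budget (>= 0).
#' @param seed Integer seed controlling the whole training path.
#' @param bounds_margin Centre search box: each feature's observed
#'   `[min, max]` widened by `bounds_margin` times its range.
#' @param log_width_range Box for log-widths, in standardized input units.
#' @param weight_scale Output weights searched in
#'   `[-weight_scale, weight_scale] * sd(y)`; the bias box is the same but
#'   centred on `mean(y)` (targets such as yields sit far from zero).
#' @param fitness_on `"train"` (default) evaluates the mean relative error
#'   fitness on the training split; `"validation"` uses a held-out split
#'   supplied to [train_gwo_rbf()] (changes model selection).
#' @param refine Logical: run the gradient polish ([refine_rbf()]) on the
#'   best wolf after the search. On by default -- the backpropagation
#'   polish is part of the hybrid method.
#' @param refine_lr Initial learning rate of the polish (backtracking line
#'   search adapts it).
#' @param refine_epochs Polish epochs.
#' @param warm_start Logical: seed one wolf of the initial pack with the
#'   conventional RBF recipe (farthest-point centres, least-squares output
#'   layer); the rest of the pack stays uniform over the bounds. On by
#'   default.
#' @return A list of class `train_config`.
#' @export
train_config <- function(K = 10L, n_wolves = 30L, k_max = 100L, seed = 1L,
                         bounds_margin = 0.5,
                         log_width_range = c(log(0.05), log(5)),
                         weight_scale = 10,
                         fitness_on = c("train", "validation"),
                         refine = TRUE, refine_lr = 0.1,
                         refine_epochs = 300L, warm_start = TRUE) {
  fitness_on <- match.arg(fitness_on)
  stopifnot(K >= 1L, n_wolves >= 3L, k_max >= 0L, bounds_margin >= 0,
            length(log_width_range) == 2L,
            log_width_range[1L] < log_width_range[2L],
            weight_scale > 0, refine_lr > 0, refine_epochs >= 0L)
  structure(list(K = as.integer(K), n_wolves = as.integer(n_wolves),
                 k_max = as.integer(k_max), seed = as.integer(seed),
                 bounds_margin = bounds_margin,
                 log_width_range = log_width_range,
                 weight_scale = weight_scale, fitness_on = fitness_on,
                 refine = isTRUE(refine), refine_lr = refine_lr,
                 refine_epochs = as.integer(refine_epochs),
                 warm_start = isTRUE(warm_start)),
            class = "train_config")
}

#' Mean relative error fitness of a flat RBF parameter vector
#'
#' The optimizer's objective: decode the vector into a network, predict,
#' and return the mean relative error `mean(|y - yhat| / |y|)` -- i.e.
#' MAPE as a fraction rather than percent.
#'
#' @param vec Flat parameter vector (see [encode_rbf()]).
#' @param K,d Network shape.
#' @param X Inputs (`n x d`).
#' @param y Strictly positive targets.
#' @param eps Guard on `|y|`; see [mape()].
#' @return Mean relative error as a fraction.
#' @export
rbf_fitness <- function(vec, K, d, X, y, eps = 1e-8) {
  net <- decode_rbf(vec, K, d)
  mape(y, predict(net, X), eps = eps) / 100
}

# Search box for the flat parameter vector, built from the training data.
# Centres live in each feature's observed range widened by the margin;
# log-widths use a fixed box (meaningful for standardized inputs); weights
# and bias scale with the target.
gwo_rbf_bounds <- function(X, y, config) {
  rng <- apply(X, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (any(span <= 0)) {
    bad <- colnames(X)[which(span <= 0)[1L]]
    if (is.null(bad)) bad <- which(span <= 0)[1L]
    stop("degenerate bounds: feature '", bad, "' is constant", call. = FALSE)
  }
  c_lo <- rng[1L, ] - config$bounds_margin * span
  c_hi <- rng[2L, ] + config$bounds_margin * span
  s_y <- stats::sd(y)
  if (!is.finite(s_y) || s_y <= 0) s_y <- max(abs(y), 1)
  w <- config$weight_scale * s_y
  K <- config$K
  list(lower = c(rep(c_lo, K), rep(config$log_width_range[1L], K),
                 rep(-w, K), mean(y) - w),
       upper = c(rep(c_hi, K), rep(config$log_width_range[2L], K),
                 rep(w, K), mean(y) + w))
}

#' Train an RBF network with the grey wolf optimizer
#'
#' The hybrid trainer: every network parameter -- centres, log-widths,
#' output weights and the output bias -- is packed into one wolf position
#' vector, and the pack minimizes the mean relative prediction error.
#' After the search the best network is optionally polished by gradient
#' descent on squared training error ([refine_rbf()]). Inputs are expected
#' in standardized units (see [standardize()]); targets stay in their
#' original, strictly positive units so the relative-error fitness is
#' meaningful.
#'
#' @param X Standardized training inputs (`n x d` matrix).
#' @param y Strictly positive training targets.
#' @param config A [train_config()].
#' @param X_val,y_val Optional held-out split; required when
#'   `config$fitness_on == "validation"`.
#' @return A list of class `gwo_rbf_fit`: `net` (the trained
#'   [rbf_network()]), `trace` (non-increasing best-fitness trace of the
#'   wolf search), `config`, and `fitness` (final training fitness).
#' @export
train_gwo_rbf <- function(X, y, config = train_config(),
                          X_val = NULL, y_val = NULL) {
  stopifnot(inherits(config, "train_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(y) >= 1L)
  if (any(abs(y) < 1e-8)) {
    stop("targets must be bounded away from zero for the relative-error ",
         "fitness", call. = FALSE)
  }
  if (nrow(X) < config$K) {
    warning("fewer training records (", nrow(X), ") than hidden units (",
            config$K, "); the network can memorize the data")
  }
  d <- ncol(X)
  if (config$fitness_on == "validation") {
    if (is.null(X_val) || is.null(y_val)) {
      stop("fitness_on = 'validation' requires X_val and y_val",
           call. = FALSE)
    }
    fit_X <- as.matrix(X_val); fit_y <- as.numeric(y_val)
  } else {
    fit_X <- X; fit_y <- y
  }
  bounds <- gwo_rbf_bounds(X, y, config)
  fn <- function(vec) rbf_fitness(vec, config$K, d, fit_X, fit_y)
  init <- NULL
  if (config$warm_start && config$K <= nrow(X)) {
    warm <- train_plain_rbf(X, y, K = config$K, seed = config$seed)
    init <- matrix(encode_rbf(warm), nrow = 1L)
  }
  res <- gwo_optimize(fn, bounds$lower, bounds$upper,
                      n_wolves = config$n_wolves, k_max = config$k_max,
                      seed = config$seed, init_positions = init)
  net <- decode_rbf(res$par, config$K, d)
  if (config$refine && config$refine_epochs > 0L) {
    net <- refine_rbf(net, X, y, lr = config$refine_lr,
                      epochs = config$refine_epochs,
                      width_floor = config$log_width_range[1L])
  }
  structure(list(net = net, trace = res$trace, config = config,
                 fitness = rbf_fitness(encode_rbf(net), config$K, d,
                                       fit_X, fit_y)),
            class = "gwo_rbf_fit")
}

#' @export
predict.gwo_rbf_fit <- function(object, newdata, ...) {
  predict(object$net, newdata, ...)
}

#' @export
print.gwo_rbf_fit <- function(x, ...) {
  cat("Grey-wolf-trained RBF network (seed ", x$config$seed, ")\n", sep = "")
  print(x$net)
  cat("  final mean relative error:", format(x$fitness, digits = 4), "\n")
  invisible(x)
}

# Analytic gradient of mean squared error wrt the encoded parameter
# vector [centers row-major | log-widths | weights | bias].
rbf_mse_gradient <- function(net, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  G <- rbf_design(net$centers, net$widths, X)       # n x K
  r <- drop(G %*% net$weights) + net$bias - y       # residuals
  gw <- drop(crossprod(G, r)) * 2 / n               # d/dw_s
  gb <- 2 * mean(r)                                 # d/dbias
  K <- net$K; d <- net$d
  gc <- matrix(0, K, d)
  gl <- numeric(K)
  for (s in seq_len(K)) {
    diff <- sweep(X, 2L, net$centers[s, ])          # x_i - o_s
    rG <- r * G[, s]
    gc[s, ] <- (2 / n) * net$weights[s] *
      colSums(rG * diff) / net$widths[s]^2
    gl[s] <- (2 / n) * net$weights[s] *
      sum(rG * rowSums(diff^2)) / net$widths[s]^2
  }
  c(as.vector(t(gc)), gl, gw, gb)
}

rbf_mse <- function(vec, K, d, X, y) {
  net <- decode_rbf(vec, K, d)
  mean((predict(net, X) - y)^2)
}

# Ridge-regularized least-squares solve of the output layer; the small
# penalty keeps the weights bounded when the activation design is nearly
# singular (e.g. overlapping centres or collapsing widths).
rbf_ridge_output <- function(centers, widths, X, y, lambda) {
  G <- cbind(rbf_design(centers, widths, X), 1)
  A <- crossprod(G) + diag(lambda, ncol(G))
  coef <- solve(A, crossprod(G, y))
  K <- nrow(as.matrix(centers))
  list(weights = coef[seq_len(K)], bias = coef[K + 1L])
}

#' Gradient fine-tuning of an RBF network
#'
#' Backpropagation polish on mean squared training error. Two modes:
#'
#' * `solve_output = FALSE`: full-batch gradient descent over *all*
#'   network parameters (centres, log-widths, weights, bias), with a
#'   backtracking line search on the step size.
#' * `solve_output = TRUE` (default): each epoch takes a backtracking
#'   gradient step on the nonlinear parameters (centres and log-widths)
#'   and then solves the linear output layer exactly by ridge-regularized
#'   least squares -- separable least squares, which converges far faster
#'   and is the mode the trainer uses.
#'
#' In both modes the best parameters seen (including the input network)
#' are returned, so the returned network never has a higher training loss
#' than its input.
#'
#' @param net An [rbf_network()].
#' @param X Training inputs.
#' @param y Training targets.
#' @param lr Initial learning rate (> 0); the line search adapts it.
#' @param epochs Number of gradient epochs; 0 returns `net` unchanged.
#' @param solve_output Solve the output layer exactly each epoch.
#' @param ridge Ridge penalty of the output-layer solve, per training
#'   record (total penalty `ridge * n`).
#' @param width_floor Optional lower bound on log-widths during the
#'   polish, guarding against degenerate spike units.
#' @return The fine-tuned `rbf_network`.
#' @export
refine_rbf <- function(net, X, y, lr = 0.1, epochs = 300L,
                       solve_output = TRUE, ridge = 1e-6,
                       width_floor = NULL) {
  stopifnot(inherits(net, "rbf_network"), lr > 0, epochs >= 0L)
  if (epochs == 0L) return(net)
  X <- as.matrix(X)
  y <- as.numeric(y)
  K <- net$K; d <- net$d
  lambda <- ridge * nrow(X)
  nl_idx <- seq_len(K * d + K)          # centres + log-widths
  lw_idx <- K * d + seq_len(K)

  as_net <- function(vec) {
    if (is.null(width_floor)) return(decode_rbf(vec, K, d))
    vec[lw_idx] <- pmax(vec[lw_idx], width_floor)
    decode_rbf(vec, K, d)
  }
  with_ls_output <- function(vec) {
    nn <- as_net(vec)
    out <- rbf_ridge_output(nn$centers, nn$widths, X, y, lambda)
    rbf_network(nn$centers, nn$widths, out$weights, out$bias)
  }
  loss_of <- function(nn) mean((predict(nn, X) - y)^2)

  best_net <- net
  best_loss <- loss_of(net)
  cur <- net
  if (solve_output) {
    cur <- tryCatch(with_ls_output(encode_rbf(net)), error = function(e) net)
  }
  loss <- loss_of(cur)
  if (loss < best_loss) { best_loss <- loss; best_net <- cur }
  step <- lr
  for (e in seq_len(epochs)) {
    g <- rbf_mse_gradient(cur, X, y)
    if (any(!is.finite(g))) {
      stop("non-finite gradient during refinement; try a smaller lr",
           call. = FALSE)
    }
    vec <- encode_rbf(cur)
    improved <- FALSE
    for (half in 0:30) {
      cand <- vec
      if (solve_output) {
        cand[nl_idx] <- cand[nl_idx] - step * g[nl_idx]
        # a too-large step can underflow widths; treat as infeasible
        cand_net <- tryCatch(with_ls_output(cand), error = function(e) NULL)
      } else {
        cand <- cand - step * g
        cand_net <- tryCatch(as_net(cand), error = function(e) NULL)
      }
      cand_loss <- if (is.null(cand_net)) Inf else loss_of(cand_net)
      if (is.finite(cand_loss) && cand_loss < loss) {
        cur <- cand_net
        loss <- cand_loss
        step <- step * 1.5
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (loss < best_loss) {
      best_loss <- loss
      best_net <- cur
    }
    if (!improved) break  # line search found no descent progress
  }
  best_net
}
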