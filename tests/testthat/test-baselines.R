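test_that("plain RBF baseline interpolates when K = n and is seeded", {
  set.seed(20)
  X <- matrix(runif(40, -2, 2), 20, 2)
  y <- rnorm(20, 100, 15)
  net <- train_plain_rbf(X, y, K = 20, seed = 1)
  expect_lt(mean((predict(net, X) - y)^2), 1e-4)
  expect_identical(train_plain_rbf(X, y, K = 5, seed = 3),
                   train_plain_rbf(X, y, K = 5, seed = 3))
  expect_error(train_plain_rbf(X, y, K = 21), "exceed")
})

test_that("farthest-point centres are distinct training points", {
  set.seed(21)
  X <- matrix(runif(60, -1, 1), 30, 2)
  net <- train_plain_rbf(X, rnorm(30), K = 6, seed = 2)
  on_data <- apply(net$centers, 1, function(ctr) {
    any(apply(X, 1, function(row) all(row == ctr)))
  })
  expect_true(all(on_data))
  expect_equal(nrow(unique(net$centers)), 6L)
})

test_that("BPNN with zero epochs returns the seeded initialization", {
  set.seed(22)
  X <- matrix(rnorm(30), 15, 2)
  y <- rnorm(15)
  cfg0 <- bpnn_config(epochs = 0, seed = 7)
  m <- train_bpnn(X, y, cfg0)
  set.seed(7)
  W1 <- matrix(runif(2 * 10, -0.5, 0.5), 2, 10)
  expect_equal(m$weights$W1, W1)
  expect_identical(train_bpnn(X, y, bpnn_config(seed = 5)),
                   train_bpnn(X, y, bpnn_config(seed = 5)))
})

test_that("BPNN gradient matches finite differences on a 2-2-1 net", {
  set.seed(23)
  X <- matrix(rnorm(16), 8, 2)
  y <- rnorm(8)
  w <- list(W1 = matrix(rnorm(4), 2, 2), b1 = rnorm(2),
            w2 = rnorm(2), b2 = rnorm(1))
  g <- gwrbf:::bpnn_gradient(w, X, y)
  pack <- function(w) c(as.vector(w$W1), w$b1, w$w2, w$b2)
  unpack <- function(v) list(W1 = matrix(v[1:4], 2, 2), b1 = v[5:6],
                             w2 = v[7:8], b2 = v[9])
  fd <- numeric_gradient(function(v) {
    fw <- gwrbf:::bpnn_forward(unpack(v), X)
    mean((fw$yhat - y)^2)
  }, pack(w))
  expect_equal(c(as.vector(g$W1), g$b1, g$w2, g$b2), fd,
               tolerance = 1e-5)
})

test_that("BPNN training beats the constant predictor on a linear response", {
  sim <- generate_soil_data(synthetic_config(n = 300, response = "linear",
                                             seed = 24))
  sp <- split_soil_data(sim$data, 0.7, seed = 24)
  fit <- fit_soil_model(sp$train, method = "bpnn",
                        config = bpnn_config(seed = 24))
  train_pred <- predict(fit, sp$train)
  y <- sp$train$yield_actual
  expect_lt(mape(y, train_pred), mape(y, rep(mean(y), length(y))))
})

test_that("benchmark runs are reproducible and share splits across models", {
  cfg <- synthetic_config(n = 120)
  b1 <- run_benchmark(cfg, models = c("RBNNA", "BPNN"), seeds = 1:2,
                      train_cfg = train_config(K = 5),
                      bpnn_cfg = bpnn_config(epochs = 20))
  b2 <- run_benchmark(cfg, models = c("RBNNA", "BPNN"), seeds = 1:2,
                      train_cfg = train_config(K = 5),
                      bpnn_cfg = bpnn_config(epochs = 20))
  expect_identical(b1$per_seed, b2$per_seed)
  expect_equal(rownames(b1$summary), c("MAPE", "MAE", "R2"))
  expect_equal(names(b1$summary), c("RBNNA", "BPNN"))
  # external comparator column joins the summary
  b3 <- run_benchmark(cfg, models = "RBNNA", seeds = 1,
                      train_cfg = train_config(K = 5),
                      external = list(NUBCA = c(MAPE = 8.17, MAE = 5.94,
                                                R2 = 0.762)),
                      reference = "RBNNA")
  expect_true("NUBCA" %in% names(b3$summary))
  expect_true("vs_NUBCA" %in% names(b3$comparison))
})

test_that("benchmark records model failures without aborting", {
  cfg <- synthetic_config(n = 40)
  # K larger than the training split: the plain baseline must fail,
  # the BPNN column must still be produced
  b <- run_benchmark(cfg, models = c("RBNNA", "BPNN"), seeds = 1,
                     train_cfg = train_config(K = 35),
                     bpnn_cfg = bpnn_config(epochs = 5))
  expect_false(is.null(b$failures))
  expect_true(all(is.finite(b$per_seed[b$per_seed$model == "BPNN",
                                       c("MAPE", "MAE", "R2")][[1]])))
})
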