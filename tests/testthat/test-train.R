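make_task <- function(n = 60, d = 2, seed = 5) {
  set.seed(seed)
  X <- matrix(runif(n * d, -2, 2), n, d)
  y <- 150 + 20 * exp(-rowSums(X^2) / 2) + 5 * X[, 1]
  list(X = X, y = y)
}

test_that("fitness is MAPE/100 of the decoded network", {
  tk <- make_task()
  net <- rbf_network(matrix(0, 1, 2), 1, 0, 155)
  vec <- encode_rbf(net)
  expect_equal(rbf_fitness(vec, 1, 2, tk$X, tk$y),
               mape(tk$y, predict(net, tk$X)) / 100)
  # perfect predictor has zero fitness
  perfect <- rbf_network(matrix(0, 1, 2), 1, 0, 100)
  expect_equal(rbf_fitness(encode_rbf(perfect), 1, 2,
                           matrix(0, 3, 2), rep(100, 3)), 0)
  # hand case: y = (100, 200), yhat = (110, 180) -> (0.10 + 0.10)/2
  hand <- rbf_network(matrix(0, 1, 1), 0.1, -70, 180)
  X2 <- matrix(c(0, 50), 2, 1)     # activations 1 and (numerically) 0
  expect_equal(predict(hand, X2), c(110, 180))
  expect_equal(rbf_fitness(encode_rbf(hand), 1, 1, X2, c(100, 200)), 0.10)
  # definitional loop oracle on a random network
  set.seed(6)
  rnet <- rbf_network(matrix(rnorm(6), 3, 2), runif(3, 0.5, 2),
                      rnorm(3), 150)
  pred <- predict(rnet, tk$X)
  expect_equal(rbf_fitness(encode_rbf(rnet), 3, 2, tk$X, tk$y),
               loop_mape(tk$y, pred) / 100, tolerance = 1e-12)
  expect_error(rbf_fitness(encode_rbf(rnet), 3, 2, tk$X,
                           c(0, tk$y[-1])), "mape undefined")
})

test_that("training is deterministic per seed and the trace never rises", {
  tk <- make_task()
  cfg <- train_config(K = 3, k_max = 15, seed = 9, refine_epochs = 20L)
  f1 <- train_gwo_rbf(tk$X, tk$y, cfg)
  f2 <- train_gwo_rbf(tk$X, tk$y, cfg)
  expect_identical(f1$net, f2$net)
  expect_false(is.unsorted(rev(f1$trace)))
  expect_length(f1$trace, 16L)
})

test_that("constant features are rejected by name", {
  tk <- make_task()
  X <- cbind(tk$X, bad = 1)
  expect_error(train_gwo_rbf(X, tk$y, train_config(K = 2, k_max = 2)),
               "bad")
})

test_that("validation-fitness mode requires and uses the held-out split", {
  tk <- make_task(n = 40)
  cfg <- train_config(K = 2, k_max = 5, seed = 1,
                      fitness_on = "validation", refine = FALSE)
  expect_error(train_gwo_rbf(tk$X, tk$y, cfg), "X_val")
  tv <- make_task(n = 20, seed = 99)
  fit <- train_gwo_rbf(tk$X, tk$y, cfg, X_val = tv$X, y_val = tv$y)
  expect_equal(fit$fitness,
               mape(tv$y, predict(fit$net, tv$X)) / 100)
})

test_that("refine with epochs = 0 is a no-op and never increases loss", {
  tk <- make_task()
  net <- rbf_network(matrix(rnorm(4), 2, 2), c(1, 1), c(5, -5), 150)
  expect_identical(refine_rbf(net, tk$X, tk$y, epochs = 0L), net)
  loss0 <- mean((predict(net, tk$X) - tk$y)^2)
  for (solve_out in c(TRUE, FALSE)) {
    ref <- refine_rbf(net, tk$X, tk$y, epochs = 40L,
                      solve_output = solve_out)
    expect_lte(mean((predict(ref, tk$X) - tk$y)^2), loss0)
  }
})

test_that("one small-step epoch on a single point strictly reduces loss", {
  net <- rbf_network(matrix(0.5, 1, 1), 1, 1, 0)
  X <- matrix(1, 1, 1); y <- 3
  ref <- refine_rbf(net, X, y, lr = 1e-3, epochs = 1L,
                    solve_output = FALSE)
  expect_lt(mean((predict(ref, X) - y)^2),
            mean((predict(net, X) - y)^2))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(13)
  K <- 3; d <- 2
  net <- rbf_network(matrix(rnorm(K * d), K, d), runif(K, 0.8, 1.5),
                     rnorm(K, 0, 2), rnorm(1))
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20, 5, 2)
  g <- gwrbf:::rbf_mse_gradient(net, X, y)
  fd <- numeric_gradient(function(v) {
    gwrbf:::rbf_mse(v, K, d, X, y)
  }, encode_rbf(net))
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("default training reaches low error on a smooth synthetic target", {
  sim <- generate_soil_data(synthetic_config(n = 500, seed = 11))
  sp <- split_soil_data(sim$data, 0.7, seed = 11)
  fit <- fit_soil_model(sp$train, method = "imrbnna",
                        config = train_config(seed = 11))
  val <- evaluate_soil_model(fit, sp$validation)
  expect_lt(val[["MAPE"]], 15)
  expect_true(all(is.finite(val)))
})
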