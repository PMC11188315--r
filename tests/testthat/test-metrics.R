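test_that("metric hand cases evaluate exactly", {
  expect_equal(mape(c(100, 200), c(100, 200)), 0)
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, 2), c(2, 4)), 1.5)
  y <- c(3, 5, 9, 12)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
})

test_that("metrics match definitional loops within 1e-12 on random pairs", {
  for (seed in c(101, 202, 303)) {
    p <- random_pair(1000, seed)
    expect_equal(mape(p$actual, p$predicted),
                 loop_mape(p$actual, p$predicted), tolerance = 1e-12)
    expect_equal(mae(p$actual, p$predicted),
                 loop_mae(p$actual, p$predicted), tolerance = 1e-12)
    expect_equal(r_squared(p$actual, p$predicted),
                 loop_r2(p$actual, p$predicted), tolerance = 1e-12)
  }
})

test_that("metric guards reject degenerate inputs", {
  expect_error(mape(c(0, 1), c(1, 1)), "mape undefined")
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(mae(1:3, 1:4), "lengths")
  expect_error(mape(c(1, NA), c(1, 1)), "non-finite")
})

test_that("permutation, scaling and affine invariances hold", {
  p <- random_pair(200, 7)
  set.seed(8)
  perm <- sample(200)
  expect_equal(mape(p$actual[perm], p$predicted[perm]),
               mape(p$actual, p$predicted))
  expect_equal(mae(p$actual[perm], p$predicted[perm]),
               mae(p$actual, p$predicted))
  expect_equal(r_squared(p$actual[perm], p$predicted[perm]),
               r_squared(p$actual, p$predicted))
  # mae scales linearly, mape is scale-invariant
  expect_equal(mae(3 * p$actual, 3 * p$predicted),
               3 * mae(p$actual, p$predicted))
  expect_equal(mape(3 * p$actual, 3 * p$predicted),
               mape(p$actual, p$predicted))
  # r2 is invariant under a common affine map
  expect_equal(r_squared(2 * p$actual + 50, 2 * p$predicted + 50),
               r_squared(p$actual, p$predicted))
})

test_that("relative change reproduces the published reduction sentences", {
  expect_equal(relative_change(4.82, 1.61, "reduction"), 66.60,
               tolerance = 0.0001)
  expect_equal(relative_change(15.08, 8.28, "reduction"), 45.09,
               tolerance = 0.0001)
  expect_equal(relative_change(3, 3, "reduction"), 0)
  expect_equal(relative_change(3, 3, "increase"), 0)
  expect_equal(relative_change(0.8, 1, "increase"), 25)
  expect_error(relative_change(0, 1), "reference")
})

test_that("metric_comparison appends change columns against the reference", {
  tab <- data.frame(A = c(10, 5, 0.8), B = c(5, 2.5, 0.9),
                    row.names = c("MAPE", "MAE", "R2"))
  cmp <- metric_comparison(tab, reference = "B")
  expect_equal(cmp$vs_A, c(50, 50, 12.5))
  same <- metric_comparison(data.frame(A = c(1, 1, 0.5), B = c(1, 1, 0.5),
                                       row.names = c("MAPE", "MAE", "R2")),
                            reference = "B")
  expect_equal(same$vs_A, c(0, 0, 0))
  expect_error(metric_comparison(tab, reference = "Z"), "reference")
})

test_that("compare_models computes metrics and relative changes per model", {
  p <- random_pair(50, 21)
  single <- compare_models(list(m1 = p$predicted), actual = p$actual)
  expect_equal(dim(single), c(3L, 1L))
  expect_equal(single["MAPE", "m1"], mape(p$actual, p$predicted))

  two <- compare_models(list(m1 = p$predicted, m2 = p$predicted),
                        actual = p$actual, reference = "m2")
  expect_equal(two$vs_m1, c(0, 0, 0))
  other <- random_pair(50, 22)
  expect_error(compare_models(list(
    m1 = list(actual = p$actual, predicted = p$predicted),
    m2 = list(actual = other$actual, predicted = other$predicted))),
    "same actual")
})

test_that("presentation rounding is half-up at two decimals", {
  expect_equal(round_half_up(66.595), 66.6)   # base round() gives 66.59
  expect_equal(round_half_up(0.125), 0.13)    # exact binary half case
  expect_equal(round_half_up(-0.125), -0.13)
  expect_equal(round_half_up(2.344), 2.34)
})
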