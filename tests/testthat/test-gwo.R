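sphere <- function(x) sum(x^2)

test_that("convergence factor decays linearly from 2 to 0", {
  expect_equal(convergence_factor(0, 100), 2)
  expect_equal(convergence_factor(100, 100), 0)
  expect_equal(convergence_factor(50, 100), 1)
  expect_error(convergence_factor(101, 100), "k must lie")
  expect_error(convergence_factor(5, 0), "k_max")
})

test_that("coefficient vectors follow M = 2*omega*p1 - omega, N = 2*p2", {
  half <- function(n) rep(0.5, n)
  co <- gwo_coefficients(1.7, 4, rand = half)
  expect_equal(co$M, rep(0, 4))
  expect_equal(co$N, rep(1, 4))
  one <- function(n) rep(1, n)
  co2 <- gwo_coefficients(2, 3, rand = one)
  expect_equal(co2$M, rep(2, 3))
  expect_equal(co2$N, rep(2, 3))
  set.seed(9)
  for (i in 1:20) {
    om <- runif(1, 0, 2)
    co3 <- gwo_coefficients(om, 6)
    expect_true(all(co3$M >= -om & co3$M <= om))
    expect_true(all(co3$N >= 0 & co3$N <= 2))
  }
})

test_that("encircling distance is the componentwise |N*target - w|", {
  expect_equal(encircle_distance(c(1, 1), c(1, 1), c(1, 1)), c(0, 0))
  expect_equal(encircle_distance(c(0.5, 3), c(1, 1), c(2, 2)), c(1.5, 1))
  # symmetry of the absolute value under swapping the two terms
  w <- c(0.3, -2); tg <- c(1.1, 0.4); N <- c(1.7, 0.2)
  expect_equal(encircle_distance(w, tg, N),
               abs(w - N * tg))
  expect_error(encircle_distance(c(1, 2), c(1, 2, 3), c(1, 1, 1)),
               "dimension mismatch")
})

test_that("a pack collapsed onto its leaders is a fixed point when M = 0", {
  half <- function(n) rep(0.5, n)  # p1 = 0.5 => M = 0; p2 = 0.5 => N = 1
  res <- gwo_optimize(sphere, c(-5, -5), c(5, 5), n_wolves = 3, k_max = 0,
                      seed = 1)
  st <- res$state
  pt <- c(0.7, -0.3)
  st$positions <- matrix(rep(pt, each = 3), 3, 2)
  st$leaders <- matrix(rep(pt, each = 3), 3, 2)
  st$leader_fitness <- rep(sphere(pt), 3)
  st2 <- gwo_update_positions(st, sphere, omega = 1.3, rand = half)
  for (i in 1:3) expect_equal(st2$positions[i, ], pt)
})

test_that("leader-guided update averages the three candidates", {
  # wolves at 0, all leaders at 1, M = 0, N = 1 -> new position (1+1+1)/3
  half <- function(n) rep(0.5, n)
  res <- gwo_optimize(sphere, -5, 5, n_wolves = 3, k_max = 0, seed = 2)
  st <- res$state
  st$positions <- matrix(0, 3, 1)
  st$leaders <- matrix(1, 3, 1)
  st$leader_fitness <- rep(1, 3)
  st2 <- gwo_update_positions(st, sphere, omega = 2, rand = half)
  expect_equal(drop(st2$positions), rep(1, 3))
  expect_equal(st2$k, st$k + 1L)
})

test_that("one update never worsens the best-so-far fitness", {
  set.seed(42)
  res <- gwo_optimize(sphere, rep(-5, 5), rep(5, 5), n_wolves = 30,
                      k_max = 0, seed = 42)
  st <- res$state
  st$k_max <- 10L
  before <- st$leader_fitness[1L]
  st2 <- gwo_update_positions(st, sphere)
  expect_lte(st2$leader_fitness[1L], before)
})

test_that("optimize contract: trace length, monotonicity, bounds, budget 0", {
  res0 <- gwo_optimize(sphere, rep(-5, 3), rep(5, 3), n_wolves = 10,
                       k_max = 0, seed = 7)
  expect_length(res0$trace, 1L)
  expect_equal(res0$value, min(res0$state$fitness))

  objectives <- list(sphere,
                     function(x) sum(abs(x)),
                     function(x) 10 * length(x) +
                       sum(x^2 - 10 * cos(2 * pi * x)))
  for (i in seq_along(objectives)) {
    res <- gwo_optimize(objectives[[i]], rep(-5.12, 3), rep(5.12, 3),
                        n_wolves = 12, k_max = 40, seed = 100 + i)
    expect_length(res$trace, 41L)
    expect_false(is.unsorted(rev(res$trace)))
    expect_true(all(res$par >= -5.12 & res$par <= 5.12))
  }
  expect_error(gwo_optimize(sphere, -1, 1, n_wolves = 2, k_max = 5),
               "n_wolves")
})

test_that("sphere in dim 5 is solved below 1e-2 and Rastrigin improves", {
  res <- gwo_optimize(sphere, rep(-5, 5), rep(5, 5), n_wolves = 30,
                      k_max = 200, seed = 42)
  expect_lt(res$value, 1e-2)
  rast <- function(x) 20 + sum(x^2 - 10 * cos(2 * pi * x))
  rr <- gwo_optimize(rast, rep(-5.12, 2), rep(5.12, 2), n_wolves = 30,
                     k_max = 200, seed = 7)
  expect_lt(rr$trace[length(rr$trace)], rr$trace[1])
})

test_that("equal seeds give bit-identical traces, positions stay boxed", {
  a <- gwo_optimize(sphere, rep(-3, 4), rep(2, 4), n_wolves = 15,
                    k_max = 30, seed = 11)
  b <- gwo_optimize(sphere, rep(-3, 4), rep(2, 4), n_wolves = 15,
                    k_max = 30, seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$par, b$par)

  set.seed(5)
  for (rep in 1:25) {
    d <- sample(1:6, 1)
    lo <- runif(d, -10, 0); hi <- lo + runif(d, 0.5, 10)
    res <- gwo_optimize(sphere, lo, hi, n_wolves = 8,
                        k_max = 5, seed = rep)
    expect_true(all(sweep(res$state$positions, 2, lo, ">=")))
    expect_true(all(sweep(res$state$positions, 2, hi, "<=")))
  }
})

test_that("longer budgets improve convex quadratics (omega schedule sanity)", {
  quad <- function(x) sum((x - 1)^2)
  finals <- sapply(c(10, 50, 200), function(km) {
    stats::median(sapply(1:20, function(s) {
      gwo_optimize(quad, rep(-5, 3), rep(5, 3), n_wolves = 15,
                   k_max = km, seed = s)$value
    }))
  })
  expect_true(finals[2] < finals[1])
  expect_true(finals[3] < finals[2])
})

test_that("non-finite fitness identifies the wolf, init warm starts clip", {
  bad <- function(x) if (x[1] > 0) NA_real_ else sum(x^2)
  expect_error(gwo_optimize(bad, -1, 1, n_wolves = 5, k_max = 2, seed = 3),
               "wolf")
  res <- gwo_optimize(sphere, rep(-1, 2), rep(1, 2), n_wolves = 5,
                      k_max = 0, seed = 4,
                      init_positions = matrix(c(9, -9), 1, 2))
  expect_equal(res$state$positions[1, ], c(1, -1))
})
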