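# Independent definitional oracles used to cross-check the vectorized
# implementations. Deliberately written as plain loops / textbook formulas.

loop_mape <- function(actual, predicted) {
  s <- 0
  for (j in seq_along(actual)) {
    s <- s + abs(actual[j] - predicted[j]) / abs(actual[j])
  }
  100 * s / length(actual)
}

loop_mae <- function(actual, predicted) {
  s <- 0
  for (j in seq_along(actual)) s <- s + abs(actual[j] - predicted[j])
  s / length(actual)
}

loop_r2 <- function(actual, predicted) {
  ybar <- mean(actual)
  sse <- 0
  sst <- 0
  for (j in seq_along(actual)) {
    sse <- sse + (actual[j] - predicted[j])^2
    sst <- sst + (actual[j] - ybar)^2
  }
  1 - sse / sst
}

# Two-pass mean / population-sd standardization oracle.
loop_standardize <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / length(x)
  (x - m) / sqrt(v)
}

# Normal-equations least squares for a design with explicit intercept.
normal_equations_fit <- function(Phi, y) {
  A <- cbind(Phi, 1)
  solve(crossprod(A), crossprod(A, y))
}

# Central finite differences of f at x.
numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1L))
}

# Small random soil-like design for property tests.
random_pair <- function(n, seed) {
  set.seed(seed)
  actual <- runif(n, 50, 250)
  predicted <- actual + rnorm(n, 0, 10)
  list(actual = actual, predicted = predicted)
}
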