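#' Grey wolf optimizer over bounded real vectors
#'
#' Population metaheuristic in which candidate solutions ("wolves") move
#' toward the three best solutions found so far (alpha, beta, delta)
#' under a linearly shrinking exploration coefficient. Each wolf's new
#' position is the average of three leader-guided candidates
#' `W_i = leader_i - M_i * |N_i * leader_i - W|`, with `M` drawn
#' componentwise from `[-omega, omega]` and `N` from `[0, 2]`; the
#' convergence factor `omega` decreases linearly from 2 to 0 over the
#' iteration budget. Positions leaving the box are clipped to the
#' boundary. Leaders are the best-so-far top three across *all*
#' evaluations (ties broken by earliest evaluation), which makes the
#' best-so-far fitness trace non-increasing by construction.
#'
#' @param fn Objective function mapping a numeric vector to a finite
#'   scalar; minimized.
#' @param lower,upper Numeric bound vectors (recycled to a common length);
#'   `lower < upper` elementwise.
#' @param n_wolves Pack size, at least 3 (the leaders must exist).
#' @param k_max Iteration budget (0 returns the best of the initial pack).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   runs.
#' @param init_positions Optional matrix of starting positions (one per
#'   row, clipped to the bounds) that replace the first rows of the
#'   uniform initial pack -- e.g. a warm start from a heuristic solution.
#' @return A list of class `gwo_result`: `par` (best position), `value`
#'   (best fitness), `trace` (best-so-far fitness, length `k_max + 1`),
#'   `n_eval`, and the final `state`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- gwo_optimize(sphere, lower = rep(-5, 3), upper = rep(5, 3),
#'                     n_wolves = 20, k_max = 50, seed = 1)
#' res$value
gwo_optimize <- function(fn, lower, upper, n_wolves = 30, k_max = 100,
                         seed = NULL, init_positions = NULL) {
  if (k_max < 0) stop("k_max must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- gwo_init(fn, lower, upper, n_wolves, init_positions)
  state$k_max <- as.integer(max(k_max, 1L))
  trace <- numeric(k_max + 1L)
  trace[1L] <- state$leader_fitness[1L]
  k <- 0L
  while (k < k_max) {
    state <- gwo_update_positions(state, fn)
    k <- k + 1L
    trace[k + 1L] <- state$leader_fitness[1L]
  }
  structure(list(par = state$leaders[1L, ], value = state$leader_fitness[1L],
                 trace = trace, n_eval = state$n_eval, state = state),
            class = "gwo_result")
}

#' Convergence factor schedule
#'
#' Linear decay `omega = 2 * (1 - k / k_max)` from 2 (full exploration) at
#' `k = 0` to 0 (pure exploitation) at `k = k_max`.
#'
#' @param k Current iteration, `0 <= k <= k_max`.
#' @param k_max Iteration budget, at least 1.
#' @return The convergence factor.
#' @export
convergence_factor <- function(k, k_max) {
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > k_max)) {
    stop("k must lie in [0, k_max]", call. = FALSE)
  }
  2 * (1 - k / k_max)
}

#' Draw the stochastic coefficient vectors M and N
#'
#' `M = 2 * omega * p1 - omega` (componentwise in `[-omega, omega]`) and
#' `N = 2 * p2` (componentwise in `[0, 2]`), with `p1`, `p2` uniform(0,1)
#' drawn independently per component.
#'
#' @param omega Convergence factor in `[0, 2]`.
#' @param d Dimension.
#' @param rand Uniform(0,1) generator taking a count; injectable for
#'   deterministic tests.
#' @return List with components `M` and `N`, each length `d`.
#' @export
gwo_coefficients <- function(omega, d, rand = stats::runif) {
  stopifnot(omega >= 0, omega <= 2, d >= 1)
  list(M = 2 * omega * rand(d) - omega, N = 2 * rand(d))
}

#' Encircling distance between a wolf and a target
#'
#' Componentwise `|N * target - position|`.
#'
#' @param position Current wolf position.
#' @param target Target (leader/prey) position.
#' @param N Coefficient vector from [gwo_coefficients()].
#' @return Nonnegative distance vector.
#' @export
encircle_distance <- function(position, target, N) {
  if (length(position) != length(target) || length(position) != length(N)) {
    stop("dimension mismatch in encircle_distance", call. = FALSE)
  }
  abs(N * target - position)
}

# Initialize a pack uniformly over the bounds and rank the leaders.
# Rows of init_positions (clipped into the box) overwrite the first wolves.
gwo_init <- function(fn, lower, upper, n_wolves, init_positions = NULL) {
  if (n_wolves < 3) {
    stop("n_wolves must be >= 3 so that all three leaders exist",
         call. = FALSE)
  }
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(lower >= upper)) stop("need lower < upper elementwise", call. = FALSE)
  positions <- matrix(stats::runif(n_wolves * d), n_wolves, d)
  positions <- sweep(sweep(positions, 2L, upper - lower, "*"), 2L, lower, "+")
  if (!is.null(init_positions)) {
    init_positions <- matrix(init_positions, ncol = d)
    m <- min(nrow(init_positions), n_wolves)
    for (i in seq_len(m)) {
      positions[i, ] <- pmin(pmax(init_positions[i, ], lower), upper)
    }
  }
  fitness <- gwo_evaluate(fn, positions)
  state <- list(positions = positions, fitness = fitness,
                leaders = matrix(NA_real_, 3L, d),
                leader_fitness = rep(Inf, 3L),
                lower = lower, upper = upper,
                k = 0L, k_max = NA_integer_, n_eval = 0L)
  class(state) <- "gwo_state"
  gwo_rank_leaders(state, positions, fitness)
}

gwo_evaluate <- function(fn, positions) {
  fitness <- vapply(seq_len(nrow(positions)),
                    function(i) as.numeric(fn(positions[i, ])), numeric(1L))
  bad <- which(!is.finite(fitness))
  if (length(bad) > 0L) {
    stop("non-finite fitness for wolf ", bad[1L], call. = FALSE)
  }
  fitness
}

# Fold new evaluations (in order) into the best-so-far top three.
# Strictly-better insertion keeps the earliest evaluation on ties.
gwo_rank_leaders <- function(state, positions, fitness) {
  for (i in seq_along(fitness)) {
    f <- fitness[i]
    slot <- which(f < state$leader_fitness)
    if (length(slot) > 0L) {
      j <- slot[1L]
      if (j < 3L) {
        keep <- setdiff(seq_len(3L), 3L)[setdiff(seq_len(3L), 3L) >= j]
        state$leaders[seq(j + 1L, 3L), ] <- state$leaders[keep, , drop = FALSE]
        state$leader_fitness[seq(j + 1L, 3L)] <- state$leader_fitness[keep]
      }
      state$leaders[j, ] <- positions[i, ]
      state$leader_fitness[j] <- f
    }
  }
  state$n_eval <- state$n_eval + length(fitness)
  state
}

#' One leader-guided position update (advanced use)
#'
#' Moves every wolf to the clipped average of the three leader-guided
#' candidates, re-evaluates the pack, folds the new evaluations into the
#' best-so-far leaders and increments the iteration counter. Exposed
#' mainly for stepwise inspection; [gwo_optimize()] drives it.
#'
#' @param state A `gwo_state` from within [gwo_optimize()].
#' @param fn Objective function.
#' @param omega Convergence factor; defaults to the linear schedule at the
#'   state's current iteration (requires `state$k_max`).
#' @param rand Uniform(0,1) generator, injectable for deterministic tests.
#' @return Updated `gwo_state`.
#' @export
gwo_update_positions <- function(state, fn, omega = NULL,
                                 rand = stats::runif) {
  stopifnot(inherits(state, "gwo_state"))
  if (is.null(omega)) {
    omega <- if (is.na(state$k_max)) 1 else
      convergence_factor(min(state$k, state$k_max), state$k_max)
  }
  d <- ncol(state$positions)
  new_pos <- state$positions
  for (i in seq_len(nrow(state$positions))) {
    w <- state$positions[i, ]
    cand <- matrix(0, 3L, d)
    for (l in seq_len(3L)) {
      co <- gwo_coefficients(omega, d, rand)
      dist <- encircle_distance(w, state$leaders[l, ], co$N)
      cand[l, ] <- state$leaders[l, ] - co$M * dist
    }
    new_pos[i, ] <- pmin(pmax(colMeans(cand), state$lower), state$upper)
  }
  fitness <- gwo_evaluate(fn, new_pos)
  state$positions <- new_pos
  state$fitness <- fitness
  state <- gwo_rank_leaders(state, new_pos, fitness)
  state$k <- state$k + 1L
  state
}

#' @export
print.gwo_result <- function(x, ...) {
  cat("Grey wolf optimization result\n")
  cat("  dimensions:", length(x$par), "  evaluations:", x$n_eval, "\n")
  cat("  best fitness:", format(x$value), "\n")
  invisible(x)
}

#' Export a fitness trace as a two-column table
#'
#' @param result A `gwo_result`.
#' @param path Optional CSV path; when given the table is also written.
#' @return Data frame with columns `iteration` and `best_fitness`.
#' @export
gwo_trace <- function(result, path = NULL) {
  df <- data.frame(iteration = seq_along(result$trace) - 1L,
                   best_fitness = result$trace)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
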