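#' Forward stepwise multiple linear regression
#'
#' Builds the linear yield model
#' `Y = e0 + e1*X1 + ... + ez*Xz` by forward selection with a backward
#' look: at each step the candidate with the smallest partial-F p-value
#' enters if it clears `alpha_enter`, then any included variable whose
#' p-value has drifted above `alpha_remove` is dropped. Selection stops
#' when no candidate can enter. The partial F-test for a single candidate
#' is equivalent to the t-test on its coefficient in the enlarged model.
#'
#' By default the entry p-value is Bonferroni-adjusted for the number of
#' candidates screened at that step (`adjust = "bonferroni"`), so the
#' chance of admitting *any* pure-noise variable at a step is about
#' `alpha_enter` rather than `alpha_enter` per candidate. Set
#' `adjust = "none"` for the classic per-candidate rule used by
#' commercial stepwise implementations.
#'
#' @param X Candidate predictor matrix or data frame (columns named).
#' @param y Response vector (e.g. yield).
#' @param alpha_enter Significance level to enter (default 0.05).
#' @param alpha_remove Significance level to remove (default 0.10); must
#'   be at least `alpha_enter`.
#' @param adjust `"bonferroni"` (default) or `"none"` -- multiplicity
#'   handling of the entry test.
#' @return An object of class `stepwise_model` with elements `intercept`,
#'   `coefficients` (named, selected predictors only), `selected`,
#'   `r_squared`, `sigma2` (residual variance), `steps` (selection log)
#'   and the final `lm` fit.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(500), 100, 5,
#'             dimnames = list(NULL, paste0("X", 1:5)))
#' y <- 2 * X[, 1] - 3 * X[, 2] + rnorm(100, sd = 0.5)
#' forward_stepwise(X, y)$selected
forward_stepwise <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.10,
                             adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (alpha_enter > alpha_remove) {
    stop("alpha_enter must not exceed alpha_remove", call. = FALSE)
  }
  df <- as.data.frame(as.matrix(X))
  if (is.null(colnames(X))) names(df) <- paste0("X", seq_along(df))
  y <- as.numeric(y)
  stopifnot(nrow(df) == length(y))
  if (nrow(df) <= ncol(df) + 1L) {
    stop("need n > number of candidates + 1", call. = FALSE)
  }
  const <- vapply(df, function(v) stats::var(v) == 0, TRUE)
  if (any(const)) {
    warning("excluding zero-variance candidate(s): ",
            paste(names(df)[const], collapse = ", "))
    df <- df[, !const, drop = FALSE]
  }
  data <- cbind(.y = y, df)
  candidates <- names(df)
  selected <- character(0)
  steps <- list()

  fit_on <- function(vars) {
    fml <- if (length(vars) == 0L) .y ~ 1 else
      stats::reformulate(vars, response = ".y")
    stats::lm(fml, data = data)
  }
  coef_p <- function(fit, var) {
    cf <- summary(fit)$coefficients
    if (!var %in% rownames(cf)) return(NA_real_)
    cf[var, "Pr(>|t|)"]
  }

  fit <- fit_on(selected)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    pvals <- vapply(remaining, function(v) {
      coef_p(fit_on(c(selected, v)), v)
    }, numeric(1L))
    pvals[is.na(pvals)] <- 1  # collinear with current set: can never enter
    p_entry <- if (adjust == "bonferroni") {
      pmin(pvals * length(remaining), 1)
    } else pvals
    best <- which.min(p_entry)  # ties: earliest candidate column
    if (p_entry[best] >= alpha_enter) break
    entering <- remaining[best]
    selected <- c(selected, entering)
    fit <- fit_on(selected)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, action = "enter", variable = entering,
      p_value = pvals[best], r_squared = summary(fit)$r.squared)
    # backward look: drop anything whose (unadjusted) p-value now exceeds
    # the removal threshold, worst first
    repeat {
      if (length(selected) == 0L) break
      p_in <- vapply(selected, function(v) coef_p(fit, v), numeric(1L))
      worst <- which.max(p_in)
      if (is.na(p_in[worst]) || p_in[worst] <= alpha_remove) break
      leaving <- selected[worst]
      selected <- setdiff(selected, leaving)
      fit <- fit_on(selected)
      steps[[length(steps) + 1L]] <- data.frame(
        step = length(steps) + 1L, action = "remove", variable = leaving,
        p_value = p_in[worst], r_squared = summary(fit)$r.squared)
    }
  }

  if (any(!is.finite(stats::coef(fit)))) {
    stop("rank-deficient final design", call. = FALSE)
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  structure(list(
    intercept = unname(cf["(Intercept)"]),
    coefficients = cf[setdiff(names(cf), "(Intercept)")],
    selected = selected,
    z = length(selected),
    alpha_enter = alpha_enter, alpha_remove = alpha_remove, adjust = adjust,
    r_squared = sm$r.squared, sigma2 = sm$sigma^2,
    sse = sum(stats::residuals(fit)^2),
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(), action = character(),
                 variable = character(), p_value = numeric(),
                 r_squared = numeric()),
    fit = fit), class = "stepwise_model")
}

#' Predict yield from a stepwise model
#'
#' Evaluates `e0 + sum(e_i * X_i)` over the selected predictors.
#'
#' @param object A `stepwise_model`.
#' @param newdata Matrix or data frame containing every selected predictor
#'   column.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  nd <- as.data.frame(as.matrix(newdata))
  missing <- setdiff(object$selected, names(nd))
  if (length(missing) > 0L) {
    stop("newdata is missing selected predictor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- rep(object$intercept, nrow(nd))
  for (v in object$selected) out <- out + object$coefficients[[v]] * nd[[v]]
  out
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("Forward stepwise linear model (", x$z, " of ",
      length(unique(c(x$selected, x$steps$variable))),
      "+ candidates selected)\n", sep = "")
  cat("  intercept:", format(x$intercept, digits = 5), "\n")
  if (x$z > 0) {
    cat("  coefficients:\n")
    print(round(x$coefficients, 5))
  }
  cat("  R-squared:", format(x$r_squared, digits = 4), "\n")
  invisible(x)
}
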