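#' Mean absolute percentage error (MAPE)
#'
#' `100 / t * sum(|actual - predicted| / |actual|)`. Undefined when any
#' actual value is (numerically) zero; soil nutrient contents and yields
#' are strictly positive so the guard should never trigger on real data.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @param eps Guard: every `|actual|` must be at least `eps`.
#' @return MAPE in percent.
#' @export
#' @examples
#' mape(c(100, 200), c(110, 180))  # 10
mape <- function(actual, predicted, eps = 1e-8) {
  check_pair(actual, predicted)
  if (any(abs(actual) < eps)) {
    stop("mape undefined: |actual| < ", format(eps),
         " for some observations; raise `eps` only if you know the target ",
         "scale permits it", call. = FALSE)
  }
  100 * mean(abs(actual - predicted) / abs(actual))
}

#' Mean absolute error (MAE)
#'
#' @inheritParams mape
#' @return MAE in the target's units.
#' @export
mae <- function(actual, predicted) {
  check_pair(actual, predicted)
  mean(abs(actual - predicted))
}

#' Coefficient of determination (R-squared)
#'
#' `1 - SSE/SST` with the total sum of squares taken about the mean of the
#' *actual* values, the standard definition. Can be negative for models
#' worse than predicting the mean.
#'
#' @inheritParams mape
#' @return R-squared, dimensionless, at most 1.
#' @export
r_squared <- function(actual, predicted) {
  check_pair(actual, predicted)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) {
    stop("r_squared undefined: actual values are constant (SST = 0)",
         call. = FALSE)
  }
  1 - sum((actual - predicted)^2) / sst
}

check_pair <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted have different lengths", call. = FALSE)
  }
  if (length(actual) < 1L) stop("need at least one observation", call. = FALSE)
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) {
    stop("non-finite values in actual/predicted", call. = FALSE)
  }
  invisible(TRUE)
}

#' All three evaluation metrics at once
#'
#' @inheritParams mape
#' @return Named numeric vector `c(MAPE=, MAE=, R2=)`.
#' @export
evaluate_predictions <- function(actual, predicted) {
  c(MAPE = mape(actual, predicted),
    MAE = mae(actual, predicted),
    R2 = r_squared(actual, predicted))
}

#' Relative change between two metric values, in percent
#'
#' For error metrics one reports a *reduction*,
#' `100 * (reference - new) / reference`; for goodness-of-fit metrics an
#' *increase*, `100 * (new - reference) / reference`. The raw value is
#' returned; reports round to two decimals for presentation.
#'
#' @param reference Metric value of the comparison model (nonzero).
#' @param new Metric value of the model of interest.
#' @param direction `"reduction"` or `"increase"`.
#' @return Percent change (raw, unrounded).
#' @export
#' @examples
#' relative_change(4.82, 1.61, "reduction")  # ~66.60
relative_change <- function(reference, new,
                            direction = c("reduction", "increase")) {
  direction <- match.arg(direction)
  if (isTRUE(any(reference == 0))) {
    stop("relative_change undefined for reference = 0", call. = FALSE)
  }
  switch(direction,
         reduction = 100 * (reference - new) / reference,
         increase = 100 * (new - reference) / reference)
}

#' Relative-change columns for a metrics table
#'
#' Takes a table of metric values (rows `MAPE`, `MAE`, `R2`; one column per
#' model) and appends, for every non-reference model, the percent change of
#' the reference model relative to it: reductions for MAPE/MAE, increases
#' for R2. This is the arithmetic behind statements like "the MAPE of the
#' proposed model is reduced by 66.60% relative to the BPNN".
#'
#' @param metrics Data frame or matrix with rownames `MAPE`, `MAE`, `R2`
#'   and one column per model.
#' @param reference Column name of the model the changes are credited to
#'   (default: last column).
#' @return Data frame: original columns plus `vs_<model>` change columns,
#'   rounded to two decimals (half-up) in the `*_rounded` attribute-free
#'   display; raw values kept.
#' @export
metric_comparison <- function(metrics, reference = NULL) {
  m <- as.data.frame(metrics)
  required <- c("MAPE", "MAE", "R2")
  if (!all(required %in% rownames(m))) {
    stop("metrics table must have rows MAPE, MAE and R2", call. = FALSE)
  }
  m <- m[required, , drop = FALSE]
  if (is.null(reference)) reference <- names(m)[ncol(m)]
  if (!reference %in% names(m)) {
    stop("reference model '", reference, "' not in table", call. = FALSE)
  }
  others <- setdiff(names(m), reference)
  out <- m
  for (other in others) {
    chg <- c(
      relative_change(m[["MAPE", other]], m[["MAPE", reference]], "reduction"),
      relative_change(m[["MAE", other]], m[["MAE", reference]], "reduction"),
      relative_change(m[["R2", other]], m[["R2", reference]], "increase"))
    out[[paste0("vs_", other)]] <- chg
  }
  out
}

#' Compare fitted models on a shared validation set
#'
#' Computes MAPE/MAE/R2 for each (actual, predicted) pair and, when more
#' than one model is supplied, appends relative-change columns against a
#' designated reference model via [metric_comparison()]. All pairs must
#' share the same actual vector (same validation split).
#'
#' @param predictions Named list; each element either a numeric vector of
#'   predictions or a list with elements `actual` and `predicted`.
#' @param actual Common actual vector (required when `predictions` holds
#'   bare prediction vectors).
#' @param reference Name of the reference model for change columns
#'   (default: last element of `predictions`).
#' @return Data frame with rows `MAPE`, `MAE`, `R2`.
#' @export
compare_models <- function(predictions, actual = NULL, reference = NULL) {
  stopifnot(is.list(predictions), length(predictions) >= 1L,
            !is.null(names(predictions)))
  pairs <- lapply(predictions, function(p) {
    if (is.list(p)) list(actual = p$actual, predicted = p$predicted)
    else list(actual = actual, predicted = p)
  })
  ref_actual <- pairs[[1L]]$actual
  if (is.null(ref_actual)) stop("no actual values supplied", call. = FALSE)
  for (p in pairs) {
    if (!isTRUE(all.equal(p$actual, ref_actual, tolerance = 0))) {
      stop("all models must be evaluated against the same actual vector",
           call. = FALSE)
    }
  }
  metrics <- vapply(pairs, function(p)
    evaluate_predictions(p$actual, p$predicted), numeric(3L))
  metrics <- as.data.frame(metrics)
  if (length(predictions) == 1L) return(metrics)
  metric_comparison(metrics, reference = reference)
}

#' Round half-up to a fixed number of decimals
#'
#' Presentation rounding used in comparison tables (base `round()` rounds
#' half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
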