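#' Seeded multi-model benchmark on synthetic soil data
#'
#' For every seed: generate a dataset, make the 7:3 train/validation
#' split, standardize on the training split only, train every requested
#' model on the identical split, and score MAPE/MAE/R2 on the validation
#' records in original units. Per-model medians across seeds are
#' summarized into a comparison table with relative-change columns
#' against a designated reference model. All models in a given seed share
#' the same split and the same standardization parameters (fairness
#' contract).
#'
#' @param config A [synthetic_config()] describing the data-generating
#'   conditions; its `seed` field is overridden per run by `seeds`.
#' @param models Character subset of `c("IM-RBNNA", "RBNNA", "BPNN")`.
#' @param seeds Integer vector of run seeds (one dataset/split per seed).
#' @param ratio Training fraction of the split (default 0.7).
#' @param train_cfg A [train_config()] shared by the RBF-based models.
#' @param bpnn_cfg A [bpnn_config()] for the BPNN (its seed is overridden
#'   per run).
#' @param target,predictors Passed to [fit_soil_model()].
#' @param reference Model credited in the relative-change columns
#'   (default `"IM-RBNNA"` when present).
#' @param external Optional named list of externally supplied metric
#'   vectors `c(MAPE=, MAE=, R2=)` appended as extra columns of the
#'   summary (e.g. literature values for a comparator that is not
#'   implemented here).
#' @return Object of class `soil_benchmark`: `per_seed` (long data frame),
#'   `summary` (median metrics, rows MAPE/MAE/R2), `comparison`
#'   (summary plus relative-change columns), `failures`.
#' @export
run_benchmark <- function(config = synthetic_config(),
                          models = c("IM-RBNNA", "RBNNA", "BPNN"),
                          seeds = 1:10, ratio = 0.7,
                          train_cfg = train_config(),
                          bpnn_cfg = bpnn_config(),
                          target = "yield_actual",
                          predictors = c("alk_N", "avail_P", "avail_K"),
                          reference = NULL, external = NULL) {
  models <- match.arg(models, c("IM-RBNNA", "RBNNA", "BPNN"),
                      several.ok = TRUE)
  stopifnot(length(models) >= 1L, length(seeds) >= 1L)
  method_of <- c("IM-RBNNA" = "imrbnna", "RBNNA" = "rbnna", "BPNN" = "bpnn")
  rows <- list()
  failures <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- generate_soil_data(cfg)
    sp <- split_soil_data(sim$data, ratio = ratio, seed = s)
    for (m in models) {
      mc <- if (m == "BPNN") {
        bc <- bpnn_cfg; bc$seed <- as.integer(s); bc
      } else {
        tc <- train_cfg; tc$seed <- as.integer(s); tc
      }
      res <- tryCatch({
        fit <- fit_soil_model(sp$train, target = target,
                              predictors = predictors,
                              method = method_of[[m]], config = mc)
        evaluate_soil_model(fit, sp$validation)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(seed = s, model = m, message = conditionMessage(res))
        res <- c(MAPE = NA_real_, MAE = NA_real_, R2 = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, model = m, MAPE = res[["MAPE"]], MAE = res[["MAE"]],
        R2 = res[["R2"]])
    }
  }
  per_seed <- do.call(rbind, rows)
  summary <- vapply(models, function(m) {
    d <- per_seed[per_seed$model == m, ]
    c(MAPE = stats::median(d$MAPE, na.rm = TRUE),
      MAE = stats::median(d$MAE, na.rm = TRUE),
      R2 = stats::median(d$R2, na.rm = TRUE))
  }, numeric(3L))
  summary <- as.data.frame(summary, check.names = FALSE)
  if (!is.null(external)) {
    for (nm in names(external)) {
      summary[[nm]] <- external[[nm]][c("MAPE", "MAE", "R2")]
    }
  }
  if (is.null(reference)) {
    reference <- if ("IM-RBNNA" %in% names(summary)) "IM-RBNNA"
                 else names(summary)[ncol(summary)]
  }
  comparison <- if (ncol(summary) > 1L) {
    metric_comparison(summary, reference = reference)
  } else summary
  structure(list(per_seed = per_seed, summary = summary,
                 comparison = comparison, reference = reference,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 seeds = seeds, target = target),
            class = "soil_benchmark")
}

#' @export
print.soil_benchmark <- function(x, ...) {
  cat("Benchmark on", length(x$seeds), "seeds; target:", x$target, "\n")
  cat("Median validation metrics:\n")
  print(round_half_up(as.matrix(x$comparison), 2))
  if (!is.null(x$failures)) {
    cat("Failures:\n")
    print(x$failures)
  }
  invisible(x)
}

#' Write a benchmark comparison table to CSV
#'
#' @param benchmark A `soil_benchmark`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(benchmark, path) {
  tab <- cbind(metric = rownames(benchmark$comparison),
               round_half_up(as.data.frame(benchmark$comparison), 2))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
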