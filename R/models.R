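#' Fit a soil nutrient / yield prediction model
#'
#' High-level wrapper tying standardization and training together so the
#' same workflow serves all three model families. Predictor columns are
#' standardized with parameters estimated on the supplied (training) data
#' only; the parameters travel with the model and are re-applied at
#' prediction time, so validation data never leaks into them. One model
#' predicts one target variable.
#'
#' @param data A [soil_data] table (or data frame) holding the training
#'   split.
#' @param target Name of the target column (default `"yield_actual"`).
#' @param predictors Predictor column names; default the three soil
#'   nutrient contents.
#' @param method `"imrbnna"` (grey-wolf-trained RBF network, the default),
#'   `"rbnna"` (plain RBF baseline) or `"bpnn"` (backpropagation
#'   baseline).
#' @param config A [train_config()] for `"imrbnna"` / `"rbnna"` (its `K`
#'   and `seed` are used by the plain baseline), or a [bpnn_config()] for
#'   `"bpnn"`.
#' @return Object of class `soil_model`: `model`, `method`, `target`,
#'   `predictors`, input (and for BPNN target) standardization parameters,
#'   and the training seed.
#' @export
#' @examples
#' sim <- generate_soil_data(synthetic_config(n = 80, seed = 1))
#' fit <- fit_soil_model(sim$data, method = "rbnna",
#'                       config = train_config(K = 5, seed = 1))
#' head(predict(fit, sim$data))
fit_soil_model <- function(data, target = "yield_actual",
                           predictors = c("alk_N", "avail_P", "avail_K"),
                           method = c("imrbnna", "rbnna", "bpnn"),
                           config = NULL) {
  method <- match.arg(method)
  df <- as.data.frame(data)
  missing <- setdiff(c(target, predictors), names(df))
  if (length(missing) > 0L) {
    stop("data is missing column(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  std <- standardize(df, columns = predictors)
  y <- df[[target]]
  target_params <- NULL
  if (method == "imrbnna") {
    if (is.null(config)) config <- train_config()
    model <- train_gwo_rbf(std$values, y, config = config)
    seed <- config$seed
  } else if (method == "rbnna") {
    if (is.null(config)) config <- train_config()
    model <- train_plain_rbf(std$values, y, K = config$K, seed = config$seed)
    seed <- config$seed
  } else {
    if (is.null(config)) config <- bpnn_config()
    ty <- standardize(matrix(y, ncol = 1L, dimnames = list(NULL, target)))
    target_params <- ty$params
    model <- train_bpnn(std$values, drop(ty$values), config = config)
    seed <- config$seed
  }
  structure(list(model = model, method = method, target = target,
                 predictors = predictors, input_params = std$params,
                 target_params = target_params, config = config,
                 seed = seed),
            class = "soil_model")
}

#' @export
predict.soil_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  X <- apply_standardization(object$input_params,
                             df[, object$predictors, drop = FALSE])
  pred <- predict(object$model, X)
  if (!is.null(object$target_params)) {
    pred <- drop(inverse_standardize(
      matrix(pred, ncol = 1L, dimnames = list(NULL, object$target)),
      object$target_params))
  }
  unname(pred)
}

#' Evaluate a fitted soil model on a dataset
#'
#' @param object A `soil_model`.
#' @param data Dataset containing the target and predictor columns.
#' @return Named vector `c(MAPE=, MAE=, R2=)`.
#' @export
evaluate_soil_model <- function(object, data) {
  df <- as.data.frame(data)
  evaluate_predictions(df[[object$target]], predict(object, df))
}

#' @export
print.soil_model <- function(x, ...) {
  cat("Soil prediction model [", toupper(x$method), "] for target '",
      x$target, "'\n", sep = "")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("  training seed:", x$seed, "\n")
  invisible(x)
}

#' Save a fitted soil model as a JSON document
#'
#' Serializes the network parameters, the standardization parameters, the
#' configuration and the seed, so a saved model is a complete, portable
#' description of a run.
#'
#' @param object A `soil_model` (methods `imrbnna` or `rbnna`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_soil_model <- function(object, path) {
  stopifnot(inherits(object, "soil_model"))
  if (object$method == "bpnn") {
    stop("JSON serialization covers the RBF-based models", call. = FALSE)
  }
  net <- if (inherits(object$model, "gwo_rbf_fit")) object$model$net
         else object$model
  doc <- list(
    method = object$method, target = object$target,
    predictors = object$predictors, seed = object$seed,
    network = list(K = net$K, d = net$d,
                   centers = unclass(net$centers),
                   widths = net$widths, weights = net$weights,
                   bias = net$bias),
    standardization = list(mean = as.list(object$input_params$mean),
                           scale = as.list(object$input_params$scale),
                           convention = object$input_params$convention,
                           columns = object$input_params$columns),
    config = unclass(object$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a soil model saved by [save_soil_model()]
#'
#' @param path JSON file path.
#' @return A `soil_model` usable with `predict()`.
#' @export
load_soil_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- rbf_network(matrix(doc$network$centers, doc$network$K,
                            doc$network$d),
                     doc$network$widths, doc$network$weights,
                     doc$network$bias)
  params <- structure(
    list(mean = unlist(doc$standardization$mean),
         scale = unlist(doc$standardization$scale),
         convention = doc$standardization$convention,
         columns = doc$standardization$columns),
    class = "standardization_params")
  structure(list(model = net, method = doc$method, target = doc$target,
                 predictors = doc$predictors, input_params = params,
                 target_params = NULL, config = doc$config,
                 seed = doc$seed),
            class = "soil_model")
}
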