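#' Canonical soil-sample column names
#'
#' The plot-level schema used throughout the package: three soil nutrient
#' assays (mg/kg), three fertilizer application amounts (kg/ha) and the
#' measured yield (kg).
#'
#' @format A character vector of the seven numeric column names, in table
#'   order: `alk_N`, `avail_P`, `avail_K`, `applied_P`, `applied_N`,
#'   `applied_K`, `yield_actual`.
#' @export
soil_columns <- c("alk_N", "avail_P", "avail_K",
                  "applied_P", "applied_N", "applied_K", "yield_actual")

#' Construct a validated soil-sample table
#'
#' A soil-sample table is a plain `data.frame` carrying one record per
#' orchard plot: a unique `plot_id` label plus the seven numeric columns of
#' [soil_columns]. Nutrient contents are in mg/kg (alkaline-hydrolyzable
#' nitrogen, available phosphorus, available potassium), fertilizer
#' applications in kg/ha, yield in kg.
#'
#' @param df A data frame with a `plot_id` column and the seven numeric
#'   columns of [soil_columns].
#' @return The validated data frame with class `soil_data` prepended.
#' @export
#' @examples
#' soil_data(orchard_samples())
soil_data <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(c("plot_id", soil_columns), names(df))
  if (length(missing) > 0L) {
    stop("soil data is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$plot_id <- as.character(df$plot_id)
  for (col in soil_columns) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    if (nrow(df) > 0L && any(!is.finite(v))) {
      stop("column '", col, "' contains non-finite values", call. = FALSE)
    }
  }
  nonneg <- setdiff(soil_columns, "yield_actual")
  for (col in nonneg) {
    if (nrow(df) > 0L && any(df[[col]] < 0)) {
      stop("column '", col, "' contains negative values", call. = FALSE)
    }
  }
  if (anyDuplicated(df$plot_id)) {
    stop("plot_id values must be unique", call. = FALSE)
  }
  df <- df[, c("plot_id", soil_columns)]
  class(df) <- unique(c("soil_data", class(df)))
  df
}

#' Read a plot-level soil sample table from CSV
#'
#' Reads a UTF-8, comma-separated file with a header row. The header must
#' contain `plot_id` and the seven numeric columns of [soil_columns];
#' verbose survey-style headers can be renamed on the fly through
#' `col_map`.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping file column names
#'   to canonical names, e.g. `c("Available potassium K (mg/kg)" = "avail_K")`.
#' @return A [soil_data] data frame, rows in file order.
#' @export
read_soil_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- unname(col_map[names(df)[hit]])
  }
  missing <- setdiff(c("plot_id", soil_columns), names(df))
  if (length(missing) > 0L) {
    stop("schema error: file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in soil_columns) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & nzchar(trimws(raw)))
    if (length(bad) > 0L) {
      stop("parse error in column '", col, "', row ", bad[1L],
           ": '", raw[bad[1L]], "' is not numeric", call. = FALSE)
    }
    if (anyNA(num)) {
      stop("parse error in column '", col, "': empty or missing value",
           call. = FALSE)
    }
    df[[col]] <- num
  }
  soil_data(df)
}

#' Write a soil sample table to CSV
#'
#' @param data A [soil_data] data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_soil_csv <- function(data, path) {
  data <- soil_data(as.data.frame(data))
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Example nutrient records from a durian orchard
#'
#' Ten plot-level records sampled in a durian orchard in Penang, Malaysia:
#' soil nutrient assays, fertilizer application amounts and measured yield.
#' Useful as a small worked-example dataset and as the calibration source of
#' the `"table1"` synthetic preset (see [synthetic_config()]).
#'
#' @return A [soil_data] data frame with 10 rows.
#' @export
#' @examples
#' head(orchard_samples())
orchard_samples <- function() {
  path <- system.file("extdata", "durian_orchard_plots.csv",
                      package = "gwrbf", mustWork = TRUE)
  read_soil_csv(path)
}

#' Reference benchmark metrics for four prediction algorithms
#'
#' Published performance figures (MAPE in percent, MAE in target units,
#' R-squared) of four algorithms -- a plain RBF network (RBNNA), a nutrient
#' balance calculation (NUBCA), a backpropagation network (BPNN) and the
#' grey-wolf-optimised RBF network (IM-RBNNA) -- on a durian-orchard
#' benchmark, one table per predicted target (soil nitrogen, phosphorus,
#' potassium, and yield). Used to demonstrate the relative-change
#' machinery of [metric_comparison()].
#'
#' @return A named list of data frames, one per target, each with rows
#'   `MAPE`, `MAE`, `R2` and one column per algorithm.
#' @export
reference_benchmark_metrics <- function() {
  path <- system.file("extdata", "algorithm_benchmark_metrics.csv",
                      package = "gwrbf", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  split_by <- factor(df$target, levels = unique(df$target))
  out <- lapply(split(df, split_by), function(d) {
    m <- d[, setdiff(names(d), c("target", "metric")), drop = FALSE]
    rownames(m) <- d$metric
    m
  })
  out
}
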