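#' Default e-tongue sensor names
#'
#' The seven cross-sensitive bitterness sensors of the array, in the
#' column order used throughout the package.
#' @export
ETONGUE_SENSORS <- c("ZZ", "CA", "DA", "BA", "GA", "BB", "AB")

#' Average the stabilized tail of a replicate series
#'
#' E-tongue signals fluctuate during the first acquisition cycles and then
#' stabilize; only the final per-cycle values are informative.  The sample
#' response is the arithmetic mean of the last `n_last` cycle values.
#'
#' @param readings numeric vector of per-cycle final values, in
#'   acquisition order.
#' @param n_last number of trailing cycles to average (default 4).
#' @param sample_id,sensor_name identifiers used in error messages.
#' @return scalar averaged response.
#' @export
average_replicates <- function(readings, n_last = 4,
                               sample_id = "?", sensor_name = "?") {
  stopifnot_numeric(readings, "readings")
  if (length(readings) < n_last) {
    stop(sprintf(
      "sample %s, sensor %s: %d readings but %d required for averaging",
      sample_id, sensor_name, length(readings), n_last
    ), call. = FALSE)
  }
  mean(utils::tail(readings, n_last))
}

#' Assemble a samples-by-sensors matrix from replicate series
#'
#' @param all_series data frame with columns `sample_id`, `sensor`,
#'   `cycle`, `value` (long format, one row per cycle), or a list of
#'   per-(sample, sensor) numeric vectors named `"<sample>.<sensor>"`.
#' @param sensor_order character vector fixing the column order.
#' @param n_last trailing cycles averaged per series.
#' @return numeric matrix, rows named by sample id (input order of first
#'   appearance), columns by sensor.
#' @export
assemble_matrix <- function(all_series, sensor_order = ETONGUE_SENSORS,
                            n_last = 4) {
  if (is.data.frame(all_series)) {
    need <- c("sample_id", "sensor", "cycle", "value")
    if (!all(need %in% names(all_series))) {
      stop("long-format series need columns sample_id, sensor, cycle, value",
           call. = FALSE)
    }
    ids <- unique(as.character(all_series$sample_id))
    all_series <- all_series[order(all_series$cycle), , drop = FALSE]
    series <- split(
      all_series$value,
      list(sample = as.character(all_series$sample_id),
           sensor = as.character(all_series$sensor)),
      drop = TRUE, sep = "\r"
    )
  } else {
    stop("all_series must be a long-format data frame", call. = FALSE)
  }

  X <- matrix(NA_real_, nrow = length(ids), ncol = length(sensor_order),
              dimnames = list(ids, sensor_order))
  for (id in ids) {
    for (sn in sensor_order) {
      key <- paste(id, sn, sep = "\r")
      if (is.null(series[[key]])) next
      X[id, sn] <- average_replicates(series[[key]], n_last,
                                      sample_id = id, sensor_name = sn)
    }
  }
  extra <- setdiff(unique(as.character(all_series$sensor)), sensor_order)
  if (length(extra)) {
    stop("unknown sensors in series: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(X)) {
    gaps <- which(is.na(X), arr.ind = TRUE)
    msg <- paste(sprintf("(%s, %s)", rownames(X)[gaps[, 1]],
                         colnames(X)[gaps[, 2]]), collapse = ", ")
    stop("missing (sample, sensor) pairs: ", msg, call. = FALSE)
  }
  dup <- table(paste(all_series$sample_id, all_series$sensor,
                     all_series$cycle, sep = "\r"))
  if (any(dup > 1)) {
    stop("duplicate (sample, sensor, cycle) rows in replicate series",
         call. = FALSE)
  }
  X
}

#' Construct an e-tongue calibration dataset
#'
#' Pairs the samples-by-sensors predictor matrix with the panel
#' bitterness response.  The container used by all model fitting.
#'
#' @param X numeric matrix (n x p) of averaged sensor responses.
#' @param y numeric response vector of panel bitterness means.
#' @param ids sample identifiers (default: rownames of X or 1..n).
#' @return object of class `etongue_dataset` with elements `X`, `y`,
#'   `ids`, `n`, `p`.
#' @export
etongue_dataset <- function(X, y, ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot_numeric(as.numeric(X), "X")
  stopifnot_numeric(y, "y")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  ids <- ids %||% rownames(X) %||% as.character(seq_len(nrow(X)))
  if (nrow(X) <= ncol(X)) {
    warning("n <= p: classical full-rank fits will be unavailable",
            call. = FALSE)
  }
  structure(
    list(X = X, y = as.numeric(y), ids = as.character(ids),
         n = nrow(X), p = ncol(X)),
    class = "etongue_dataset"
  )
}

#' @export
print.etongue_dataset <- function(x, ...) {
  cat(sprintf("e-tongue dataset: %d samples x %d sensors (%s)\n",
              x$n, x$p, paste(colnames(x$X), collapse = ", ")))
  cat(sprintf("bitterness range: %.2f - %.2f\n", min(x$y), max(x$y)))
  invisible(x)
}

#' Read a calibration dataset from feature and response CSV files
#'
#' The features file is wide-format (`sample_id` plus one numeric column
#' per sensor); the response file has `sample_id` and `bitterness`
#' columns.  Rows are aligned by `sample_id`, preserving the order of the
#' features file.
#'
#' @param features_path CSV of averaged sensor responses.
#' @param response_path CSV of panel bitterness means.
#' @return an [etongue_dataset()].
#' @export
read_dataset <- function(features_path, response_path) {
  feats <- utils::read.csv(features_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  resp <- utils::read.csv(response_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(feats) || !"sample_id" %in% names(resp)) {
    stop("both CSV files need a sample_id column", call. = FALSE)
  }
  if (!"bitterness" %in% names(resp)) {
    stop("response CSV needs a bitterness column", call. = FALSE)
  }
  ids <- as.character(feats$sample_id)
  sens <- setdiff(names(feats), "sample_id")
  for (cn in sens) {
    if (!is.numeric(feats[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(feats[[cn]]))))[1]
      stop(sprintf("non-numeric cell in column %s, row %d of %s",
                   cn, bad, features_path), call. = FALSE)
    }
  }
  miss <- setdiff(ids, as.character(resp$sample_id))
  if (length(miss)) {
    stop("sample ids missing from response file: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- resp$bitterness[match(ids, as.character(resp$sample_id))]
  stopifnot_numeric(y, "bitterness")
  X <- as.matrix(feats[, sens, drop = FALSE])
  rownames(X) <- ids
  etongue_dataset(X, y, ids)
}

#' Write a sensor matrix to wide-format CSV
#'
#' @param X samples-by-sensors matrix with row and column names.
#' @param path output path.
#' @export
write_sensor_matrix <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
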