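# Validated CSV ingestion for the tabular inputs. All tabular formats are
# long (one value per row) so the schemas stay unambiguous; numbers are
# parsed locale-independently (period decimal separator).

MEASUREMENT_SCHEMAS <- list(
  icg = list(
    required = c("subject_id", "time_min", "concentration_ugml"),
    numeric = c("time_min", "concentration_ugml"),
    key = c("subject_id", "time_min")),
  doppler_features = list(
    required = c("subject_id", "vessel", "psv", "edv"),
    numeric = c("psv", "edv", "vti", "area", "diameter", "hr", "sv"),
    key = c("subject_id", "vessel")),
  doppler_trace = list(
    required = c("subject_id", "vessel", "time_s", "velocity_mms"),
    numeric = c("time_s", "velocity_mms"),
    key = c("subject_id", "vessel", "time_s")),
  weights = list(
    required = c("subject_id", "week", "weight_g"),
    numeric = c("week", "weight_g"),
    key = c("subject_id", "week")),
  analytes = list(
    required = c("subject_id", "week", "analyte", "value"),
    numeric = c("week", "value"),
    key = c("subject_id", "week", "analyte")))

#' Read and validate a measurement table
#'
#' Reads a long-format CSV against one of the known schemas, checking for
#' required columns, numeric parsability (malformed rows are reported with
#' their file line numbers) and duplicate key rows.
#'
#' @param path CSV path.
#' @param schema one of \code{"icg"} (subject_id, time_min,
#'   concentration_ugml), \code{"doppler_features"} (subject_id, vessel,
#'   psv, edv, and optionally vti, area, diameter, hr, sv),
#'   \code{"doppler_trace"} (subject_id, vessel, time_s, velocity_mms),
#'   \code{"weights"} (subject_id, week, weight_g) or \code{"analytes"}
#'   (subject_id, week, analyte, value).
#' @return the validated data.frame, with the schema name in attribute
#'   \code{"schema"}.
#' @export
read_measurements <- function(path, schema = names(MEASUREMENT_SCHEMAS)) {
  schema <- match.arg(schema)
  sc <- MEASUREMENT_SCHEMAS[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("empty or unreadable input file: ", path,
                             call. = FALSE))
  if (nrow(df) == 0L)
    stop("input file has a header but no data rows: ", path, call. = FALSE)
  missing_cols <- setdiff(sc$required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in intersect(sc$numeric, names(df))) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !(is.na(df[[col]]) | df[[col]] == "" |
                                     df[[col]] == "NA"))
    if (length(bad))
      stop(sprintf("non-numeric value(s) in column `%s` at line(s) %s", col,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    df[[col]] <- parsed
  }
  key <- do.call(paste, c(df[sc$key], sep = "\r"))
  if (anyDuplicated(key)) {
    dups <- which(duplicated(key))
    stop(sprintf("duplicate %s key(s) at line(s) %s",
                 paste(sc$key, collapse = "+"),
                 paste(dups + 1L, collapse = ", ")), call. = FALSE)
  }
  attr(df, "schema") <- schema
  df
}

#' Split a long ICG table into per-subject concentration series
#'
#' @param df a validated \code{"icg"} table from
#'   \code{\link{read_measurements}}, or any data.frame with the same
#'   columns.
#' @return named list of \code{\link{concentration_series}}.
#' @export
as_concentration_series <- function(df) {
  stopifnot(all(c("subject_id", "time_min", "concentration_ugml") %in%
                  names(df)))
  sapply(unique(df$subject_id), function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    concentration_series(id, sub$time_min, sub$concentration_ugml)
  }, simplify = FALSE)
}

#' Write a data frame as locale-independent CSV
#'
#' Full-precision numbers, period decimal separator, no row names.
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(df, path) {
  write.csv(format(df, trim = TRUE, digits = 15, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
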