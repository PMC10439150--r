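## Readers/writers for measurement tables and percentile tables.
## Measurement files are plain delimited text with a header; the delimiter is
## auto-detected among comma, semicolon and tab.  Decimal separator is ".".

.detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))))
  if (all(counts == 0)) stop("could not detect delimiter in ", path)
  names(counts)[which.max(counts)]
}

#' Read a routine-measurement table
#'
#' Reads delimiter-separated routine laboratory measurements (one row per
#' measurement) and validates them for pipeline entry.  Rows with
#' non-numeric or non-positive values, or missing/negative ages, are dropped
#' with a message reporting the count; fractional ages are floored.  The
#' pipeline is run per sex, so `sex_filter` is normally supplied to retain a
#' single stratum.
#'
#' @param path Path to a delimited text file with a header row; the
#'   delimiter (comma, semicolon or tab) is auto-detected.
#' @param column_map Named character vector mapping the required fields
#'   `value`, `age_days`, `sex`, `subject_id` to the file's column names.
#' @param sex_filter Optional sex code; only matching rows are retained.
#' @param analyte Optional analyte label stored with the data.
#' @param unit Optional unit label stored with the data.
#' @return A `data.frame` of class `measurement_set` with columns `value`
#'   (positive numeric), `age_days` (integer >= 0), `sex` (character) and
#'   `subject_id` (character), plus attributes `analyte` and `unit`.
#' @export
read_measurements <- function(path,
                              column_map = c(value = "value",
                                             age_days = "age_days",
                                             sex = "sex",
                                             subject_id = "subject_id"),
                              sex_filter = NULL,
                              analyte = "", unit = "") {
  if (!file.exists(path)) stop("input file not found: ", path)
  need <- c("value", "age_days", "sex", "subject_id")
  if (!all(need %in% names(column_map)))
    stop("column_map must name: ", paste(need, collapse = ", "))
  delim <- .detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE)
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(value = suppressWarnings(as.numeric(raw[[column_map["value"]]])),
                   age_days = suppressWarnings(as.numeric(raw[[column_map["age_days"]]])),
                   sex = trimws(raw[[column_map["sex"]]]),
                   subject_id = trimws(raw[[column_map["subject_id"]]]),
                   stringsAsFactors = FALSE)
  n0 <- nrow(df)
  if (!is.null(sex_filter)) {
    df <- df[df$sex == sex_filter, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("no rows remain for sex code '", sex_filter, "'")
  }
  frac <- is.finite(df$age_days) & df$age_days != floor(df$age_days)
  if (any(frac)) {
    message(sum(frac), " fractional age(s) floored to whole days")
    df$age_days <- floor(df$age_days)
  }
  keep <- is.finite(df$value) & df$value > 0 &
    is.finite(df$age_days) & df$age_days >= 0 &
    nzchar(df$subject_id)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " row(s) dropped during validation (non-positive or ",
            "non-numeric value, invalid age, or empty subject id)")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid measurements after validation")
  df$age_days <- as.integer(df$age_days)
  rownames(df) <- NULL
  measurement_set(df, analyte = analyte, unit = unit)
}

#' Construct a measurement set from a data frame
#'
#' @param df Data frame with columns `value`, `age_days`, `sex`,
#'   `subject_id`.
#' @param analyte,unit Labels stored as attributes.
#' @return The validated `measurement_set`.
#' @export
measurement_set <- function(df, analyte = "", unit = "") {
  need <- c("value", "age_days", "sex", "subject_id")
  if (!all(need %in% names(df)))
    stop("measurement set needs columns: ", paste(need, collapse = ", "))
  stopifnot(is.numeric(df$value), all(is.finite(df$value)), all(df$value > 0),
            all(df$age_days >= 0), all(nzchar(df$subject_id)))
  df$age_days <- as.integer(df$age_days)
  df$subject_id <- as.character(df$subject_id)
  attr(df, "analyte") <- analyte
  attr(df, "unit") <- unit
  class(df) <- c("measurement_set", "data.frame")
  df
}

#' Write a percentile table to delimited text
#'
#' One row per age (days), one column per percentile; when confidence bands
#' are present, each percentile contributes three columns (estimate, lower,
#' upper).  Values are written with enough digits to round-trip through
#' [read_percentile_table()] to within 1e-9.
#'
#' @param table A `percentile_table` as returned by [predict.ri_model()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return Invisibly, the path written.
#' @export
write_percentile_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "percentile_table"), nrow(table$values) > 0)
  probs <- table$probs
  lab <- sub("\\.?0+$", "", formatC(100 * probs, format = "f", digits = 3))
  out <- data.frame(age_days = table$ages, check.names = FALSE)
  for (j in seq_along(probs)) {
    out[[paste0("p", lab[j])]] <- table$values[, j]
    if (!is.null(table$ci_lower)) {
      out[[paste0("p", lab[j], "_lo")]] <- table$ci_lower[, j]
      out[[paste0("p", lab[j], "_hi")]] <- table$ci_upper[, j]
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open output path: ", path))
  on.exit(close(con))
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a percentile table written by [write_percentile_table()]
#'
#' @param path Path to the delimited file.
#' @return A `percentile_table` object.
#' @export
read_percentile_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE)
  est_cols <- grep("^p[0-9.]+$", names(df), value = TRUE)
  probs <- as.numeric(sub("^p", "", est_cols)) / 100
  values <- as.matrix(df[, est_cols, drop = FALSE])
  lo_cols <- paste0(est_cols, "_lo")
  ci_lower <- ci_upper <- NULL
  if (all(lo_cols %in% names(df))) {
    ci_lower <- as.matrix(df[, paste0(est_cols, "_lo"), drop = FALSE])
    ci_upper <- as.matrix(df[, paste0(est_cols, "_hi"), drop = FALSE])
  }
  percentile_table(ages = df$age_days, probs = probs, values = values,
                   ci_lower = ci_lower, ci_upper = ci_upper)
}

#' Construct a percentile table
#'
#' @param ages Integer ages in days (rows).
#' @param probs Strictly increasing probabilities (columns).
#' @param values Matrix `length(ages) x length(probs)` of percentile values.
#' @param ci_lower,ci_upper Optional confidence-band matrices of the same
#'   shape.
#' @return An object of class `percentile_table`.
#' @export
percentile_table <- function(ages, probs, values,
                             ci_lower = NULL, ci_upper = NULL) {
  values <- as.matrix(values)
  stopifnot(length(ages) == nrow(values), length(probs) == ncol(values),
            !is.unsorted(probs, strictly = TRUE))
  dimnames(values) <- NULL
  if (!is.null(ci_lower)) {
    ci_lower <- as.matrix(ci_lower); ci_upper <- as.matrix(ci_upper)
    stopifnot(all(dim(ci_lower) == dim(values)),
              all(dim(ci_upper) == dim(values)))
    dimnames(ci_lower) <- dimnames(ci_upper) <- NULL
  }
  structure(list(ages = as.integer(ages), probs = probs, values = values,
                 ci_lower = ci_lower, ci_upper = ci_upper),
            class = "percentile_table")
}

#' @export
print.percentile_table <- function(x, ...) {
  cat(sprintf("Percentile table: %d ages x %d percentiles%s\n",
              length(x$ages), length(x$probs),
              if (is.null(x$ci_lower)) "" else " (with confidence bands)"))
  cat("  ages:", min(x$ages), "-", max(x$ages), "days\n")
  cat("  percentiles:", paste(100 * x$probs, collapse = " "), "\n")
  invisible(x)
}

#' Number of rows helper for percentile tables
#' @param table A `percentile_table`.
#' @return Integer row count.
#' @keywords internal
#' @noRd
nrow.percentile_table <- function(table) nrow(table$values)
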