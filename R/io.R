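#' Fixed CSV schemas for the pipeline stages
#'
#' Column names (and which of them must be numeric) for the four interchange
#' tables: the long fit table, the pooled table, the beta-range summary, and
#' the bootstrap draw table.
#'
#' @return named list of lists with elements `columns` and `numeric`.
#' @export
table_schemas <- function() {
  list(
    fit = list(
      columns = c("predictor", "outcome", "beta", "se", "t", "p",
                  "ci_lower", "ci_upper", "n_obs", "degenerate", "error"),
      numeric = c("beta", "se", "t", "p", "ci_lower", "ci_upper", "n_obs")
    ),
    pooled = list(
      columns = c("domain", "predictor", "m", "beta_pooled", "se_pooled",
                  "df_rubin", "ci_lower", "ci_upper"),
      numeric = c("m", "beta_pooled", "se_pooled", "df_rubin",
                  "ci_lower", "ci_upper")
    ),
    ranges = list(
      columns = c("domain", "predictor", "beta_pooled", "est_min", "est_max",
                  "ci_outer_lower", "ci_outer_upper"),
      numeric = c("beta_pooled", "est_min", "est_max",
                  "ci_outer_lower", "ci_outer_upper")
    ),
    bootstrap = list(
      columns = c("beta", "predictor", "outcome", "replicate"),
      numeric = c("beta", "replicate")
    )
  )
}

#' Read a CSV table and check it against a schema
#'
#' Reads a headered CSV (missing values as empty fields or `NA`), verifies
#' that all expected columns are present (extra columns are preserved), and
#' that the designated numeric columns parse as numbers — reporting the
#' first offending cell by row and column on failure.
#'
#' @param path CSV file path.
#' @param expected_schema character vector of required column names, or the
#'   name of a built-in schema (`"fit"`, `"pooled"`, `"ranges"`,
#'   `"bootstrap"`).
#' @param numeric_columns columns that must be numeric; defaults to the
#'   built-in schema's list when `expected_schema` is a schema name.
#' @return data frame.
#' @export
read_table <- function(path, expected_schema = NULL, numeric_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(expected_schema) && length(expected_schema) == 1 &&
      expected_schema %in% names(table_schemas())) {
    sch <- table_schemas()[[expected_schema]]
    expected_schema <- sch$columns
    if (is.null(numeric_columns)) numeric_columns <- sch$numeric
  }
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  if (!is.null(expected_schema)) {
    missing_cols <- setdiff(expected_schema, names(d))
    if (length(missing_cols) > 0) {
      stop("missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  for (col in intersect(numeric_columns, names(d))) {
    x <- d[[col]]
    if (is.numeric(x) || is.logical(x)) next
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "', row ", bad[1], ": '",
           x[bad[1]], "'", call. = FALSE)
    }
    d[[col]] <- parsed
  }
  d
}

#' Write a pipeline table with its fixed schema header
#'
#' Subsets/reorders to the schema columns and writes plain CSV (no row
#' names, no quoting of numbers), so output is diff-able and round-trips
#' through [read_table()].
#'
#' @param table data frame holding at least the schema columns.
#' @param path output path.
#' @param schema one of `"fit"`, `"pooled"`, `"ranges"`, `"bootstrap"`, or a
#'   character vector of column names, or `NULL` to write all columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, schema = NULL) {
  stopifnot(is.data.frame(table))
  cols <- schema
  if (is.character(schema) && length(schema) == 1 &&
      schema %in% names(table_schemas())) {
    cols <- table_schemas()[[schema]]$columns
  }
  if (!is.null(cols)) {
    missing_cols <- setdiff(cols, names(table))
    if (length(missing_cols) > 0) {
      stop("table lacks schema column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    table <- table[, cols, drop = FALSE]
  }
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
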