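#' Weighted mean and standard deviation
#'
#' Moments used throughout the package for z-scoring. With weights `w`, the
#' mean is `sum(w * x) / sum(w)` and the variance uses the unbiased-analog
#' denominator for reliability weights, `V1 - V2 / V1` with `V1 = sum(w)` and
#' `V2 = sum(w^2)`. Both reduce to the ordinary sample moments when all
#' weights are equal, and both are invariant to rescaling the weights by a
#' positive constant.
#'
#' @param x numeric vector.
#' @param w optional positive weights, recycled nowhere; same length as `x`.
#' @return named list with elements `mean` and `sd`.
#' @keywords internal
weighted_moments <- function(x, w = NULL) {
  if (is.null(w)) {
    return(list(mean = mean(x), sd = stats::sd(x)))
  }
  stopifnot(length(w) == length(x))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  v1 <- sum(w)
  v2 <- sum(w^2)
  m <- sum(w * x) / v1
  denom <- v1 - v2 / v1
  if (denom <= 0) {
    # single effective observation: variance undefined, report 0
    return(list(mean = m, sd = 0))
  }
  list(mean = m, sd = sqrt(sum(w * (x - m)^2) / denom))
}

#' Z-score columns of a data frame
#'
#' Replaces each named column by `(x - mean) / sd`. When a weight column is
#' supplied, weighted moments are used (see [weighted_moments()]), so the
#' transformed columns have weighted mean 0 and weighted SD 1.
#'
#' @param data a data frame.
#' @param columns character vector of column names to standardize.
#' @param weights optional name of a positive weight column in `data`.
#' @return `data` with the named columns standardized.
#' @examples
#' standardize_columns(data.frame(x = c(1, 2, 3)), "x")
#' @export
standardize_columns <- function(data, columns, weights = NULL) {
  stopifnot(is.data.frame(data), is.character(columns), length(columns) >= 1)
  missing_cols <- setdiff(c(columns, weights), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  w <- if (is.null(weights)) NULL else data[[weights]]
  if (!is.null(w) && (any(!is.finite(w)) || any(w <= 0))) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  for (col in columns) {
    x <- data[[col]]
    if (!is.numeric(x)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    mom <- weighted_moments(x, w)
    if (!is.finite(mom$sd) || mom$sd <= 0) {
      stop("zero-variance variable: '", col, "'", call. = FALSE)
    }
    data[[col]] <- (x - mom$mean) / mom$sd
  }
  data
}
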