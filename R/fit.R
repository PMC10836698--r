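#' Specify a single-predictor model
#'
#' A lightweight description of one regression cell: which column is the
#' outcome, which the predictor, and optionally which columns carry sampling
#' weights and a cluster identifier (a school, say) for a random intercept.
#'
#' @param outcome name of the outcome column.
#' @param predictor name of the predictor column.
#' @param weights optional name of a positive sampling-weight column.
#' @param cluster optional name of a grouping column; when present the model
#'   gains a per-cluster random intercept (REML fit via \pkg{lme4}).
#' @param conf_level confidence level for the Wald interval, in (0, 1).
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("y", "x")
#' @export
model_spec <- function(outcome, predictor, weights = NULL, cluster = NULL,
                       conf_level = 0.95) {
  stopifnot(is.character(outcome), length(outcome) == 1,
            is.character(predictor), length(predictor) == 1)
  if (identical(outcome, predictor)) {
    stop("outcome and predictor must name different columns", call. = FALSE)
  }
  if (!is.numeric(conf_level) || length(conf_level) != 1 ||
      conf_level <= 0 || conf_level >= 1) {
    stop("conf_level must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(outcome = outcome, predictor = predictor, weights = weights,
         cluster = cluster, conf_level = conf_level),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$outcome, " ~ ", x$predictor, sep = "")
  if (!is.null(x$weights)) cat(", weights =", x$weights)
  if (!is.null(x$cluster)) cat(", cluster =", x$cluster)
  cat(" [", format(x$conf_level), " CI]\n", sep = "")
  invisible(x)
}

# Residual SD below this (on z-scored data) marks a perfect, zero-residual fit.
DEGENERATE_TOL <- 1e-7

fit_result_row <- function(spec, beta = NA_real_, se = NA_real_,
                           t_stat = NA_real_, p_value = NA_real_,
                           ci_lower = NA_real_, ci_upper = NA_real_,
                           n_obs = NA_integer_, degenerate = FALSE,
                           error = NA_character_) {
  data.frame(
    predictor = spec$predictor, outcome = spec$outcome,
    beta = beta, se = se, t = t_stat, p = p_value,
    ci_lower = ci_lower, ci_upper = ci_upper,
    n_obs = as.integer(n_obs), degenerate = degenerate, error = error,
    stringsAsFactors = FALSE
  )
}

#' Fit one standardized single-predictor model
#'
#' The outcome and predictor are z-scored first (weighted moments when a
#' weight column is given), then the model is fitted:
#' ordinary least squares without weights or cluster, weighted least squares
#' with weights only, and a random-intercept mixed model (REML, \pkg{lme4})
#' when a cluster column is named. The reported slope is therefore a
#' standardized coefficient (a beta weight); for simple OLS it equals the
#' Pearson correlation. Confidence limits are Wald, `beta +/- t * se`, with
#' `n - 2` degrees of freedom (also used, as a pragmatic approximation, for
#' the clustered fits).
#'
#' Rows with a missing value in any involved column are dropped (listwise
#' deletion per model). A perfect fit with zero residual variance is reported
#' with `se = 0`, `p = 0`, a point confidence interval, and
#' `degenerate = TRUE` rather than an error. A cluster column with a single
#' level falls back to the non-clustered fit with a warning.
#'
#' @param data a data frame containing all columns named in `spec`.
#' @param spec a [model_spec()].
#' @return one-row data frame with columns `predictor`, `outcome`, `beta`,
#'   `se`, `t`, `p`, `ci_lower`, `ci_upper`, `n_obs`, `degenerate`, `error`.
#' @examples
#' fit_single_model(data.frame(x = 1:5, y = c(2, 1, 4, 3, 5)),
#'                  model_spec("y", "x"))
#' @export
fit_single_model <- function(data, spec) {
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"))
  used <- c(spec$outcome, spec$predictor, spec$weights, spec$cluster)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("insufficient data: fewer than 3 complete rows", call. = FALSE)

  d <- standardize_columns(d, c(spec$outcome, spec$predictor), spec$weights)
  y <- d[[spec$outcome]]
  x <- d[[spec$predictor]]
  w <- if (is.null(spec$weights)) NULL else d[[spec$weights]]

  cluster <- NULL
  if (!is.null(spec$cluster)) {
    cluster <- factor(d[[spec$cluster]])
    if (nlevels(cluster) < 2) {
      warning("cluster column '", spec$cluster,
              "' has a single level; fitting without a random intercept",
              call. = FALSE)
      cluster <- NULL
    }
  }

  if (is.null(cluster)) {
    fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
    beta <- unname(stats::coef(fit)[["x"]])
    # summary.lm warns on zero-residual fits; those are handled below
    sfit <- withCallingHandlers(
      summary(fit),
      warning = function(w_) {
        if (grepl("essentially perfect fit", conditionMessage(w_))) {
          invokeRestart("muffleWarning")
        }
      })
    sigma <- sfit$sigma
    se <- unname(sfit$coefficients["x", "Std. Error"])
  } else {
    fd <- data.frame(y = y, x = x, cl = cluster)
    fit <- if (is.null(w)) {
      lme4::lmer(y ~ x + (1 | cl), data = fd, REML = TRUE)
    } else {
      fd$w <- w
      lme4::lmer(y ~ x + (1 | cl), data = fd, weights = w, REML = TRUE)
    }
    co <- summary(fit)$coefficients
    beta <- unname(co["x", "Estimate"])
    se <- unname(co["x", "Std. Error"])
    sigma <- stats::sigma(fit)
  }

  degenerate <- is.finite(sigma) && sigma < DEGENERATE_TOL
  df <- n - 2
  alpha <- 1 - spec$conf_level
  if (degenerate) {
    se <- 0
    t_stat <- sign(beta) * Inf
    p <- 0
    ci <- c(beta, beta)
  } else {
    t_stat <- beta / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    ci <- beta + c(-1, 1) * stats::qt(1 - alpha / 2, df) * se
  }
  fit_result_row(spec, beta = beta, se = se, t_stat = t_stat, p_value = p,
                 ci_lower = ci[1], ci_upper = ci[2], n_obs = n,
                 degenerate = degenerate)
}

#' Fit a grid of single-predictor models
#'
#' One fit per (outcome, predictor) pair: the outer loop runs over
#' predictors, the inner over outcomes, so the output is blocked by predictor
#' as in a long model-parameter table. A cell whose fit fails is recorded
#' with its error message in the `error` column instead of aborting the grid.
#'
#' @param data a data frame.
#' @param outcomes,predictors character vectors of column names; must be
#'   disjoint and nonempty.
#' @inheritParams model_spec
#' @param conf_level confidence level shared by all cells.
#' @return data frame of stacked [fit_single_model()] rows,
#'   `length(outcomes) * length(predictors)` of them.
#' @export
fit_model_grid <- function(data, outcomes, predictors, weights = NULL,
                           cluster = NULL, conf_level = 0.95) {
  stopifnot(is.character(outcomes), is.character(predictors))
  if (length(outcomes) == 0 || length(predictors) == 0) {
    stop("outcomes and predictors must be nonempty", call. = FALSE)
  }
  overlap <- intersect(outcomes, predictors)
  if (length(overlap) > 0) {
    stop("outcomes and predictors overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  rows <- vector("list", length(outcomes) * length(predictors))
  i <- 0
  for (p in predictors) {
    for (o in outcomes) {
      i <- i + 1
      spec <- model_spec(o, p, weights = weights, cluster = cluster,
                         conf_level = conf_level)
      rows[[i]] <- tryCatch(
        fit_single_model(data, spec),
        error = function(e) fit_result_row(spec, error = conditionMessage(e))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
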