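#' Pool plausible-value fits with Rubin's rules
#'
#' Large-scale assessments report each proficiency as m plausible values;
#' the recommended workflow fits the model once per plausible value and then
#' combines the m results. Given m estimates \eqn{\beta_i} with standard
#' errors \eqn{se_i}, the classic combining rules give
#' \deqn{\bar{Q} = \frac{1}{m}\sum \beta_i, \quad
#'       W = \frac{1}{m}\sum se_i^2, \quad
#'       B = \frac{1}{m-1}\sum (\beta_i - \bar{Q})^2,}
#' total variance \eqn{T = W + (1 + 1/m) B}, pooled standard error
#' \eqn{\sqrt{T}}, and degrees of freedom
#' \eqn{\nu = (m - 1)\,[1 + W / ((1 + 1/m) B)]^2}. The confidence interval is
#' \eqn{\bar{Q} \pm t_{\nu}\sqrt{T}}. When all m estimates agree exactly
#' (\eqn{B = 0}), \eqn{\nu} is infinite and the normal quantile is used.
#'
#' @param fits data frame of fit rows (schema of [fit_single_model()]), all
#'   sharing one predictor; at least 2 rows, none errored.
#' @param domain label for the pooled cell (defaults to the common domain of
#'   the outcome names under [map_pv_to_domain()]).
#' @param conf_level confidence level of the pooled interval.
#' @return one-row data frame with columns `domain`, `predictor`, `m`,
#'   `beta_pooled`, `w_within`, `b_between`, `t_total`, `se_pooled`,
#'   `df_rubin`, `ci_lower`, `ci_upper`.
#' @examples
#' fits <- fit_model_grid(
#'   data.frame(x = rnorm(50), pv1 = rnorm(50), pv2 = rnorm(50)),
#'   outcomes = c("pv1", "pv2"), predictors = "x")
#' pool_estimates(fits, domain = "pv")
#' @export
pool_estimates <- function(fits, domain = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(fits))
  m <- nrow(fits)
  if (m < 2) stop("need at least 2 fits to pool", call. = FALSE)
  if (length(unique(fits$predictor)) != 1) {
    stop("cannot pool fits with mixed predictors: ",
         paste(unique(fits$predictor), collapse = ", "), call. = FALSE)
  }
  errored <- !is.na(fits$error)
  if (any(errored)) {
    stop("cannot pool errored fits in cell ",
         paste(unique(fits$outcome[errored]), collapse = ", "), " x ",
         fits$predictor[1], call. = FALSE)
  }
  if (is.null(domain)) {
    domain <- unique(map_pv_to_domain(fits$outcome))
    if (length(domain) != 1) {
      stop("fits map to several domains: ", paste(domain, collapse = ", "),
           call. = FALSE)
    }
  }
  betas <- fits$beta
  q_bar <- mean(betas)
  w_within <- mean(fits$se^2)
  b_between <- stats::var(betas)
  t_total <- w_within + (1 + 1 / m) * b_between
  se_pooled <- sqrt(t_total)
  df_rubin <- if (b_between == 0) {
    Inf
  } else {
    (m - 1) * (1 + w_within / ((1 + 1 / m) * b_between))^2
  }
  q <- stats::qt(1 - (1 - conf_level) / 2, df = df_rubin)
  data.frame(
    domain = domain, predictor = fits$predictor[1], m = as.integer(m),
    beta_pooled = q_bar, w_within = w_within, b_between = b_between,
    t_total = t_total, se_pooled = se_pooled, df_rubin = df_rubin,
    ci_lower = q_bar - q * se_pooled, ci_upper = q_bar + q * se_pooled,
    stringsAsFactors = FALSE
  )
}

#' Pool a whole fit table by domain and predictor
#'
#' Groups a long fit table into (domain, predictor) cells — the domain of an
#' outcome given by `domain_of` — and applies [pool_estimates()] to each.
#' Cells appear in first-appearance order of the input rows.
#'
#' @param fit_table data frame of fit rows ([fit_model_grid()] schema).
#' @param domain_of either a function mapping outcome names to domain labels
#'   or a named character vector; defaults to [map_pv_to_domain()], which
#'   strips a trailing two-digit plausible-value index.
#' @param conf_level confidence level for all pooled intervals.
#' @return data frame of [pool_estimates()] rows, one per cell.
#' @export
pool_table <- function(fit_table, domain_of = map_pv_to_domain,
                       conf_level = 0.95) {
  stopifnot(is.data.frame(fit_table), nrow(fit_table) > 0)
  domains <- resolve_domains(fit_table$outcome, domain_of)
  key <- paste(domains, fit_table$predictor, sep = "\r")
  cells <- unique(key)
  rows <- lapply(cells, function(k) {
    idx <- key == k
    pool_estimates(fit_table[idx, , drop = FALSE],
                   domain = domains[idx][1], conf_level = conf_level)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Apply a domain mapping (function or named vector) to outcome names,
# erroring on outcomes the mapping does not cover.
resolve_domains <- function(outcomes, domain_of) {
  if (is.function(domain_of)) {
    d <- vapply(outcomes, function(o) domain_of(o)[[1]], character(1))
  } else {
    d <- unname(domain_of[outcomes])
  }
  bad <- unique(outcomes[is.na(d) | !nzchar(d)])
  if (length(bad) > 0) {
    stop("no domain mapping for outcome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(d)
}
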