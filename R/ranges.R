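#' Map a plausible-value column name to its domain
#'
#' Assessment score columns carry a trailing two-digit plausible-value index
#' ("BSMMAT01" ... "BSMMAT05"); the domain is the name with that index
#' stripped ("BSMMAT"). Names without a trailing index (macro indicators such
#' as "Gini") are returned unchanged. An explicit mapping table overrides the
#' rule.
#'
#' @param outcome_name character vector of outcome names.
#' @param mapping optional named character vector; names are outcome names,
#'   values their domains. Names not in the table fall back to the rule.
#' @return character vector of domain labels.
#' @examples
#' map_pv_to_domain(c("BSMMAT01", "BSMMAT02", "Gini"))
#' @export
map_pv_to_domain <- function(outcome_name, mapping = NULL) {
  stopifnot(is.character(outcome_name), all(nzchar(outcome_name)))
  # trailing index 01-99 (not 00), preceded by at least one character
  out <- sub("^(.+?)(0[1-9]|[1-9][0-9])$", "\\1", outcome_name)
  if (!is.null(mapping)) {
    hit <- outcome_name %in% names(mapping)
    out[hit] <- unname(mapping[outcome_name[hit]])
  }
  out
}

#' Display names for the demonstration assessment domains
#'
#' Human-readable labels for the ten mathematics and science domain codes
#' used by the hierarchical demonstration data, e.g. `BSMALG` -> "Algebra".
#'
#' @return named character vector (names = domain codes, values = labels).
#' @export
timss_domain_labels <- function() {
  c(BSMALG = "Algebra", BSMDAT = "Data and Probability", BSMGEO = "Geometry",
    BSMMAT = "Mathematics", BSMNUM = "Number",
    BSSBIO = "Biology", BSSCHE = "Chemistry", BSSEAR = "Earth Science",
    BSSPHY = "Physics", BSSSCI = "Science")
}

#' Collapse plausible-value fits to beta-range rows
#'
#' For each (domain, predictor) cell, records the smallest and largest of the
#' m point estimates, the outermost confidence limits (minimum of the lower
#' limits, maximum of the upper limits), and the Rubin-pooled estimate joined
#' from `pooled_table`. This is the data behind the beta-range forest plot:
#' each output row becomes one bar-plus-whiskers band.
#'
#' @param fit_table data frame of fit rows ([fit_model_grid()] schema).
#' @param pooled_table data frame from [pool_table()]; must cover every
#'   (domain, predictor) cell present in `fit_table`.
#' @param domain_of mapping from outcome name to domain label, as in
#'   [pool_table()]; use the same mapping for both calls.
#' @return data frame with columns `domain`, `predictor`, `beta_pooled`,
#'   `est_min`, `est_max`, `ci_outer_lower`, `ci_outer_upper`; one row per
#'   cell, cells in first-appearance order.
#' @export
summarize_ranges <- function(fit_table, pooled_table,
                             domain_of = map_pv_to_domain) {
  stopifnot(is.data.frame(fit_table), is.data.frame(pooled_table))
  errored <- !is.na(fit_table$error)
  if (any(errored)) {
    stop("fit table contains errored rows; resolve or drop them first",
         call. = FALSE)
  }
  domains <- resolve_domains(fit_table$outcome, domain_of)
  key <- paste(domains, fit_table$predictor, sep = "\r")
  pooled_key <- paste(pooled_table$domain, pooled_table$predictor, sep = "\r")
  cells <- unique(key)
  missing_cells <- setdiff(cells, pooled_key)
  if (length(missing_cells) > 0) {
    stop("pooled table is missing cell(s): ",
         paste(gsub("\r", " x ", missing_cells), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(cells, function(k) {
    f <- fit_table[key == k, , drop = FALSE]
    p <- pooled_table[match(k, pooled_key), , drop = FALSE]
    data.frame(
      domain = p$domain, predictor = p$predictor,
      beta_pooled = p$beta_pooled,
      est_min = min(f$beta), est_max = max(f$beta),
      ci_outer_lower = min(f$ci_lower), ci_outer_upper = max(f$ci_upper),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
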