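#' Derive a per-cell bootstrap seed
#'
#' Deterministic hash of the master seed and the cell labels, so that each
#' (predictor, outcome) cell of a bootstrap grid draws an independent,
#' reproducible stream that does not depend on the cell's position in the
#' grid. The hash is a 31-bit polynomial rolling hash (base 31, modulus
#' 2^31 - 1) over the UTF-8 bytes of `"<predictor>\r<outcome>"`, offset by
#' the master seed.
#'
#' @param seed master integer seed.
#' @param predictor,outcome cell labels.
#' @return integer in \[0, 2^31 - 2\], suitable for `set.seed()`.
#' @export
cell_seed <- function(seed, predictor, outcome) {
  mod <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% mod
  for (b in utf8ToInt(paste(predictor, outcome, sep = "\r"))) {
    h <- (h * 31 + b) %% mod
  }
  as.integer(h)
}

#' Case-bootstrap distribution of a standardized slope
#'
#' Resamples rows of `data` with replacement (`n_obs` rows per replicate),
#' z-scores outcome and predictor within the resample, refits, and records
#' the standardized slope. Resamples in which the outcome or predictor has
#' zero variance are discarded and redrawn so every replicate yields a
#' coefficient; after `100 * n_reps` consecutive degenerate resamples the
#' cell errors out. Bootstrap fits use the plain or weighted engine — the
#' random-intercept term, if any, is dropped (case resampling of rows is the
#' resampling unit).
#'
#' @param data a data frame.
#' @param spec a [model_spec()]; its `cluster` field is ignored here.
#' @param n_reps number of bootstrap replicates (B).
#' @param seed integer seed; draws are fully reproducible from it.
#' @return data frame with columns `beta`, `predictor`, `outcome`,
#'   `replicate` (1..B).
#' @examples
#' bootstrap_betas(data.frame(x = rnorm(30), y = rnorm(30)),
#'                 model_spec("y", "x"), n_reps = 20, seed = 1)
#' @export
bootstrap_betas <- function(data, spec, n_reps, seed) {
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"),
            n_reps >= 1, is.numeric(seed))
  used <- c(spec$outcome, spec$predictor, spec$weights)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("insufficient data: fewer than 3 complete rows", call. = FALSE)

  y <- d[[spec$outcome]]
  x <- d[[spec$predictor]]
  w <- if (is.null(spec$weights)) NULL else d[[spec$weights]]

  betas <- numeric(n_reps)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  max_failures <- 100 * n_reps
  failures <- 0
  rep_i <- 1
  while (rep_i <= n_reps) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]; xb <- x[idx]
    wb <- if (is.null(w)) NULL else w[idx]
    my <- weighted_moments(yb, wb)
    mx <- weighted_moments(xb, wb)
    if (my$sd <= 0 || mx$sd <= 0) {
      failures <- failures + 1
      if (failures >= max_failures) {
        stop("bootstrap failed: degenerate data in cell ", spec$outcome,
             " x ", spec$predictor, call. = FALSE)
      }
      next
    }
    failures <- 0
    zy <- (yb - my$mean) / my$sd
    zx <- (xb - mx$mean) / mx$sd
    # standardized slope = weighted cross-moment of the z-scores
    betas[rep_i] <- if (is.null(wb)) {
      sum(zy * zx) / sum(zx * zx)
    } else {
      sum(wb * zy * zx) / sum(wb * zx * zx)
    }
    rep_i <- rep_i + 1
  }
  data.frame(beta = betas, predictor = spec$predictor, outcome = spec$outcome,
             replicate = seq_len(n_reps), stringsAsFactors = FALSE)
}

#' Bootstrap a whole outcome-by-predictor grid
#'
#' Runs [bootstrap_betas()] for every (outcome, predictor) cell, with the
#' per-cell seed derived by [cell_seed()] from the master seed and the cell
#' labels — so permuting the outcome or predictor lists leaves every cell's
#' draws unchanged. Cells that fail are recorded as attributes rather than
#' aborting the grid.
#'
#' @inheritParams fit_model_grid
#' @param n_reps bootstrap replicates per cell.
#' @param seed master seed.
#' @return data frame with columns `beta`, `predictor`, `outcome`,
#'   `replicate`; `length(outcomes) * length(predictors) * n_reps` rows
#'   (minus any failed cells, reported in attribute `"errors"`).
#' @export
bootstrap_grid <- function(data, outcomes, predictors, n_reps, seed,
                           weights = NULL) {
  stopifnot(is.character(outcomes), is.character(predictors))
  if (length(outcomes) == 0 || length(predictors) == 0) {
    stop("outcomes and predictors must be nonempty", call. = FALSE)
  }
  overlap <- intersect(outcomes, predictors)
  if (length(overlap) > 0) {
    stop("outcomes and predictors overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  errors <- character(0)
  for (p in predictors) {
    for (o in outcomes) {
      spec <- model_spec(o, p, weights = weights)
      res <- tryCatch(
        bootstrap_betas(data, spec, n_reps, cell_seed(seed, p, o)),
        error = function(e) conditionMessage(e)
      )
      if (is.character(res)) {
        errors[paste(p, o, sep = " x ")] <- res
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(errors) > 0) attr(out, "errors") <- errors
  out
}
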