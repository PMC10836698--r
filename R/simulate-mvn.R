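# Run expr with a locally set RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Repair a correlation matrix to positive definiteness
#'
#' Floors the eigenvalues at `eps`, reassembles, and rescales to a unit
#' diagonal. A valid correlation matrix passes through unchanged.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps eigenvalue floor.
#' @return positive-definite correlation matrix.
#' @export
near_pd_corr <- function(R, eps = 1e-8) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-12) stop("matrix is not symmetric", call. = FALSE)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Configure a truncated multivariate-normal simulation
#'
#' Marginal means and SDs, per-variable truncation bounds, a correlation
#' matrix (or block parameters, see [decathlon_config()]), and a seed.
#'
#' @param n_units number of rows to simulate.
#' @param variable_names character vector, one name per variable.
#' @param means,sds numeric vectors aligned with `variable_names`; `sds > 0`.
#' @param bounds two-column matrix of `[lower, upper]` truncation intervals,
#'   one row per variable; must contain the corresponding mean. Default:
#'   `mean +/- 4 SD`.
#' @param correlation correlation matrix (symmetric, unit diagonal); repaired
#'   to the nearest positive-definite correlation if needed.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_units, variable_names, means, sds,
                              bounds = NULL, correlation = NULL, seed = 1) {
  k <- length(variable_names)
  stopifnot(n_units >= 1, length(means) == k, length(sds) == k, all(sds > 0))
  if (is.null(bounds)) {
    bounds <- cbind(means - 4 * sds, means + 4 * sds)
  }
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  stopifnot(nrow(bounds) == k)
  if (any(bounds[, 1] > means | bounds[, 2] < means)) {
    stop("each truncation interval must contain its mean", call. = FALSE)
  }
  if (is.null(correlation)) correlation <- diag(k)
  stopifnot(is.matrix(correlation), nrow(correlation) == k)
  structure(
    list(n_units = as.integer(n_units), variable_names = variable_names,
         means = means, sds = sds, bounds = bounds,
         correlation = near_pd_corr(correlation), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Sample from a truncated multivariate normal
#'
#' Draws rows from MVN(means, D R D) with D = diag(sds) and rejects any row
#' with a value outside its truncation interval, redrawing violators for up
#' to 1,000 rounds; stragglers are then clipped to the bounds with a
#' warning. With bounds a few SDs out, rejection is rare and the sample
#' keeps the exact MVN shape.
#'
#' @param config a [simulation_config()].
#' @return data frame of `n_units` rows, columns named by `variable_names`;
#'   reproducible from `config$seed`.
#' @export
sample_truncated_mvn <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_units
  k <- length(config$variable_names)
  R <- near_pd_corr(config$correlation)
  L <- chol(R)
  lo <- matrix(config$bounds[, 1], n, k, byrow = TRUE)
  hi <- matrix(config$bounds[, 2], n, k, byrow = TRUE)
  draw <- function(m) {
    z <- matrix(stats::rnorm(m * k), m, k) %*% L
    sweep(sweep(z, 2, config$sds, `*`), 2, config$means, `+`)
  }
  with_seed(config$seed, {
    x <- draw(n)
    bad <- rowSums(x < lo[seq_len(n), , drop = FALSE] |
                   x > hi[seq_len(n), , drop = FALSE]) > 0
    rounds <- 0
    while (any(bad) && rounds < 1000) {
      nb <- sum(bad)
      x[bad, ] <- draw(nb)
      bad[bad] <- rowSums(x[bad, , drop = FALSE] < lo[seq_len(nb), , drop = FALSE] |
                          x[bad, , drop = FALSE] > hi[seq_len(nb), , drop = FALSE]) > 0
      rounds <- rounds + 1
    }
    if (any(bad)) {
      warning(sum(bad), " row(s) still out of bounds after 1000 rounds; ",
              "clipping to the truncation interval", call. = FALSE)
      xm <- pmin(pmax(x, lo), hi)
      x <- xm
    }
    out <- as.data.frame(x)
    names(out) <- config$variable_names
    out
  })
}

#' Default configuration for the decathlon demonstration data
#'
#' Seventeen correlated variables per simulated athlete: ten track-and-field
#' event results and seven hematological indices, with the marginal means
#' and SDs of the demonstration dataset. The correlation matrix is assembled
#' from three block parameters — within-event, within-marker, and
#' cross-block — with a sign flip for the four timed events (100 m, 400 m,
#' 110 m hurdles, 1500 m), where a *lower* result means *better*
#' performance: a favourable blood profile raises jump and throw results but
#' lowers race times. The sign structure is applied as a similarity
#' transform of the all-positive block matrix, which preserves positive
#' definiteness.
#'
#' @param n_units number of athletes (default 10,000).
#' @param rho_within_events,rho_within_markers,rho_cross block correlation
#'   parameters in (-1, 1).
#' @param seed integer seed.
#' @return a [simulation_config()] with attributes `event_names`,
#'   `marker_names`, `timed_events`.
#' @export
decathlon_config <- function(n_units = 10000, rho_within_events = 0.6,
                             rho_within_markers = 0.5, rho_cross = 0.4,
                             seed = 1) {
  events <- c("100m", "long_jump", "shot_put", "high_jump", "400m",
              "110m_hurdles", "discus", "pole_vault", "javelin", "1500m")
  markers <- c("ferritin", "haptoglobin", "hematocrit", "hemoglobin",
               "iron", "rbc", "transferrin")
  timed <- c("100m", "400m", "110m_hurdles", "1500m")
  means <- c(10.78, 7.43, 13.66, 1.95, 48.02, 14.79, 44.20, 4.90, 57.17, 4.60,
             68.29, 65.70, 46.78, 15.92, 122.37, 5.24, 320.77)
  sds <- c(0.29, 0.44, 0.46, 0.03, 1.64, 0.71, 2.79, 0.17, 3.52, 0.23,
           8.90, 9.30, 2.68, 1.08, 10.46, 0.53, 41.41)
  stopifnot(abs(rho_within_events) < 1, abs(rho_within_markers) < 1,
            abs(rho_cross) < 1)
  ne <- length(events); nm <- length(markers)
  R <- matrix(0, ne + nm, ne + nm)
  R[seq_len(ne), seq_len(ne)] <- rho_within_events
  R[ne + seq_len(nm), ne + seq_len(nm)] <- rho_within_markers
  R[seq_len(ne), ne + seq_len(nm)] <- rho_cross
  R[ne + seq_len(nm), seq_len(ne)] <- rho_cross
  diag(R) <- 1
  sgn <- c(ifelse(events %in% timed, -1, 1), rep(1, nm))
  R <- R * tcrossprod(sgn)
  cfg <- simulation_config(n_units = n_units,
                           variable_names = c(events, markers),
                           means = means, sds = sds,
                           correlation = near_pd_corr(R), seed = seed)
  attr(cfg, "event_names") <- events
  attr(cfg, "marker_names") <- markers
  attr(cfg, "timed_events") <- timed
  cfg
}

#' Simulate the decathlon demonstration dataset
#'
#' Draws `n_units` athletes from the truncated multivariate normal described
#' by [decathlon_config()]: 10 event results plus 7 hematological indices,
#' correlated within and across blocks, truncated at mean +/- 4 SD.
#'
#' @param n_units number of athletes.
#' @param seed integer seed.
#' @param config optional full [decathlon_config()]; overrides the other
#'   arguments when given.
#' @return data frame of `n_units` rows and 17 columns; the event and marker
#'   column groups are recorded in attributes `event_names` and
#'   `marker_names`.
#' @examples
#' d <- simulate_decathlon(n_units = 500, seed = 42)
#' colMeans(d[, c("100m", "hemoglobin")])
#' @export
simulate_decathlon <- function(n_units = 10000, seed = 1, config = NULL) {
  if (is.null(config)) config <- decathlon_config(n_units = n_units, seed = seed)
  stopifnot(inherits(config, "simulation_config"))
  out <- sample_truncated_mvn(config)
  attr(out, "event_names") <- attr(config, "event_names")
  attr(out, "marker_names") <- attr(config, "marker_names")
  out
}
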