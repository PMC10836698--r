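#' Configure the hierarchical assessment simulator
#'
#' Describes a three-level world — students in schools in countries — with
#' country-level macroeconomic predictors, a latent student achievement
#' score, and ten achievement domains each reported as five plausible
#' values. The latent score is
#' \deqn{A = \mu_A + \sigma_A (\sum_k \beta_k z_k + u_s + \epsilon_i)}
#' where \eqn{z_k} is the k-th predictor z-scored across countries,
#' \eqn{\beta_k} its true standardized slope, \eqn{u_s} a school random
#' intercept and \eqn{\epsilon_i} a student residual with
#' \eqn{Var(u_s)/Var(u_s + \epsilon) = } `icc_school` and total latent
#' variance 1 before scaling. Each plausible value adds independent
#' measurement noise on the score scale.
#'
#' Defaults mirror the demonstration dataset: 38 countries, about 85,000
#' students, achievement scale mean 490 / SD 110, five macro indicators
#' (GDP per capita, gender parity index, Gini index, government education
#' expenditure in secondary and in total) with their observed means/SDs and
#' plausible pooled standardized slopes.
#'
#' @param n_countries,schools_per_country,students_per_school hierarchy
#'   sizes, all >= 1.
#' @param predictors data frame with columns `name`, `mean`, `sd`
#'   (country-level marginals).
#' @param true_slopes named numeric vector of standardized effects on latent
#'   achievement, one per predictor; `sum(true_slopes^2)` must be < 1.
#' @param icc_school share of non-predictor achievement variance at the
#'   school level, in \[0, 1).
#' @param pv_noise_sd SD of per-plausible-value measurement noise, on the
#'   achievement score scale (points).
#' @param achievement_mean,achievement_sd achievement score scale.
#' @param weight_dispersion log-SD of the lognormal student sampling
#'   weights (mean 1).
#' @param seed integer seed.
#' @return list of class `hierarchy_config`.
#' @export
hierarchy_config <- function(n_countries = 38, schools_per_country = 150,
                             students_per_school = 15,
                             predictors = NULL, true_slopes = NULL,
                             icc_school = 0.3, pv_noise_sd = 15,
                             achievement_mean = 490, achievement_sd = 110,
                             weight_dispersion = 0.5, seed = 1) {
  if (is.null(predictors)) {
    predictors <- data.frame(
      name = c("GDP", "GPI", "Gini", "GeS", "GeT"),
      mean = c(28910.56, 1.00, 36.82, 19.80, 4.58),
      sd = c(21805.43, 0.03, 10.70, 7.55, 1.42),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(true_slopes)) {
    true_slopes <- c(GDP = 0.21, GPI = 0.01, Gini = -0.12,
                     GeS = 0.17, GeT = -0.12)
    true_slopes <- true_slopes[intersect(names(true_slopes), predictors$name)]
  }
  stopifnot(n_countries >= 1, schools_per_country >= 1,
            students_per_school >= 1,
            icc_school >= 0, icc_school < 1, pv_noise_sd >= 0,
            achievement_sd > 0, weight_dispersion >= 0)
  if (length(true_slopes) != nrow(predictors) ||
      !setequal(names(true_slopes), predictors$name)) {
    stop("true_slopes must name exactly the configured predictors",
         call. = FALSE)
  }
  if (sum(true_slopes^2) >= 1) {
    stop("sum of squared true slopes must be < 1", call. = FALSE)
  }
  structure(
    list(n_countries = as.integer(n_countries),
         schools_per_country = as.integer(schools_per_country),
         students_per_school = as.integer(students_per_school),
         predictors = predictors,
         true_slopes = true_slopes[predictors$name],
         icc_school = icc_school, pv_noise_sd = pv_noise_sd,
         achievement_mean = achievement_mean,
         achievement_sd = achievement_sd,
         weight_dispersion = weight_dispersion, seed = as.integer(seed)),
    class = "hierarchy_config"
  )
}

#' The ten demonstration achievement domain codes
#'
#' Five mathematics domains (`BSM...`) and five science domains (`BSS...`);
#' each gets plausible-value columns suffixed `01` to `05`.
#'
#' @return character vector of length 10.
#' @export
timss_domains <- function() names(timss_domain_labels())

#' Simulate a hierarchical assessment dataset with plausible values
#'
#' Generates students nested in schools nested in countries per the
#' generative model in [hierarchy_config()]: country-level predictor values,
#' latent achievement with a school random intercept, 10 domains x 5
#' plausible-value columns (`BSMALG01` ... `BSSSCI05`), lognormal sampling
#' weights with mean 1, and school/country identifier columns.
#'
#' @param config a [hierarchy_config()].
#' @return data frame with one row per student and columns `student`,
#'   `country`, `school`, `weight`, the predictor columns (constant within
#'   country), and 50 plausible-value columns. The latent achievement score
#'   is exposed as attribute `"latent"` for diagnostics.
#' @examples
#' d <- simulate_timss_like(hierarchy_config(
#'   n_countries = 4, schools_per_country = 3, students_per_school = 5))
#' dim(d)
#' @export
simulate_timss_like <- function(config = hierarchy_config()) {
  stopifnot(inherits(config, "hierarchy_config"))
  C <- config$n_countries
  S <- config$schools_per_country
  m <- config$students_per_school
  n <- C * S * m
  slopes <- config$true_slopes
  with_seed(config$seed, {
    country_idx <- rep(seq_len(C), each = S * m)
    school_idx <- rep(seq_len(C * S), each = m)

    # country-level predictors, z-scored across the realized countries so the
    # configured slopes are exact standardized effects in this sample
    pred_raw <- sapply(seq_len(nrow(config$predictors)), function(k) {
      stats::rnorm(C, config$predictors$mean[k], config$predictors$sd[k])
    })
    pred_raw <- matrix(pred_raw, nrow = C)
    colnames(pred_raw) <- config$predictors$name
    pred_z <- if (C > 1) scale(pred_raw) else pred_raw * 0

    systematic_c <- as.numeric(pred_z %*% slopes)
    resid_var <- 1 - sum(slopes^2)
    u <- stats::rnorm(C * S, 0, sqrt(config$icc_school * resid_var))
    eps <- stats::rnorm(n, 0, sqrt((1 - config$icc_school) * resid_var))
    latent <- config$achievement_mean + config$achievement_sd *
      (systematic_c[country_idx] + u[school_idx] + eps)

    out <- data.frame(
      student = seq_len(n),
      country = sprintf("C%02d", country_idx),
      school = sprintf("C%02dS%04d", country_idx,
                       school_idx - (country_idx - 1) * S),
      weight = stats::rlnorm(n, -config$weight_dispersion^2 / 2,
                             config$weight_dispersion),
      stringsAsFactors = FALSE
    )
    for (nm in config$predictors$name) {
      out[[nm]] <- pred_raw[country_idx, nm]
    }
    for (dom in timss_domains()) {
      for (pv in 1:5) {
        out[[sprintf("%s%02d", dom, pv)]] <-
          latent + stats::rnorm(n, 0, config$pv_noise_sd)
      }
    }
    attr(out, "latent") <- latent
    out
  })
}
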