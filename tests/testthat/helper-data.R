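# Small in-code fixtures shared across test files.

# Bivariate normal sample with population correlation rho.
make_xy <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  data.frame(x = x, y = y)
}

# Hand-built fit-table row, for exercising pooling/summarizing in isolation.
fake_fit <- function(beta, se, predictor = "p", outcome = "o",
                     ci = NULL, n_obs = 100) {
  if (is.null(ci)) ci <- beta + c(-1, 1) * 1.96 * se
  data.frame(predictor = predictor, outcome = outcome, beta = beta, se = se,
             t = ifelse(se > 0, beta / se, Inf),
             p = 0, ci_lower = ci[1], ci_upper = ci[2],
             n_obs = as.integer(n_obs), degenerate = FALSE,
             error = NA_character_, stringsAsFactors = FALSE)
}

fake_fit_table <- function(betas, ses, predictor = "p", outcomes = NULL,
                           cis = NULL) {
  if (is.null(outcomes)) outcomes <- sprintf("PV%02d", seq_along(betas))
  do.call(rbind, lapply(seq_along(betas), function(i) {
    fake_fit(betas[i], ses[i], predictor = predictor, outcome = outcomes[i],
             ci = if (is.null(cis)) NULL else cis[[i]])
  }))
}

# A reduced hierarchical config with a single predictor of known slope.
one_predictor_config <- function(slope, seed, n_countries = 15,
                                 schools_per_country = 12,
                                 students_per_school = 10) {
  hierarchy_config(
    n_countries = n_countries, schools_per_country = schools_per_country,
    students_per_school = students_per_school,
    predictors = data.frame(name = "GDP", mean = 28910.56, sd = 21805.43),
    true_slopes = c(GDP = slope), seed = seed)
}
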