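test_that("model_spec validates its fields", {
  s <- model_spec("y", "x", conf_level = 0.9)
  expect_s3_class(s, "model_spec")
  expect_output(print(s), "y ~ x")
  expect_error(model_spec("y", "y"), "different columns")
  expect_error(model_spec("y", "x", conf_level = 1), "strictly between")
  expect_error(model_spec("y", "x", conf_level = 0), "strictly between")
})

test_that("simple OLS beta equals the Pearson correlation (hand oracle)", {
  # deviations oracle: r = 8 / sqrt(10 * 10) = 0.80
  d <- data.frame(x = 1:5, y = c(2, 1, 4, 3, 5))
  f <- fit_single_model(d, model_spec("y", "x"))
  expect_equal(f$beta, 0.80, tolerance = 1e-12)
  # closed-form Wald pieces for simple OLS on z-scores
  r <- 0.8; n <- 5
  se <- sqrt((1 - r^2) / (n - 2))
  expect_equal(f$se, se, tolerance = 1e-10)
  expect_equal(f$t, r / se, tolerance = 1e-10)
  expect_equal(f$p, 2 * pt(-abs(r / se), n - 2), tolerance = 1e-10)
  expect_equal(f$ci_lower, r - qt(0.975, n - 2) * se, tolerance = 1e-10)
  expect_equal(f$ci_upper, r + qt(0.975, n - 2) * se, tolerance = 1e-10)
  expect_equal(f$n_obs, 5L)
  expect_false(f$degenerate)

  # property: beta == cor(x, y) across random tables, and is symmetric
  for (s in 1:10) {
    d <- make_xy(25, runif(1, -0.9, 0.9), seed = 100 + s)
    f1 <- fit_single_model(d, model_spec("y", "x"))
    f2 <- fit_single_model(d, model_spec("x", "y"))
    expect_lt(abs(f1$beta - cor(d$x, d$y)), 1e-10)
    expect_lt(abs(f1$beta - f2$beta), 1e-10)
    expect_true(f1$ci_lower <= f1$beta && f1$beta <= f1$ci_upper)
    expect_true(f1$p >= 0 && f1$p <= 1 && f1$se >= 0)
  }
})

test_that("perfect fits are flagged degenerate, not errors", {
  d <- data.frame(x = 1:10, y = -(1:10))
  f <- fit_single_model(d, model_spec("y", "x"))
  expect_equal(f$beta, -1.0, tolerance = 1e-10)
  expect_true(f$degenerate)
  expect_equal(f$se, 0)
  expect_equal(f$p, 0)
  expect_equal(f$ci_lower, f$beta)
  expect_equal(f$ci_upper, f$beta)
})

test_that("missing data, degenerate columns, tiny n are handled per contract", {
  d <- data.frame(x = c(1:6, NA), y = c(2, 1, 4, 3, 5, NA, 7))
  f <- fit_single_model(d, model_spec("y", "x"))
  expect_equal(f$n_obs, 5L)  # listwise deletion
  expect_error(
    fit_single_model(data.frame(x = c(1, 2, NA), y = c(1, 2, 3)),
                     model_spec("y", "x")),
    "insufficient data")
  expect_error(
    fit_single_model(data.frame(x = rep(1, 5), y = 1:5), model_spec("y", "x")),
    "zero-variance variable")
  expect_error(fit_single_model(data.frame(x = 1:5), model_spec("y", "x")),
               "columns not found.*y")
})

test_that("weights: scale invariance and weighted slope oracle", {
  set.seed(21)
  d <- make_xy(60, 0.5, seed = 21)
  d$w <- runif(60, 0.5, 3)
  f1 <- fit_single_model(d, model_spec("y", "x", weights = "w"))
  d2 <- d; d2$w <- d$w * 41.7
  f2 <- fit_single_model(d2, model_spec("y", "x", weights = "w"))
  for (col in c("beta", "se", "t", "p", "ci_lower", "ci_upper")) {
    expect_lt(abs(f1[[col]] - f2[[col]]), 1e-10)
  }
  # oracle: weighted correlation from explicit weighted moments
  w <- d$w
  mx <- sum(w * d$x) / sum(w); my <- sum(w * d$y) / sum(w)
  r_w <- sum(w * (d$x - mx) * (d$y - my)) /
    sqrt(sum(w * (d$x - mx)^2) * sum(w * (d$y - my)^2))
  expect_equal(f1$beta, r_w, tolerance = 1e-10)
})

test_that("clustered fits: random intercept model runs, single level falls back", {
  d <- simulate_timss_like(one_predictor_config(0.25, seed = 5,
                                                n_countries = 6,
                                                schools_per_country = 5,
                                                students_per_school = 8))
  f <- fit_single_model(d, model_spec("BSMMAT01", "GDP", weights = "weight",
                                      cluster = "school"))
  expect_true(is.finite(f$beta) && is.finite(f$se))
  expect_true(f$ci_lower <= f$beta && f$beta <= f$ci_upper)
  # clustered SE must exceed the naive OLS SE for a cluster-constant predictor
  f_ols <- fit_single_model(d, model_spec("BSMMAT01", "GDP",
                                          weights = "weight"))
  expect_gt(f$se, f_ols$se)

  d1 <- make_xy(20, 0.3, seed = 3)
  d1$g <- "only"
  expect_warning(
    f1 <- fit_single_model(d1, model_spec("y", "x", cluster = "g")),
    "single level")
  expect_equal(f1$beta, cor(d1$x, d1$y), tolerance = 1e-10)
})

test_that("CI width shrinks with n on nested samples", {
  d <- make_xy(2000, 0.3, seed = 42)
  widths <- sapply(c(100, 500, 2000), function(n) {
    f <- fit_single_model(d[seq_len(n), ], model_spec("y", "x"))
    f$ci_upper - f$ci_lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("fit_model_grid has the right shape, order, and error handling", {
  set.seed(8)
  d <- data.frame(o1 = rnorm(20), o2 = rnorm(20), o3 = rep(1, 20),
                  p1 = rnorm(20), p2 = rnorm(20))
  g <- fit_model_grid(d, outcomes = c("o1", "o2", "o3"),
                      predictors = c("p1", "p2"))
  expect_equal(nrow(g), 6L)
  # outer loop predictors, inner outcomes
  expect_equal(g$predictor, rep(c("p1", "p2"), each = 3))
  expect_equal(g$outcome, rep(c("o1", "o2", "o3"), 2))
  # constant outcome recorded as an error row, grid not aborted
  expect_true(all(grepl("zero-variance", g$error[g$outcome == "o3"])))
  expect_true(all(is.na(g$error[g$outcome != "o3"])))

  g1 <- fit_model_grid(d, "o1", "p1")
  f1 <- fit_single_model(d, model_spec("o1", "p1"))
  expect_equal(g1, f1)

  expect_error(fit_model_grid(d, character(0), "p1"), "nonempty")
  expect_error(fit_model_grid(d, c("o1", "p1"), "p1"), "overlap")
})

test_that("95% CI covers the true standardized slope (parameter recovery)", {
  # scaled-down simulation oracle: slope recovered across seeds
  for (b0 in c(-0.3, 0, 0.25)) {
    hits <- 0
    n_rep <- 100
    for (s in seq_len(n_rep)) {
      set.seed(4000 + s)
      x <- rnorm(150)
      y <- b0 * x + sqrt(1 - b0^2) * rnorm(150)
      f <- fit_single_model(data.frame(x = x, y = y), model_spec("y", "x"))
      if (f$ci_lower <= b0 && b0 <= f$ci_upper) hits <- hits + 1
    }
    expect_gte(hits, 90)
  }
})
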