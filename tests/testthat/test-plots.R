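# Structural assertions target the ggplot layer data (the vector object
# tree), not rendered pixels. Layer order in all three plots: null line,
# benchmark lines, then the data geometry.

ranges_fixture <- function(n_dom = 3, n_pred = 2) {
  grid <- expand.grid(predictor = sprintf("p%d", seq_len(n_pred)),
                      domain = sprintf("D%d", seq_len(n_dom)),
                      stringsAsFactors = FALSE)
  set.seed(1)
  beta <- runif(nrow(grid), -0.2, 0.4)
  data.frame(domain = grid$domain, predictor = grid$predictor,
             beta_pooled = beta, est_min = beta - 0.02,
             est_max = beta + 0.02, ci_outer_lower = beta - 0.08,
             ci_outer_upper = beta + 0.08, stringsAsFactors = FALSE)
}

draws_fixture <- function(n_out = 2, n_pred = 2, n_reps = 60) {
  set.seed(2)
  cells <- expand.grid(predictor = sprintf("m%d", seq_len(n_pred)),
                       outcome = sprintf("e%d", seq_len(n_out)),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(beta = rnorm(n_reps, 0.1 * i, 0.05),
               predictor = cells$predictor[i], outcome = cells$outcome[i],
               replicate = seq_len(n_reps), stringsAsFactors = FALSE)
  }))
}

test_that("beta-range forest plot: band counts, reference lines, geometry", {
  r <- ranges_fixture(3, 2)
  p <- plot_beta_range_forest(r, plot_options())
  b <- ggplot2::ggplot_build(p)
  expect_length(b$data, 5)
  expect_equal(b$data[[1]]$xintercept, 0)               # red null line
  expect_equal(b$data[[1]]$colour, "red")
  expect_equal(b$data[[2]]$xintercept,
               c(-0.5, -0.3, -0.1, 0.1, 0.3, 0.5))      # benchmarks
  expect_equal(nrow(b$data[[3]]), 6)                    # whiskers
  expect_equal(nrow(b$data[[4]]), 6)                    # bands
  expect_equal(nrow(b$data[[5]]), 6)                    # pooled ticks
  # whiskers span the outer CI limits; bands span the estimate range
  expect_setequal(round(b$data[[3]]$x, 10), round(r$ci_outer_lower, 10))
  expect_setequal(round(b$data[[4]]$xmin, 10), round(r$est_min, 10))
  expect_setequal(round(b$data[[5]]$x, 10), round(r$beta_pooled, 10))
})

test_that("a whisker spanning zero crosses the null line in the geometry", {
  r <- data.frame(domain = "D", predictor = "p", beta_pooled = 0.03,
                  est_min = 0.02, est_max = 0.05, ci_outer_lower = -0.04,
                  ci_outer_upper = 0.1)
  b <- ggplot2::ggplot_build(plot_beta_range_forest(r, plot_options()))
  expect_lt(b$data[[3]]$x, 0)
  expect_gt(b$data[[3]]$xend, 0)
})

test_that("degenerate single-row range renders; invalid rows error first", {
  r <- data.frame(domain = "D", predictor = "p", beta_pooled = 0.2,
                  est_min = 0.2, est_max = 0.2, ci_outer_lower = 0.1,
                  ci_outer_upper = 0.3)
  expect_silent(p <- plot_beta_range_forest(r, plot_options()))
  expect_equal(nrow(ggplot2::ggplot_build(p)$data[[4]]), 1)

  bad <- r; bad$est_min <- 0.5  # violates est_min <= beta_pooled <= est_max
  expect_error(plot_beta_range_forest(bad, plot_options()),
               "invariant violated")
  expect_error(plot_beta_range_forest(r[0, ], plot_options()), "empty")
})

test_that("ridgeline: one lane per outcome, one density per predictor", {
  d <- draws_fixture(3, 2)
  p <- plot_bootstrap_ridgeline(d, plot_options())
  b <- ggplot2::ggplot_build(p)
  expect_length(b$data, 3)
  expect_equal(length(unique(b$data[[3]]$group)), 6)    # 3 lanes x 2 curves
  # cell with < 2 distinct values errors with the cell name
  bad <- rbind(d, data.frame(beta = rep(0.5, 5), predictor = "solo",
                             outcome = "e1", replicate = 1:5))
  expect_error(plot_bootstrap_ridgeline(bad, plot_options()),
               "solo x e1.*distinct")
})

test_that("density mode lands where the draws concentrate (histogram oracle)", {
  set.seed(33)
  d <- data.frame(beta = rnorm(500, 0.4, 0.01), predictor = "p",
                  outcome = "o", replicate = 1:500)
  den <- cell_densities(d)
  mode_x <- den$x[which.max(den$density)]
  expect_gt(mode_x, 0.37)
  expect_lt(mode_x, 0.43)
  h <- hist(d$beta, breaks = 30, plot = FALSE)
  expect_lt(abs(mode_x - h$mids[which.max(h$counts)]), 0.02)
})

test_that("violin: one glyph per cell, mirrored about its center", {
  d <- draws_fixture(2, 3)
  p <- plot_bootstrap_violin(d, plot_options())
  b <- ggplot2::ggplot_build(p)
  expect_length(b$data, 3)
  poly <- b$data[[3]]
  expect_equal(length(unique(poly$group)), 6)           # 2 outcomes x 3
  for (g in unique(poly$group)) {
    xs <- poly$x[poly$group == g]
    center <- (max(xs) + min(xs)) / 2
    # mirrored outline: right half drawn forward, left half drawn back,
    # so the two halves are reflections of one another about the center
    right <- xs[seq_len(length(xs) / 2)]
    left <- rev(xs[-seq_len(length(xs) / 2)])
    expect_lt(max(abs((left - center) + (right - center))), 1e-8)
  }
})

test_that("ridgeline and violin share the same density estimate per cell", {
  d <- draws_fixture(2, 2)
  den <- cell_densities(d)
  rp <- ggplot2::ggplot_build(plot_bootstrap_ridgeline(d, plot_options()))
  vp <- ggplot2::ggplot_build(plot_bootstrap_violin(d, plot_options()))
  key <- paste(den$predictor, den$outcome)
  for (k in unique(key)) {
    cell <- den[key == k, ]
    peak_x <- cell$x[which.max(cell$density)]
    # ridgeline: abscissa of the tallest ribbon point in this cell
    rd <- rp$data[[3]]
    # locate the group whose tallest point sits at the same abscissa
    grp_match <- vapply(split(rd, rd$group), function(g) {
      min(g$x) <= peak_x && peak_x <= max(g$x) &&
        abs(g$x[which.max(g$ymax - g$ymin)] - peak_x) < 1e-6
    }, logical(1))
    expect_true(any(grp_match))
    # violin: ordinate of the widest point matches the same peak
    vd <- vp$data[[3]]
    grp_match_v <- vapply(split(vd, vd$group), function(g) {
      wid <- tapply(g$x, g$y, function(x) max(x) - min(x))
      abs(as.numeric(names(which.max(wid))) - peak_x) < 1e-6
    }, logical(1))
    expect_true(any(grp_match_v))
  }
})

test_that("identical inputs give byte-identical SVG output", {
  dir <- withr::local_tempdir()
  r <- ranges_fixture(2, 2)
  f1 <- file.path(dir, "a.svg"); f2 <- file.path(dir, "b.svg")
  plot_beta_range_forest(r, plot_options(), f1)
  plot_beta_range_forest(r, plot_options(), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  d <- draws_fixture(2, 2)
  plot_bootstrap_violin(d, plot_options(), f1)
  plot_bootstrap_violin(d, plot_options(), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("x-limits bound the panel and drop out-of-range benchmarks", {
  opts <- plot_options(x_limits = c(-0.2, 0.4))
  expect_equal(opts$benchmark_lines, c(-0.1, 0.1, 0.3))
  p <- plot_beta_range_forest(ranges_fixture(2, 2), opts)
  b <- ggplot2::ggplot_build(p)
  expect_equal(b$layout$panel_params[[1]]$x.range, c(-0.2, 0.4))
})

test_that("plot files are written in the requested formats", {
  dir <- withr::local_tempdir()
  r <- ranges_fixture(2, 1)
  for (ext in c("svg", "pdf", "png")) {
    f <- file.path(dir, paste0("fig.", ext))
    plot_beta_range_forest(r, plot_options(width = 4, height = 3, dpi = 72), f)
    expect_true(file.exists(f))
    expect_gt(file.size(f), 0)
  }
  expect_error(render_figure <- plot_beta_range_forest(
    r, plot_options(), file.path(dir, "fig.bmp")), "cannot infer")
})
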