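#' Options shared by the three ensemble plots
#'
#' @param null_line_x abscissa of the no-effect reference line (solid red).
#' @param benchmark_lines abscissae of the dotted effect-size benchmark
#'   lines; the defaults mirror the conventional 0.1 / 0.3 / 0.5 thresholds
#'   for small, moderate and large standardized effects, on both sides of
#'   zero since slopes may be negative.
#' @param color_by key the fill color by `"predictor"` (default) or
#'   `"domain"`.
#' @param width,height device size in inches.
#' @param output_format one of `"png"`, `"svg"`, `"pdf"`; default inferred
#'   from the output file extension.
#' @param dpi raster resolution for PNG output.
#' @param x_limits optional length-2 numeric, limits of the beta axis.
#' @return list of class `plot_options`.
#' @export
plot_options <- function(null_line_x = 0,
                         benchmark_lines = c(-0.5, -0.3, -0.1, 0.1, 0.3, 0.5),
                         color_by = c("predictor", "domain"),
                         width = 9, height = 7, output_format = NULL,
                         dpi = 300, x_limits = NULL) {
  color_by <- match.arg(color_by)
  stopifnot(is.numeric(null_line_x), length(null_line_x) == 1,
            all(is.finite(benchmark_lines)), width > 0, height > 0, dpi > 0)
  benchmark_lines <- sort(benchmark_lines)
  if (!is.null(x_limits)) {
    stopifnot(length(x_limits) == 2, x_limits[1] < x_limits[2])
    benchmark_lines <- benchmark_lines[benchmark_lines >= x_limits[1] &
                                       benchmark_lines <= x_limits[2]]
  }
  if (!is.null(output_format)) {
    output_format <- match.arg(output_format, c("png", "svg", "pdf"))
  }
  structure(list(null_line_x = null_line_x,
                 benchmark_lines = benchmark_lines, color_by = color_by,
                 width = width, height = height,
                 output_format = output_format, dpi = dpi,
                 x_limits = x_limits),
            class = "plot_options")
}

# Colorblind-safe qualitative palette keyed by first-appearance order.
ensemble_palette <- function(n) {
  if (n <= 9) {
    unname(grDevices::palette.colors(n, "Okabe-Ito"))
  } else {
    grDevices::hcl.colors(n, "Dark 3")
  }
}

# Write a ggplot to disk with the device chosen from options/extension.
render_figure <- function(p, out_path, options) {
  fmt <- options$output_format
  if (is.null(fmt)) {
    fmt <- tolower(tools::file_ext(out_path))
    if (!fmt %in% c("png", "svg", "pdf")) {
      stop("cannot infer output format from '", out_path,
           "'; set options$output_format", call. = FALSE)
    }
  }
  switch(fmt,
    png = grDevices::png(out_path, width = options$width,
                         height = options$height, units = "in",
                         res = options$dpi),
    svg = grDevices::svg(out_path, width = options$width,
                         height = options$height),
    pdf = grDevices::pdf(out_path, width = options$width,
                         height = options$height)
  )
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out_path)
}

#' Per-cell kernel density estimates of bootstrap draws
#'
#' The single density routine behind both the ridgeline and the violin
#' plot, so the two displays of the same cell are numerically identical.
#' Bandwidth is Silverman's rule of thumb (`bw.nrd0`) on each cell's draws.
#'
#' @param draws data frame with columns `beta`, `predictor`, `outcome`.
#' @param n_grid grid points per cell.
#' @return data frame with columns `outcome`, `predictor`, `x`, `density`.
#' @export
cell_densities <- function(draws, n_grid = 512) {
  stopifnot(is.data.frame(draws), nrow(draws) > 0,
            all(c("beta", "predictor", "outcome") %in% names(draws)))
  key <- paste(draws$predictor, draws$outcome, sep = "\r")
  cells <- unique(key)
  rows <- lapply(cells, function(k) {
    b <- draws$beta[key == k]
    if (length(unique(b)) < 2) {
      stop("cell ", gsub("\r", " x ", k),
           " has fewer than 2 distinct beta values", call. = FALSE)
    }
    den <- stats::density(b, bw = "nrd0", n = n_grid)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(outcome = parts[2], predictor = parts[1],
               x = den$x, density = den$y, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

first_appearance_factor <- function(x) factor(x, levels = unique(x))

# Solid red null line + dotted benchmark lines, shared by all three plots.
reference_vlines <- function(options) {
  list(
    ggplot2::geom_vline(xintercept = options$null_line_x, color = "red",
                        linewidth = 0.6),
    ggplot2::geom_vline(xintercept = options$benchmark_lines,
                        linetype = "dotted", color = "grey30")
  )
}

#' Beta-range forest plot
#'
#' One horizontal band per (domain, predictor) cell: a filled rectangle
#' spanning the range of the plausible-value point estimates, whiskers
#' spanning the outermost confidence limits, and a black vertical tick at
#' the Rubin-pooled estimate. Domains are stacked along the y-axis with the
#' predictor bands dodged within each domain; a solid red line marks the
#' null effect and dotted lines the effect-size benchmarks.
#'
#' @param ranges data frame from [summarize_ranges()].
#' @param options a [plot_options()].
#' @param out_path output file (`.png`, `.svg`, or `.pdf`).
#' @param domain_labels optional named vector of display names for domains
#'   (defaults to [timss_domain_labels()] for codes it knows).
#' @return the ggplot object, invisibly; the figure is written to
#'   `out_path`.
#' @export
plot_beta_range_forest <- function(ranges, options = plot_options(),
                                   out_path = NULL,
                                   domain_labels = timss_domain_labels()) {
  stopifnot(is.data.frame(ranges))
  if (nrow(ranges) == 0) stop("empty beta-range table", call. = FALSE)
  req <- c("domain", "predictor", "beta_pooled", "est_min", "est_max",
           "ci_outer_lower", "ci_outer_upper")
  missing_cols <- setdiff(req, names(ranges))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- with(ranges, !(ci_outer_lower <= est_min & est_min <= beta_pooled &
                        beta_pooled <= est_max & est_max <= ci_outer_upper))
  if (any(bad)) {
    stop("beta-range invariant violated in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }

  d <- ranges
  d$domain <- first_appearance_factor(d$domain)
  d$predictor <- first_appearance_factor(d$predictor)
  nd <- nlevels(d$domain)
  np <- nlevels(d$predictor)
  # domains top-down; predictors dodged top-down within each domain band
  base_y <- nd - as.integer(d$domain) + 1
  offset <- (((np + 1) / 2) - as.integer(d$predictor)) * (0.8 / max(np, 1))
  d$y <- base_y + offset
  h <- 0.8 / max(np, 1) * 0.7   # band thickness
  fill_var <- options$color_by
  labs <- levels(d$domain)
  known <- labs %in% names(domain_labels)
  labs[known] <- domain_labels[labs[known]]

  p <- ggplot2::ggplot(d) +
    reference_vlines(options) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_outer_lower,
                                       xend = .data$ci_outer_upper,
                                       y = .data$y, yend = .data$y),
                          linewidth = 0.4, color = "grey25") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$est_min,
                                    xmax = .data$est_max,
                                    ymin = .data$y - h / 2,
                                    ymax = .data$y + h / 2,
                                    fill = .data[[fill_var]]),
                       color = NA) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$beta_pooled,
                                       xend = .data$beta_pooled,
                                       y = .data$y - h / 2,
                                       yend = .data$y + h / 2),
                          linewidth = 0.7, color = "black") +
    ggplot2::scale_fill_manual(
      values = ensemble_palette(nlevels(d[[fill_var]])), name = fill_var) +
    ggplot2::scale_y_continuous(breaks = nd:1, labels = labs,
                                expand = ggplot2::expansion(add = 0.5)) +
    ggplot2::labs(x = "standardized coefficient (beta)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(options$x_limits)) {
    p <- p + ggplot2::coord_cartesian(xlim = options$x_limits, expand = FALSE)
  }
  if (!is.null(out_path)) render_figure(p, out_path, options)
  invisible(p)
}

#' Bootstrap ridgeline plot
#'
#' One horizontal lane per outcome; within each lane, one kernel-density
#' curve per predictor of that cell's bootstrap coefficients, all sharing
#' the beta axis. Densities are scaled to a common lane height within each
#' outcome. Reference lines as in [plot_beta_range_forest()].
#'
#' @param draws data frame from [bootstrap_grid()] (columns `beta`,
#'   `predictor`, `outcome`).
#' @inheritParams plot_beta_range_forest
#' @return the ggplot object, invisibly.
#' @export
plot_bootstrap_ridgeline <- function(draws, options = plot_options(),
                                     out_path = NULL) {
  stopifnot(is.data.frame(draws))
  if (nrow(draws) == 0) stop("empty bootstrap table", call. = FALSE)
  den <- cell_densities(draws)
  den$outcome <- factor(den$outcome, levels = unique(draws$outcome))
  den$predictor <- factor(den$predictor, levels = unique(draws$predictor))
  nl <- nlevels(den$outcome)
  den$base <- nl - as.integer(den$outcome) + 1
  # common height scale per lane so predictors stay comparable
  lane_max <- stats::ave(den$density, den$outcome, FUN = max)
  den$height <- den$density / lane_max * 0.9
  den$grp <- interaction(den$outcome, den$predictor, drop = TRUE)

  p <- ggplot2::ggplot(den) +
    reference_vlines(options) +
    ggplot2::geom_ribbon(ggplot2::aes(x = .data$x, ymin = .data$base,
                                      ymax = .data$base + .data$height,
                                      group = .data$grp,
                                      fill = .data$predictor),
                         alpha = 0.6, color = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = ensemble_palette(nlevels(den$predictor)), name = "predictor") +
    ggplot2::scale_y_continuous(breaks = nl:1, labels = levels(den$outcome),
                                expand = ggplot2::expansion(add = c(0.2, 1))) +
    ggplot2::labs(x = "standardized coefficient (beta)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(options$x_limits)) {
    p <- p + ggplot2::coord_cartesian(xlim = options$x_limits, expand = FALSE)
  }
  if (!is.null(out_path)) render_figure(p, out_path, options)
  invisible(p)
}

#' Bootstrap violin plot
#'
#' The same per-cell kernel densities as the ridgeline plot, drawn as
#' mirrored (violin) glyphs: outcomes along the x-axis, one violin per
#' predictor dodged within each outcome, beta on the y-axis. The reference
#' lines run horizontally here.
#'
#' @inheritParams plot_bootstrap_ridgeline
#' @return the ggplot object, invisibly.
#' @export
plot_bootstrap_violin <- function(draws, options = plot_options(),
                                  out_path = NULL) {
  stopifnot(is.data.frame(draws))
  if (nrow(draws) == 0) stop("empty bootstrap table", call. = FALSE)
  den <- cell_densities(draws)
  den$outcome <- factor(den$outcome, levels = unique(draws$outcome))
  den$predictor <- factor(den$predictor, levels = unique(draws$predictor))
  np <- nlevels(den$predictor)
  center <- as.integer(den$outcome) +
    (as.integer(den$predictor) - (np + 1) / 2) * (0.9 / max(np, 1))
  halfwidth <- 0.9 / max(np, 1) * 0.45
  cellkey <- paste(den$outcome, den$predictor, sep = "\r")
  cell_max <- stats::ave(den$density, cellkey, FUN = max)
  half <- den$density / cell_max * halfwidth
  # mirrored outline: right side down the grid, left side back up
  ord_fwd <- order(cellkey, den$x)
  ord_rev <- order(cellkey, -den$x)
  poly <- rbind(
    data.frame(xp = (center + half)[ord_fwd], yp = den$x[ord_fwd],
               grp = cellkey[ord_fwd], predictor = den$predictor[ord_fwd],
               side = "r", stringsAsFactors = FALSE),
    data.frame(xp = (center - half)[ord_rev], yp = den$x[ord_rev],
               grp = cellkey[ord_rev], predictor = den$predictor[ord_rev],
               side = "l", stringsAsFactors = FALSE)
  )
  poly <- poly[order(poly$grp, poly$side != "r"), ]

  p <- ggplot2::ggplot(poly) +
    ggplot2::geom_hline(yintercept = options$null_line_x, color = "red",
                        linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = options$benchmark_lines,
                        linetype = "dotted", color = "grey30") +
    ggplot2::geom_polygon(ggplot2::aes(x = .data$xp, y = .data$yp,
                                       group = .data$grp,
                                       fill = .data$predictor),
                          alpha = 0.8, color = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = ensemble_palette(np), name = "predictor") +
    ggplot2::scale_x_continuous(breaks = seq_len(nlevels(den$outcome)),
                                labels = levels(den$outcome)) +
    ggplot2::labs(x = NULL, y = "standardized coefficient (beta)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(options$x_limits)) {
    p <- p + ggplot2::coord_cartesian(ylim = options$x_limits, expand = FALSE)
  }
  if (!is.null(out_path)) render_figure(p, out_path, options)
  invisible(p)
}
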