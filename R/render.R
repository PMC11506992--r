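# Rendering a plot_spec with ggplot2 and the cairo graphics devices.

#' Rendering options
#'
#' Physical figure options for [render_spec()] and [autoplot.plot_spec()].
#' When `height` is `NULL` it defaults to `(1 + 0.8 * n_tracks)` inches per
#' facet row, so candidate labels stay legible as tracks are added.
#'
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution (PNG only).
#' @param format One of `"png"`, `"pdf"`, `"svg"`; inferred from the output
#'   file extension when `NULL`.
#' @param title Optional figure title.
#' @param legend_position `"right"`, `"bottom"`, or `"none"`.
#' @param point_size Point diameter in mm.
#' @param label_size Label text size in mm.
#' @param ncol Number of facet columns.
#' @return A `render_options` list.
#' @export
render_options <- function(width = 11, height = NULL, dpi = 300,
                           format = NULL, title = NULL,
                           legend_position = c("right", "bottom", "none"),
                           point_size = 3, label_size = 2.6, ncol = 2) {
  legend_position <- match.arg(legend_position)
  if (dpi <= 0) gt_config_error("`dpi` must be positive")
  if (width <= 0 || (!is.null(height) && height <= 0)) {
    gt_config_error("`width` and `height` must be positive")
  }
  if (!is.null(format) && !format %in% c("png", "pdf", "svg")) {
    gt_config_error("`format` must be one of png, pdf, svg")
  }
  structure(list(width = width, height = height, dpi = dpi, format = format,
                 title = title, legend_position = legend_position,
                 point_size = point_size, label_size = label_size,
                 ncol = ncol),
            class = "render_options")
}

# Per-family legend grob: a colourbar (or a labelled key for fixed-colour
# families, which is skipped) extracted from a throwaway ggplot.
family_legends <- function(spec, position) {
  legends <- list()
  for (s in spec$scales) {
    if (s$palette$type == "fixed") next
    cols <- if (s$palette$type == "viridis") {
      scales::viridis_pal(option = s$palette$option)(64)
    } else {
      s$palette$colours
    }
    lab <- spec$tracks$label[match(s$family, spec$tracks$family)]
    dummy <- ggplot2::ggplot(
      data.frame(x = s$domain, y = 1),
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$x)
    ) +
      ggplot2::geom_point(shape = 21) +
      ggplot2::scale_fill_gradientn(
        colours = cols, limits = s$domain, name = lab,
        # vector colourbar: rasterised bars embed a cairo image whose id is
        # session-global, which would break byte-identical SVG re-renders
        guide = ggplot2::guide_colourbar(display = "rectangles", nbin = 64)
      ) +
      ggplot2::theme(
        legend.position = position,
        legend.title = ggplot2::element_text(size = 9),
        legend.text = ggplot2::element_text(size = 8)
      )
    g <- cowplot::get_plot_component(dummy, paste0("guide-box-", position),
                                     return_all = TRUE)
    if (is.list(g) && !inherits(g, "grob")) g <- g[[1]]
    if (!is.null(g)) legends[[s$family]] <- g
  }
  legends
}

#' Render a plot specification as a ggplot
#'
#' Turns a [build_plot_spec()] result into the final figure: chromosome
#' facets with free x scales fixed to each chromosome's range (axis labelled
#' in Mb), tracks as labelled y bands, guide lines beneath the points, score
#' colours resolved from the spec's per-family palettes, and the
#' pre-computed label placements drawn with connector segments. Per-family
#' colourbar legends are composed next to the panel (cowplot), giving each
#' score family its own legend.
#'
#' @param object A `plot_spec`.
#' @param options A [render_options()] list.
#' @param ... Unused.
#' @return A ggplot / patchworked grid object ready to print.
#' @method autoplot plot_spec
#' @export
autoplot.plot_spec <- function(object, options = render_options(), ...) {
  spec <- object
  n_tracks <- nrow(spec$tracks)
  ylim <- c(1 - TRACK_BAND - 0.1, n_tracks + TRACK_BAND + 0.1)

  # Resolve point colours from each family's palette over its score domain.
  pts <- spec$points
  pts$fill <- NA_character_
  for (s in spec$scales) {
    f <- palette_fun(s$palette, s$domain)
    sel <- pts$family == s$family
    v <- pts$value[sel]
    v[is.na(v)] <- s$domain[1]
    pts$fill[sel] <- f(v)
  }
  # Shapes below 21 have no fill aesthetic: draw them in the fill colour.
  pts$colour <- ifelse(pts$shape >= 21, "grey20", pts$fill)

  facet_order <- spec$facets$chromosome
  fct <- function(x) factor(x, levels = facet_order)
  blank <- tidyr::pivot_longer(spec$facets, c("xmin", "xmax"),
                               values_to = "x")

  p <- ggplot2::ggplot() +
    ggplot2::geom_blank(data = mutate(blank, chromosome = fct(.data$chromosome)),
                        ggplot2::aes(x = .data$x, y = 1)) +
    ggplot2::geom_segment(
      data = mutate(spec$guide_lines, chromosome = fct(.data$chromosome)),
      ggplot2::aes(x = .data$x, xend = .data$x, colour = .data$colour),
      y = ylim[1], yend = ylim[2], linewidth = 0.25, alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = mutate(pts, chromosome = fct(.data$chromosome)),
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fill,
                   colour = .data$colour, shape = .data$shape),
      size = options$point_size, stroke = 0.3
    ) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_shape_identity()

  if (nrow(spec$labels) > 0) {
    lab <- mutate(spec$labels, chromosome = fct(.data$chromosome))
    p <- p +
      ggplot2::geom_segment(
        data = lab,
        ggplot2::aes(x = .data$anchor_x, xend = .data$label_x,
                     y = .data$anchor_y, yend = .data$label_y - .data$height / 2),
        linewidth = 0.2, colour = "grey40"
      ) +
      ggplot2::geom_text(
        data = lab,
        ggplot2::aes(x = .data$label_x, y = .data$label_y, label = .data$text),
        size = options$label_size, colour = "grey10"
      )
  }

  p <- p +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_x",
                        ncol = min(options$ncol, nrow(spec$facets)),
                        labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(
      name = "Position (Mb)",
      labels = function(x) format(x / 1e6, trim = TRUE, scientific = FALSE),
      expand = ggplot2::expansion(mult = 0.02)
    ) +
    ggplot2::scale_y_continuous(
      name = NULL, limits = ylim,
      breaks = spec$tracks$y, labels = spec$tracks$label,
      expand = ggplot2::expansion(0)
    ) +
    ggplot2::theme_bw(base_size = 10) +
    ggplot2::theme(
      panel.grid.major.y = ggplot2::element_blank(),
      panel.grid.minor.y = ggplot2::element_blank(),
      strip.background = ggplot2::element_rect(fill = "grey92")
    )
  if (!is.null(options$title)) p <- p + ggplot2::ggtitle(options$title)

  if (options$legend_position == "none") return(p)
  legends <- family_legends(spec, options$legend_position)
  if (length(legends) == 0) return(p)
  if (options$legend_position == "right") {
    leg <- cowplot::plot_grid(plotlist = legends, ncol = 1)
    cowplot::plot_grid(p, leg, nrow = 1, rel_widths = c(1, 0.16))
  } else {
    leg <- cowplot::plot_grid(plotlist = legends, nrow = 1)
    cowplot::plot_grid(p, leg, ncol = 1, rel_heights = c(1, 0.14))
  }
}

#' Write a plot specification to an image file
#'
#' Renders the spec with [autoplot.plot_spec()] and writes it as PNG, PDF or
#' SVG through the cairo graphics devices. Output is deterministic: the same
#' spec and options produce byte-identical SVG (and pixel-identical PNG at a
#' fixed dpi) across renders.
#'
#' @param spec A `plot_spec`.
#' @param path Output file; the extension selects the format unless
#'   `options$format` is set.
#' @param options A [render_options()] list.
#' @return The output path, invisibly.
#' @export
render_spec <- function(spec, path, options = render_options()) {
  if (!inherits(spec, "plot_spec")) gt_config_error("`spec` must be a plot_spec")
  fmt <- options$format %||% tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "pdf", "svg")) {
    gt_config_error(paste0("unsupported output format: \"", fmt, "\""))
  }
  n_rows <- ceiling(nrow(spec$facets) / min(options$ncol, nrow(spec$facets)))
  height <- options$height %||% ((1 + 0.8 * nrow(spec$tracks)) * n_rows)
  fig <- autoplot(spec, options = options)

  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    gt_io_error(paste0("cannot write to: ", path))
  }
  switch(fmt,
    png = grDevices::png(path, width = options$width, height = height,
                         units = "in", res = options$dpi, type = "cairo"),
    pdf = grDevices::cairo_pdf(path, width = options$width, height = height,
                               onefile = TRUE),
    svg = grDevices::svg(path, width = options$width, height = height)
  )
  ok <- tryCatch({ print(fig); TRUE },
                 finally = grDevices::dev.off())
  if (!ok || !file.exists(path)) gt_io_error(paste0("failed to write: ", path))
  invisible(path)
}
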