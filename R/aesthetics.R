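# Per-track display contracts.

#' Track aesthetics
#'
#' Describes how one track type is drawn: the y-axis label of its band, the
#' colour of the vertical guide lines emitted at its features' positions, the
#' point shape, whether feature names are shown as labels, and the fill scale
#' used to colour points by score.
#'
#' @param y_label Track label shown on the y axis (`NULL`: use the table's
#'   label or a kind default).
#' @param line_colour Colour of the vertical guide lines for this track.
#' @param point_shape Plotting symbol (an R `pch` number; shapes 21–25 take a
#'   fill, others are drawn in the fill colour directly).
#' @param show_name Should feature names be drawn as labels (needs a `name`
#'   column)?
#' @param fill_scale Colour scale for the score gradient: `NULL` for the
#'   track family's default, the name of a viridis palette option (e.g.
#'   `"rocket"`, `"mako"`), or a character vector of colours to interpolate.
#' @return A `track_aes` list.
#' @examples
#' track_aes(y_label = "QTL regions", line_colour = "darkgoldenrod2",
#'           point_shape = 18, show_name = TRUE)
#' @export
track_aes <- function(y_label = NULL, line_colour = "grey50",
                      point_shape = 21, show_name = FALSE,
                      fill_scale = NULL) {
  if (!is.numeric(point_shape) || length(point_shape) != 1) {
    gt_config_error("`point_shape` must be a single pch number")
  }
  structure(
    list(y_label = y_label, line_colour = line_colour,
         point_shape = as.integer(point_shape),
         show_name = isTRUE(show_name), fill_scale = fill_scale),
    class = "track_aes"
  )
}

# Built-in defaults per track kind. Custom tracks must be given an explicit
# entry keyed by their aes_type.
default_track_aes <- function(kind) {
  switch(kind,
    gwas = track_aes(y_label = "GWAS peaks", line_colour = "cornflowerblue",
                     point_shape = 21, fill_scale = "viridis"),
    de = track_aes(y_label = "DE genes", line_colour = "firebrick3",
                   point_shape = 21, fill_scale = "plasma"),
    candidate = track_aes(y_label = "Candidate genes", line_colour = "grey45",
                          point_shape = 21, show_name = TRUE,
                          fill_scale = "grey30"),
    custom = track_aes(y_label = "Custom track", line_colour = "darkorange2",
                       point_shape = 23, fill_scale = "mako")
  )
}

as_track_aes <- function(x, tag = NULL) {
  if (inherits(x, "track_aes")) return(x)
  if (!is.list(x)) {
    gt_config_error(paste0("aesthetics for `", tag %||% "?", "` must be a list"))
  }
  known <- c("y_label", "line_colour", "point_shape", "show_name", "fill_scale")
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    gt_config_error(paste0("unknown track_aes field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(track_aes, modifyList(list(point_shape = 23, line_colour = "darkorange2"), x))
}

# Serialisable palette spec for a scale family.
palette_spec <- function(fill_scale, default_option) {
  fs <- fill_scale %||% default_option
  if (is.character(fs) && length(fs) == 1 &&
      fs %in% c("viridis", "magma", "plasma", "inferno", "cividis",
                "rocket", "mako", "turbo")) {
    list(type = "viridis", option = fs)
  } else if (is.character(fs) && length(fs) == 1) {
    list(type = "fixed", colour = fs)
  } else if (is.character(fs)) {
    list(type = "gradient", colours = fs)
  } else {
    gt_config_error("`fill_scale` must be NULL, a viridis option name, a single colour, or a colour vector")
  }
}

# Resolve a palette spec to a function mapping values in [domain] to hex.
palette_fun <- function(spec, domain) {
  if (spec$type == "fixed") {
    col <- spec$colour
    return(function(v) rep(col, length(v)))
  }
  cols <- if (spec$type == "viridis") {
    scales::viridis_pal(option = spec$option)(64)
  } else {
    spec$colours
  }
  if (!is.finite(domain[1]) || !is.finite(domain[2]) || domain[1] == domain[2]) {
    mid <- cols[ceiling(length(cols) / 2)]
    return(function(v) rep(mid, length(v)))
  }
  pal <- scales::gradient_n_pal(cols)
  function(v) pal(pmin(pmax((v - domain[1]) / (domain[2] - domain[1]), 0), 1))
}
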