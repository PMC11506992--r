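# Declarative figure layout: a renderer-independent plot specification.
#
# A plot_spec fully describes the figure: one facet per chromosome with its
# x-axis range, one y-band per input table (track), points at feature
# positions carrying a colour value and scale family, full-height vertical
# guide lines at every point, overlap-free labels, and one colour scale per
# score family. Building it twice from equal inputs yields identical
# structures, so it can be serialised to JSON and snapshot-tested.

# Vertical half-height of a track band (tracks sit at integer y positions).
TRACK_BAND <- 0.45

default_family_palette <- function(kind) {
  switch(kind, gwas = "viridis", de = "plasma", candidate = "grey30", "mako")
}

# Crop tables to limits without the unknown-chromosome warning (used when
# limits were already applied upstream and are only needed for axis ranges).
crop_tables <- function(tbls, limits) {
  purrr::map(tbls, function(tb) {
    idx <- match(tb$chromosome, limits$chromosome)
    keep <- is.na(idx) |
      (tb$position >= limits$min[idx] & tb$position <= limits$max[idx])
    keep[is.na(keep)] <- FALSE
    tb[keep, , drop = FALSE]
  })
}

#' Assemble the declarative plot specification
#'
#' Lays the filtered feature tables out as a chromosome-faceted track figure:
#' the x axis is physical position in bp, each chromosome gets its own facet,
#' and each input table gets one horizontal track, stacked top to bottom as
#' GWAS track(s), DE track(s), custom track(s), then candidate genes. Every
#' feature becomes a point at its (resolved) position, coloured by its score
#' — or, on request, DE points by their log2 fold-change — and emits a
#' vertical guide line spanning all tracks in the track's line colour, so
#' co-located features in different tracks line up visually. Candidate genes
#' with a non-missing name, and features of custom tracks whose aesthetics
#' set `show_name`, receive a text label placed by [place_labels()].
#'
#' Scores of `Inf` (adjusted p-values of exactly 0) are drawn at the top of
#' the colour gradient: each family's colour scale spans the finite score
#' range and infinite values are capped there.
#'
#' @param tables A (possibly nested) list of threshold-filtered
#'   `feature_table`s; order within a kind is preserved.
#' @param lengths Chromosome lengths (see [compute_chrom_length()]); computed
#'   from `tables` when `NULL` (note the facet ranges then reflect the
#'   filtered data only).
#' @param limits Optional per-chromosome display windows
#'   (see [as_chrom_limits()]); they set the facet axis ranges and crop any
#'   record still outside them.
#' @param custom_aes Named list mapping each custom table's `aes_type` tag to
#'   a [track_aes()]; an unknown tag is a configuration error.
#' @param colour_de_by_log2fc Colour DE points by log2 fold-change instead of
#'   score.
#' @return A `plot_spec` object: a list of tibbles (`facets`, `tracks`,
#'   `points`, `guide_lines`, `labels`) plus per-family colour `scales`.
#'   Render it with [autoplot.plot_spec()] or [render_spec()].
#' @examples
#' gwas <- as_gwas_table(data.frame(
#'   chromosome = c("1", "2"), position = c(5e5, 1e6), score = c(5, 6)
#' ))
#' spec <- build_plot_spec(list(gwas))
#' glance(spec)
#' @export
build_plot_spec <- function(tables, lengths = NULL, limits = NULL,
                            custom_aes = list(), colour_de_by_log2fc = FALSE) {
  tbls <- flatten_tables(tables)
  if (length(tbls) == 0) gt_nothing_to_plot("nothing to plot: no input tables")
  ok <- vapply(tbls, is_feature_table, logical(1))
  if (!all(ok)) gt_config_error("all tables must be validated feature_tables")

  if (sum(vapply(tbls, nrow, integer(1))) == 0) gt_nothing_to_plot()

  limits_tb <- as_chrom_limits(limits)
  if (is.null(lengths)) lengths <- compute_chrom_length(tbls)
  lengths <- as_chrom_lengths(lengths)
  limits_tb <- filter(limits_tb, .data$chromosome %in% lengths$chromosome)
  tbls <- crop_tables(tbls, limits_tb)

  data_chroms <- unique(unlist(purrr::map(tbls, ~ unique(.x$chromosome))))
  missing_len <- setdiff(data_chroms, lengths$chromosome)
  if (length(missing_len) > 0) {
    gt_value_error(paste0("no chromosome length for: ",
                          paste(missing_len, collapse = ", ")))
  }

  # Track assembly in display order (top to bottom).
  kind_rank <- c(gwas = 1, de = 2, custom = 3, candidate = 4)
  ord <- order(kind_rank[vapply(tbls, table_kind, character(1))])
  tbls <- tbls[ord]

  track_rows <- purrr::imap(tbls, function(tb, i) {
    kind <- table_kind(tb)
    if (kind == "custom") {
      tag <- table_aes_type(tb)
      if (!tag %in% names(custom_aes)) {
        gt_config_error(paste0("no track aesthetics supplied for aes_type \"",
                               tag, "\""))
      }
      aes <- as_track_aes(custom_aes[[tag]], tag)
      family <- tag
    } else {
      aes <- default_track_aes(kind)
      family <- kind
    }
    tibble(
      track_id = i,
      kind = kind,
      family = family,
      label = table_label(tb) %||% aes$y_label %||% default_track_aes(kind)$y_label,
      line_colour = aes$line_colour,
      shape = aes$point_shape,
      show_name = if (kind == "candidate") TRUE else aes$show_name,
      fill_scale = list(palette_spec(aes$fill_scale, default_family_palette(kind)))
    )
  })
  tracks <- bind_rows(track_rows)
  n_tracks <- nrow(tracks)
  tracks$y <- n_tracks - tracks$track_id + 1 # top track = highest y

  # Facets: axis range is [0, length], narrowed by any display limit.
  facets <- lengths |>
    left_join(limits_tb, by = "chromosome") |>
    mutate(xmin = if_else(is.na(.data$min), 0, .data$min),
           xmax = if_else(is.na(.data$max), .data$length, .data$max)) |>
    select("chromosome", "xmin", "xmax")

  # Points: one per retained record, carrying its colour value and family.
  points <- purrr::imap(tbls, function(tb, i) {
    if (nrow(tb) == 0) return(NULL)
    kind <- table_kind(tb)
    value <- if (kind == "candidate") {
      rep(NA_real_, nrow(tb))
    } else if (kind == "de" && colour_de_by_log2fc) {
      tb$log2FoldChange
    } else {
      tb$score
    }
    tibble(track_id = i, chromosome = tb$chromosome, x = tb$position,
           value = as.numeric(value),
           name = if ("name" %in% names(tb)) as.character(tb$name) else NA_character_)
  }) |> bind_rows()

  if (is.null(points) || nrow(points) == 0) gt_nothing_to_plot()
  points <- points |>
    filter(.data$chromosome %in% facets$chromosome) |>
    left_join(select(tracks, "track_id", "y", "family", "shape"), by = "track_id")
  if (nrow(points) == 0) gt_nothing_to_plot()

  # One colour scale per score family; infinite scores cap at the finite max.
  fam_first <- tracks[!duplicated(tracks$family), ]
  scales_list <- purrr::map(seq_len(nrow(fam_first)), function(j) {
    fam <- fam_first$family[j]
    vals <- points$value[points$family == fam]
    finite <- vals[is.finite(vals)]
    domain <- if (length(finite) > 0) range(finite) else c(0, 1)
    list(family = fam, kind = fam_first$kind[j],
         palette = fam_first$fill_scale[[j]], domain = domain)
  })
  names(scales_list) <- fam_first$family
  cap <- vapply(scales_list, function(s) s$domain[2], numeric(1))
  points$value <- ifelse(is.infinite(points$value),
                         cap[points$family], points$value)

  guide_lines <- points |>
    left_join(select(tracks, "track_id", "line_colour"), by = "track_id") |>
    select("chromosome", "x", colour = "line_colour", "track_id")

  # Labels: candidate names + custom tracks with show_name, placed per
  # facet x track band with deterministic overlap avoidance.
  label_src <- points |>
    left_join(select(tracks, "track_id", "kind", "show_name"), by = "track_id") |>
    filter(.data$show_name, !is.na(.data$name), .data$name != "")
  labels <- purrr::pmap(
    distinct(label_src, .data$chromosome, .data$track_id),
    function(chromosome, track_id) {
      grp <- label_src[label_src$chromosome == chromosome &
                         label_src$track_id == track_id, ]
      fc <- facets[facets$chromosome == chromosome, ]
      ty <- tracks$y[tracks$track_id == track_id]
      placed <- place_labels(tibble(x = grp$x, text = grp$name),
                             xlim = c(fc$xmin, fc$xmax),
                             band = c(ty + 0.08, ty + TRACK_BAND))
      if (nrow(placed) == 0) return(NULL)
      tibble(chromosome = chromosome, track_id = track_id,
             text = placed$text, anchor_x = placed$x, anchor_y = ty,
             label_x = placed$label_x, label_y = placed$label_y,
             width = placed$width, height = placed$height)
    }) |> bind_rows()
  if (is.null(labels) || nrow(labels) == 0) {
    labels <- tibble(chromosome = character(), track_id = integer(),
                     text = character(), anchor_x = numeric(),
                     anchor_y = numeric(), label_x = numeric(),
                     label_y = numeric(), width = numeric(), height = numeric())
  }

  structure(
    list(facets = facets,
         tracks = select(tracks, -"fill_scale"),
         points = select(points, -"name"),
         guide_lines = guide_lines,
         labels = labels,
         scales = scales_list,
         options = list(colour_de_by_log2fc = colour_de_by_log2fc)),
    class = "plot_spec"
  )
}

#' Deterministic overlap-avoiding label placement
#'
#' Places text labels near their anchor x positions inside a horizontal band,
#' so that no two label boxes overlap. Placement is a greedy search, in input
#' order, over a fixed grid of candidate positions (stacked rows within the
#' band, then sideways displacement), so the result is fully deterministic —
#' no force simulation, no randomness. A label for which no free position
#' exists is dropped with a warning (the figure keeps its point; only the
#' text is thinned).
#'
#' Label box sizes are estimated from text length: width is
#' `(nchar + 1) * char_frac * diff(xlim)` and height is a fixed fraction of
#' the band, matching how the renderer draws them.
#'
#' @param labels A data frame with columns `x` (anchor position) and `text`.
#' @param xlim Numeric length-2 axis range of the facet.
#' @param band Numeric length-2 vertical band (in track y units) available
#'   for labels.
#' @param char_frac Width of one character as a fraction of the axis range.
#' @return A tibble with one row per placed label: `x`, `text`, `label_x`,
#'   `label_y` (box centre), `width`, `height`.
#' @examples
#' place_labels(data.frame(x = c(100, 100), text = c("geneA", "geneB")),
#'              xlim = c(0, 1000), band = c(1.1, 1.45))
#' @export
place_labels <- function(labels, xlim, band = c(0.08, TRACK_BAND),
                         char_frac = 0.013) {
  labels <- as_tibble(labels)
  if (nrow(labels) == 0) {
    return(tibble(x = numeric(), text = character(), label_x = numeric(),
                  label_y = numeric(), width = numeric(), height = numeric()))
  }
  if (any(labels$x < xlim[1] | labels$x > xlim[2])) {
    gt_value_error("label anchors must lie within `xlim`")
  }
  xr <- diff(xlim)
  h <- (band[2] - band[1]) / 3 # three stacked label rows fit in the band
  rows_y <- band[1] + h / 2 + (0:2) * h
  widths <- (nchar(labels$text) + 1) * char_frac * xr

  placed <- list()
  dropped <- character()
  overlaps <- function(x, y, w) {
    for (p in placed) {
      if (abs(x - p$x) < (w + p$w) / 2 && abs(y - p$y) < h * 0.999) return(TRUE)
    }
    FALSE
  }
  out <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    w <- widths[i]
    shifts <- c(0, rep(seq_len(6), each = 2) * c(1, -1) * 0.6 * w)
    done <- FALSE
    for (ry in rows_y) {
      if (done) break
      for (dx in shifts) {
        lx <- min(max(labels$x[i] + dx, xlim[1] + w / 2), xlim[2] - w / 2)
        if (w >= xr) lx <- mean(xlim) # degenerate: label wider than the facet
        if (!overlaps(lx, ry, w)) {
          placed[[length(placed) + 1]] <- list(x = lx, y = ry, w = w)
          out[[i]] <- tibble(x = labels$x[i], text = labels$text[i],
                             label_x = lx, label_y = ry, width = w, height = h)
          done <- TRUE
          break
        }
      }
    }
    if (!done) dropped <- c(dropped, labels$text[i])
  }
  if (length(dropped) > 0) {
    warn(paste0("thinned ", length(dropped), " label(s) that could not be placed without overlap: ",
                paste(head(dropped, 5), collapse = ", ")))
  }
  bind_rows(out)
}

#' @export
print.plot_spec <- function(x, ...) {
  g <- glance(x)
  cat("<plot_spec>: ", g$n_facets, " chromosome facet(s) x ", g$n_tracks,
      " track(s); ", g$n_points, " point(s), ", g$n_labels, " label(s)\n",
      sep = "")
  cat("tracks (top to bottom): ",
      paste(x$tracks$label[order(-x$tracks$y)], collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Tidy and summarise a plot specification
#'
#' `tidy()` returns the plotted points — one row per retained feature, with
#' its facet, track label, position and colour value. `glance()` returns a
#' one-row summary of figure dimensions.
#'
#' @param x A `plot_spec`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plot_spec
#' @export
tidy.plot_spec <- function(x, ...) {
  x$points |>
    left_join(select(x$tracks, "track_id", "label", "kind"), by = "track_id") |>
    select("chromosome", track = "label", "kind", "x", "value", "family")
}

#' @rdname tidy.plot_spec
#' @method glance plot_spec
#' @export
glance.plot_spec <- function(x, ...) {
  tibble(n_facets = nrow(x$facets), n_tracks = nrow(x$tracks),
         n_points = nrow(x$points), n_guide_lines = nrow(x$guide_lines),
         n_labels = nrow(x$labels), n_scales = length(x$scales))
}

#' Serialise a plot specification to JSON
#'
#' A stable JSON rendering of the full `plot_spec`, suitable for snapshot
#' testing and for driving external renderers.
#'
#' @param spec A `plot_spec`.
#' @param path Optional file to write to; the JSON string is returned either
#'   way (invisibly when writing).
#' @return A JSON string.
#' @export
plot_spec_json <- function(spec, path = NULL) {
  payload <- list(
    facets = spec$facets, tracks = spec$tracks, points = spec$points,
    guide_lines = spec$guide_lines, labels = spec$labels,
    scales = unname(spec$scales), options = spec$options
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
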