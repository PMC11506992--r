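# Significance filtering, chromosome lengths, display limits.

#' Filter a feature table by significance thresholds
#'
#' Retains exactly the records whose resolved score is greater than or equal
#' to `score_thr` and — for DE tables — whose absolute resolved log2
#' fold-change is at least `log2fc_thr` (absolute value, so down-regulated
#' genes are kept symmetrically). Records with a missing score, or a missing
#' log2 fold-change on a DE table, are removed. Candidate tables carry no
#' score and pass through unfiltered. Row order is preserved and retained
#' rows are unmodified.
#'
#' Filtering is idempotent at fixed thresholds and monotone in them: raising
#' a threshold never retains more records. A `score_thr` of 0 together with
#' `log2fc_thr = 0` keeps every record with non-missing values.
#'
#' @param table A validated `feature_table` (see [validate_table()]).
#' @param score_thr Minimum resolved score (a -log10 p-value scale).
#' @param log2fc_thr Minimum absolute log2 fold-change; only meaningful for
#'   DE tables (defaults to 0 there; an error if supplied for another kind).
#' @return The filtered `feature_table` (attributes preserved).
#' @examples
#' tbl <- as_gwas_table(data.frame(
#'   chromosome = "1", position = 1:5 * 100,
#'   score = c(0.5, 1.3, 2, NA, 4)
#' ))
#' apply_threshold(tbl, score_thr = 1.3)
#' @export
apply_threshold <- function(table, score_thr = 0, log2fc_thr = NULL) {
  if (!is_feature_table(table)) {
    gt_config_error("`table` must be a validated feature_table")
  }
  kind <- table_kind(table)
  if (!is.null(log2fc_thr) && kind != "de") {
    gt_config_error("`log2fc_thr` applies to DE tables only")
  }
  if (kind == "candidate") return(table)
  keep <- !is.na(table$score) & table$score >= score_thr
  if (kind == "de") {
    log2fc_thr <- log2fc_thr %||% 0
    keep <- keep & !is.na(table$log2FoldChange) &
      abs(table$log2FoldChange) >= log2fc_thr
  }
  table[keep, , drop = FALSE]
}

#' Chromosome lengths inferred from the data
#'
#' The length of each chromosome is taken as the maximum marker or gene
#' position (gene `end`, where present) across all input tables; this sets
#' the x-axis range of that chromosome's facet. User-supplied lengths
#' override the inferred value entirely for the chromosomes they list (useful
#' when no feature sits near a chromosome end), and chromosomes only listed
#' by the user are included as well. Lengths should be computed on the
#' unfiltered inputs so facet widths do not shrink as thresholds tighten.
#'
#' @param tables A feature table or (possibly nested) list of feature tables.
#' @param lengths Optional user-supplied lengths: a two-column data frame
#'   `(chromosome, length)` or a named numeric vector.
#' @return A tibble `(chromosome, length)` in natural chromosome order.
#' @examples
#' gwas <- as_gwas_table(data.frame(
#'   chromosome = "1", position = c(10, 500), score = 1
#' ))
#' compute_chrom_length(gwas)
#' @export
compute_chrom_length <- function(tables, lengths = NULL) {
  tables <- flatten_tables(tables)
  rows <- purrr::map(tables, function(tb) {
    pos <- c(tb$position, if ("end" %in% names(tb)) tb$end)
    chroms <- c(tb$chromosome, if ("end" %in% names(tb)) tb$chromosome)
    tibble(chromosome = chroms, pos = pos)
  })
  inferred <- bind_rows(rows) |> filter(!is.na(.data$pos))
  if (nrow(inferred) == 0 && is.null(lengths)) {
    gt_value_error("no features to infer chromosome lengths from")
  }
  inferred <- inferred |>
    group_by(.data$chromosome) |>
    summarise(length = max(.data$pos), .groups = "drop")

  if (!is.null(lengths)) {
    user <- as_chrom_lengths(lengths)
    short <- left_join(user, inferred, by = "chromosome",
                       suffix = c("", ".inferred")) |>
      filter(!is.na(.data$length.inferred), .data$length < .data$length.inferred)
    if (nrow(short) > 0) {
      warn(paste0("user-supplied length shorter than the largest feature position for chromosome(s): ",
                  paste(short$chromosome, collapse = ", ")))
    }
    inferred <- bind_rows(user, anti_join(inferred, user, by = "chromosome"))
  }
  inferred |>
    mutate(length = as.numeric(.data$length)) |>
    arrange(match(.data$chromosome, chrom_sort(.data$chromosome)))
}

# Normalise a lengths spec to tibble(chromosome, length).
as_chrom_lengths <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("chromosome", "length") %in% names(x))) {
      gt_schema_error("chromosome lengths need columns `chromosome` and `length`")
    }
    out <- tibble(chromosome = as.character(x$chromosome),
                  length = as.numeric(x$length))
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- tibble(chromosome = names(x), length = as.numeric(x))
  } else {
    gt_schema_error("chromosome lengths must be a data frame or named numeric vector")
  }
  if (any(is.na(out$length) | out$length <= 0)) {
    gt_value_error("chromosome lengths must be positive")
  }
  out
}

#' Per-chromosome display limits
#'
#' `as_chrom_limits()` normalises a limits specification — a named list of
#' `c(min, max)` base-pair windows, or a data frame with columns
#' `(chromosome, min, max)` — into the canonical tibble form. Chromosomes
#' absent from the limits are shown in full.
#'
#' `apply_chrom_limits()` crops feature tables to those windows: on a limited
#' chromosome only records whose plotted position lies inside the closed
#' interval `[min, max]` are kept (a record exactly on a boundary is
#' retained, mirroring the `>=` threshold convention); unlimited chromosomes
#' pass through untouched. A limit naming a chromosome absent from the data
#' is ignored with a warning.
#'
#' @param x A named list of length-2 numeric vectors, or a data frame
#'   `(chromosome, min, max)`, or `NULL` (no limits).
#' @param tables A feature table or (possibly nested) list of them.
#' @param limits A limits specification as accepted by `as_chrom_limits()`.
#' @return `as_chrom_limits()`: a tibble `(chromosome, min, max)`.
#'   `apply_chrom_limits()`: the cropped tables in the same shape as the
#'   input (single table in, single table out).
#' @examples
#' lim <- as_chrom_limits(list("5" = c(2e6, 2.5e6)))
#' tbl <- as_gwas_table(data.frame(
#'   chromosome = "5", position = c(2.1e6, 3e6), score = 5
#' ))
#' apply_chrom_limits(tbl, lim)
#' @export
as_chrom_limits <- function(x) {
  if (is.null(x)) return(tibble(chromosome = character(), min = numeric(), max = numeric()))
  if (is.data.frame(x)) {
    if (!all(c("chromosome", "min", "max") %in% names(x))) {
      gt_schema_error("chromosome limits need columns `chromosome`, `min`, `max`")
    }
    out <- tibble(chromosome = as.character(x$chromosome),
                  min = as.numeric(x$min), max = as.numeric(x$max))
  } else if (is.list(x)) {
    if (length(x) > 0 && (is.null(names(x)) || any(names(x) == ""))) {
      gt_schema_error("chromosome limits list must be named by chromosome")
    }
    bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 2, logical(1))]
    if (length(bad) > 0) {
      gt_schema_error(paste0("limits for chromosome(s) ", paste(bad, collapse = ", "),
                             " must be numeric c(min, max)"))
    }
    out <- tibble(chromosome = names(x),
                  min = unname(vapply(x, function(v) as.numeric(v[1]), numeric(1))),
                  max = unname(vapply(x, function(v) as.numeric(v[2]), numeric(1))))
  } else {
    gt_schema_error("chromosome limits must be a named list or a data frame")
  }
  if (any(duplicated(out$chromosome))) {
    gt_value_error("duplicate chromosome in limits")
  }
  if (any(is.na(out$min) | is.na(out$max) | out$min < 0 | out$max <= out$min)) {
    gt_value_error("chromosome limits require 0 <= min < max")
  }
  out
}

#' @rdname as_chrom_limits
#' @export
apply_chrom_limits <- function(tables, limits) {
  limits <- as_chrom_limits(limits)
  single <- is_feature_table(tables) || is.data.frame(tables)
  tbls <- flatten_tables(tables)
  present <- unique(unlist(purrr::map(tbls, ~ .x$chromosome)))
  unknown <- setdiff(limits$chromosome, present)
  if (length(unknown) > 0) {
    warn(paste0("chromosome limits ignore unknown chromosome(s): ",
                paste(unknown, collapse = ", ")))
    limits <- filter(limits, !.data$chromosome %in% unknown)
  }
  crop <- function(tb) {
    idx <- match(tb$chromosome, limits$chromosome)
    keep <- is.na(idx) |
      (tb$position >= limits$min[idx] & tb$position <= limits$max[idx])
    keep[is.na(keep)] <- FALSE
    tb[keep, , drop = FALSE]
  }
  out <- purrr::map(tbls, crop)
  if (single) out[[1]] else out
}

#' Drop chromosomes with no retained features
#'
#' After threshold filtering, chromosomes left with zero records across all
#' tracks can be removed from the figure so that only chromosomes with
#' significant features get a facet.
#'
#' @param tables A (possibly nested) list of threshold-filtered feature
#'   tables.
#' @param lengths A chromosome-lengths tibble, as from
#'   [compute_chrom_length()].
#' @return A list with elements `tables` (unchanged tables, flattened) and
#'   `lengths` (restricted to chromosomes holding at least one record).
#' @export
remove_empty_chromosomes <- function(tables, lengths) {
  tbls <- flatten_tables(tables)
  occupied <- unique(unlist(purrr::map(tbls, ~ unique(.x$chromosome))))
  list(tables = tbls,
       lengths = filter(lengths, .data$chromosome %in% occupied))
}

#' Read chromosome lengths / limits from files
#'
#' Lengths: a two-column CSV `(chromosome, length)`. Limits: either a JSON
#' object mapping chromosome id to a `[min, max]` array, or a three-column
#' CSV `(chromosome, min, max)`; the format is chosen by file extension.
#'
#' @param path Path to the file.
#' @return A tibble in the canonical lengths or limits form.
#' @export
read_chrom_lengths <- function(path) {
  if (!file.exists(path)) gt_io_error(paste0("file not found: ", path))
  as_chrom_lengths(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_chrom_lengths
#' @export
read_chrom_limits <- function(path) {
  if (!file.exists(path)) gt_io_error(paste0("file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_chrom_limits(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    as_chrom_limits(readr::read_csv(path, show_col_types = FALSE))
  }
}
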