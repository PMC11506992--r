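# Bridge for polyploid GWAS results organised by trait x genetic model.
#
# Polyploid GWAS tools score every marker separately under several genetic
# models (general, additive, simplex dominant for either allele, ...) and
# compute a significance threshold per trait x model combination. The bridge
# ingests those results from a language-neutral two-file CSV exchange:
#   scores:     trait, model, marker, chromosome, position, score
#   thresholds: trait, model, threshold
# and turns each trait x model combination into one GWAS track carrying its
# own significance threshold.

POLYGWAS_SCORE_COLS <- c("trait", "model", "marker", "chromosome", "position", "score")
POLYGWAS_THR_COLS <- c("trait", "model", "threshold")

#' Read exported polyploid GWAS results
#'
#' Reads the two-file CSV exchange described above and joins the per
#' trait-and-model significance thresholds onto the marker scores. Every
#' `(trait, model)` combination present in the scores must have a threshold;
#' markers may carry missing scores (they are dropped later, at filtering).
#'
#' @param scores_csv Path to the scores CSV (columns `trait`, `model`,
#'   `marker`, `chromosome`, `position`, `score`).
#' @param thresholds_csv Path to the thresholds CSV (columns `trait`,
#'   `model`, `threshold`).
#' @return A `polygwas_export` object: a list with tibbles `scores` and
#'   `thresholds`.
#' @export
read_polygwas_export <- function(scores_csv, thresholds_csv) {
  for (f in c(scores_csv, thresholds_csv)) {
    if (!file.exists(f)) gt_io_error(paste0("file not found: ", f))
  }
  scores <- readr::read_csv(scores_csv, show_col_types = FALSE)
  thresholds <- readr::read_csv(thresholds_csv, show_col_types = FALSE)
  miss_s <- setdiff(POLYGWAS_SCORE_COLS, names(scores))
  miss_t <- setdiff(POLYGWAS_THR_COLS, names(thresholds))
  if (length(miss_s) > 0 || length(miss_t) > 0) {
    gt_schema_error(paste0(
      "polyploid GWAS export is missing column(s): ",
      paste(c(miss_s, miss_t), collapse = ", ")
    ))
  }
  scores <- scores |>
    mutate(across(c("trait", "model", "marker", "chromosome"), as.character),
           position = as.numeric(.data$position),
           score = as.numeric(.data$score))
  thresholds <- thresholds |>
    mutate(across(c("trait", "model"), as.character),
           threshold = as.numeric(.data$threshold))

  dup <- scores |>
    dplyr::count(.data$trait, .data$model, .data$marker) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    gt_value_error(paste0(
      "duplicate (trait, model, marker) in scores: ",
      paste(head(paste(dup$trait, dup$model, dup$marker, sep = "/"), 5),
            collapse = ", ")
    ))
  }
  pairs <- distinct(scores, .data$trait, .data$model)
  unmatched <- anti_join(pairs, thresholds, by = c("trait", "model"))
  if (nrow(unmatched) > 0) {
    gt_schema_error(paste0(
      "no threshold for (trait, model) pair(s): ",
      paste(paste0("(", unmatched$trait, ", ", unmatched$model, ")"),
            collapse = ", ")
    ))
  }
  if (anyDuplicated(paste(thresholds$trait, thresholds$model))) {
    gt_value_error("duplicate (trait, model) in thresholds")
  }
  structure(list(scores = scores, thresholds = thresholds),
            class = "polygwas_export")
}

#' @export
print.polygwas_export <- function(x, ...) {
  pairs <- distinct(x$scores, .data$trait, .data$model)
  cat("<polygwas_export>: ", nrow(x$scores), " marker scores, ",
      dplyr::n_distinct(x$scores$trait), " trait(s) x ",
      dplyr::n_distinct(x$scores$model), " model(s) (",
      nrow(pairs), " tracks)\n", sep = "")
  invisible(x)
}

#' Turn a polyploid GWAS export into per-track GWAS tables
#'
#' One GWAS `feature_table` per retained `(trait, model)` combination,
#' labelled `"trait, model"`, each carrying its own significance threshold
#' (which [genome_tracks()] uses in place of the global GWAS threshold). By
#' default all combinations present in the export are returned; `traits`
#' and/or `models` select a subset.
#'
#' @param export A `polygwas_export` from [read_polygwas_export()].
#' @param traits,models Optional character vectors selecting traits /
#'   genetic models; an unknown value is an error listing the valid options.
#' @return A named list of GWAS `feature_table`s in trait-major order.
#' @export
to_gwas_tracks <- function(export, traits = NULL, models = NULL) {
  if (!inherits(export, "polygwas_export")) {
    gt_config_error("`export` must come from read_polygwas_export()")
  }
  scores <- export$scores
  check_subset <- function(requested, valid, what) {
    if (is.null(requested)) return(valid)
    requested <- as.character(requested)
    if (length(requested) == 0) {
      gt_value_error(paste0("empty ", what, " selection"))
    }
    unknown <- setdiff(requested, valid)
    if (length(unknown) > 0) {
      gt_value_error(paste0(
        "unknown ", what, "(s): ", paste(unknown, collapse = ", "),
        "; valid options: ", paste(valid, collapse = ", ")
      ))
    }
    requested
  }
  traits <- check_subset(traits, unique(scores$trait), "trait")
  models <- check_subset(models, unique(scores$model), "model")

  pairs <- distinct(scores, .data$trait, .data$model) |>
    filter(.data$trait %in% traits, .data$model %in% models) |>
    arrange(match(.data$trait, traits), match(.data$model, models))
  if (nrow(pairs) == 0) gt_value_error("selection retains no (trait, model) pair")

  tracks <- purrr::pmap(pairs, function(trait, model) {
    sub <- scores[scores$trait == trait & scores$model == model, ]
    thr <- export$thresholds$threshold[
      export$thresholds$trait == trait & export$thresholds$model == model]
    tb <- validate_table(
      select(sub, "chromosome", "position", "score", "marker"),
      kind = "gwas", label = paste0(trait, ", ", model)
    )
    attr(tb, "gt_threshold") <- thr
    tb
  })
  setNames(tracks, paste0(pairs$trait, ", ", pairs$model))
}

#' Genome-track figure straight from a polyploid GWAS export
#'
#' Convenience wrapper: reads or takes an export, builds one GWAS track per
#' `(trait, model)` combination filtered by its own threshold, and assembles
#' the figure specification.
#'
#' @param export A `polygwas_export`.
#' @inheritParams to_gwas_tracks
#' @inheritParams genome_tracks
#' @param ... Passed on to [genome_tracks()] (e.g. `candidates`,
#'   `chrom_limits`, `remove_empty_chrom`).
#' @return A `plot_spec`.
#' @export
polygwas_tracks <- function(export, traits = NULL, models = NULL, ...) {
  genome_tracks(gwas = to_gwas_tracks(export, traits = traits, models = models),
                ...)
}
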