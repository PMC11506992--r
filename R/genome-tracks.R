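# High-level pipeline: tables -> thresholds -> limits -> layout.

#' Build an integrated genome-track figure specification
#'
#' The main entry point: takes data frames of GWAS results, DE results,
#' candidate genes and custom genomic-feature tables, applies the
#' significance thresholds, and lays the retained features out as aligned
#' per-chromosome tracks. Each argument accepts a single data frame or a
#' list of them (one track per table); raw data frames are validated with
#' [validate_table()] on the way in. Chromosome lengths are inferred from
#' the *unfiltered* inputs (so facet widths do not depend on the thresholds)
#' unless supplied via `chrom_lengths`.
#'
#' Only markers and genes with a resolved score greater than or equal to the
#' relevant threshold — and, for DE genes, an absolute log2 fold-change of
#' at least `log2fc_thr` — are shown; features with missing scores or log2
#' fold-changes are excluded. Candidate genes are always shown. A GWAS table
#' carrying its own per-track threshold (as produced by the polyploid bridge,
#' [to_gwas_tracks()]) is filtered by that threshold instead of
#' `score_thr_gwas`.
#'
#' @param gwas,de,candidates,custom Input tables (data frame or list of
#'   data frames). Custom tables must carry an `aes_type` tag (see
#'   [as_custom_table()]) with a matching entry in `custom_aes`.
#' @param custom_aes Named list of [track_aes()] (or plain lists with those
#'   fields) keyed by `aes_type`.
#' @param score_thr_gwas,score_thr_de,score_thr_custom Minimum scores
#'   (-log10 p-value scale) for GWAS, DE and custom features. The reference
#'   points: a score of 1.3 corresponds to an adjusted p-value of 0.05 and a
#'   score of 4 to a p-value of 1e-4.
#' @param log2fc_thr Minimum absolute log2 fold-change for DE genes (0 = no
#'   fold-change filtering).
#' @param chrom_lengths Optional chromosome lengths (data frame
#'   `(chromosome, length)` or named vector); listed chromosomes override the
#'   inferred lengths.
#' @param chrom_limits Optional per-chromosome `[min, max]` display windows
#'   (named list or data frame; see [as_chrom_limits()]) to zoom into
#'   regions of interest.
#' @param remove_empty_chrom Drop chromosomes with no retained features from
#'   the figure.
#' @param colour_de_by_log2fc Colour DE points by log2 fold-change instead
#'   of score.
#' @return A `plot_spec`; render it with [autoplot()] or [render_spec()].
#' @examples
#' gwas <- data.frame(chromosome = rep(c("1", "2"), each = 3),
#'                    position = c(1e5, 5e5, 9e5, 2e5, 4e5, 8e5),
#'                    padj = c(1e-6, 0.5, 0.9, 1e-5, 0.2, 1e-7))
#' spec <- genome_tracks(gwas = gwas, score_thr_gwas = 4,
#'                       remove_empty_chrom = TRUE)
#' tidy(spec)
#' @export
genome_tracks <- function(gwas = NULL, de = NULL, candidates = NULL,
                          custom = NULL, custom_aes = list(),
                          score_thr_gwas = 4, score_thr_de = 1.3,
                          log2fc_thr = 0, score_thr_custom = 2,
                          chrom_lengths = NULL, chrom_limits = NULL,
                          remove_empty_chrom = FALSE,
                          colour_de_by_log2fc = FALSE) {
  coerce <- function(x, kind) {
    purrr::map(flatten_tables(x), function(tb) {
      if (is_feature_table(tb)) tb else validate_table(tb, kind)
    })
  }
  gwas_t <- coerce(gwas, "gwas")
  de_t <- coerce(de, "de")
  can_t <- coerce(candidates, "candidate")
  cus_t <- coerce(custom, "custom")
  all_t <- c(gwas_t, de_t, cus_t, can_t)
  if (length(all_t) == 0) {
    gt_config_error("supply at least one of `gwas`, `de`, `candidates`, `custom`")
  }

  lengths <- compute_chrom_length(all_t, lengths = chrom_lengths)

  filtered <- c(
    purrr::map(gwas_t, function(tb) {
      apply_threshold(tb, table_threshold(tb) %||% score_thr_gwas)
    }),
    purrr::map(de_t, apply_threshold, score_thr = score_thr_de,
               log2fc_thr = log2fc_thr),
    purrr::map(cus_t, apply_threshold, score_thr = score_thr_custom),
    can_t
  )

  limits_tb <- as_chrom_limits(chrom_limits)
  if (nrow(limits_tb) > 0) filtered <- apply_chrom_limits(filtered, limits_tb)
  if (isTRUE(remove_empty_chrom)) {
    trimmed <- remove_empty_chromosomes(filtered, lengths)
    filtered <- trimmed$tables
    lengths <- trimmed$lengths
  }

  build_plot_spec(filtered, lengths = lengths, limits = limits_tb,
                  custom_aes = custom_aes,
                  colour_de_by_log2fc = colour_de_by_log2fc)
}
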