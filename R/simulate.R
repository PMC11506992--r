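# Synthetic data generator: GWAS / DE / candidate / custom / polyploid
# export tables with planted significant regions.
#
# Null scores are -log10 of Uniform(0,1) p-values, so the fraction of null
# features with score >= t is exactly 10^(-t) in expectation — a closed form
# the calibration tests lean on. Planted regions add a fixed score offset
# (and a log2 fold-change boost for genes) to every feature they contain, so
# recovering the planted chromosomes after thresholding is a construction
# guarantee at large effect.

#' Configuration of the synthetic dataset
#'
#' Defaults emulate a compact autotetraploid crop setting: a genome of 12
#' chromosomes of 60 Mb, genotyped at `n_markers` markers, with expression
#' measured for `n_genes` genes, and two planted trait-associated regions of
#' 1 Mb half-width whose features get a score offset of 6 — far above the
#' usual significance thresholds (1.3 and 4), so planted signal survives
#' filtering while null features rarely do.
#'
#' @param n_chromosomes Number of chromosomes (ids `"1"`..`"12"`).
#' @param chrom_length Length of each chromosome in bp.
#' @param n_markers Number of GWAS markers (uniform over the genome).
#' @param n_genes Number of genes in the DE table.
#' @param n_candidates Number of candidate genes (the first ones sit at the
#'   planted-region centres; every fifth extra candidate has a missing name,
#'   exercising label suppression).
#' @param planted_regions Data frame `(chromosome, centre, half_width)` of
#'   planted significant regions; must lie within chromosome bounds.
#' @param effect Score offset added to features inside planted regions.
#' @param traits,models Trait and genetic-model names for the polyploid
#'   GWAS export (signal is planted for the first trait under the first two
#'   models only, so model comparisons have structure).
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 12, chrom_length = 60e6,
                       n_markers = 5000, n_genes = 2000, n_candidates = 12,
                       planted_regions = NULL, effect = 6,
                       traits = c("trait_A", "trait_B", "trait_C"),
                       models = c("general", "additive", "1-dom-ref", "1-dom-alt"),
                       seed = 1L) {
  planted_regions <- planted_regions %||% tibble(
    chromosome = c("3", "7"),
    centre = c(30e6, 10e6),
    half_width = c(1e6, 1e6)
  )
  planted_regions <- as_tibble(planted_regions)
  if (!all(c("chromosome", "centre", "half_width") %in% names(planted_regions))) {
    gt_config_error("`planted_regions` needs columns chromosome, centre, half_width")
  }
  planted_regions$chromosome <- as.character(planted_regions$chromosome)
  chroms <- as.character(seq_len(n_chromosomes))
  bad <- !planted_regions$chromosome %in% chroms |
    planted_regions$centre - planted_regions$half_width < 0 |
    planted_regions$centre + planted_regions$half_width > chrom_length
  if (any(bad)) {
    gt_config_error(paste0("planted region(s) outside chromosome bounds: row ",
                           paste(which(bad), collapse = ", ")))
  }
  structure(list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 n_markers = n_markers, n_genes = n_genes,
                 n_candidates = n_candidates,
                 planted_regions = planted_regions, effect = effect,
                 traits = traits, models = models, seed = as.integer(seed)),
            class = "sim_config")
}

in_planted <- function(chromosome, position, regions) {
  hit <- rep(FALSE, length(chromosome))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chromosome == regions$chromosome[i] &
                    abs(position - regions$centre[i]) <= regions$half_width[i])
  }
  hit
}

#' Simulate a full multi-track dataset
#'
#' Generates, deterministically for a given configuration, all the input
#' tables the package consumes: a GWAS table (`score` column), a DE table
#' (`padj` + `log2FoldChange`, exercising the p-value resolution path), a
#' candidate-gene table anchored at the planted-region centres, two custom
#' tracks (QTL-style point features and a dense methylation-difference-style
#' track, tagged `"qtl"` and `"dmr"`), and a polyploid GWAS export (scores +
#' per trait-and-model thresholds).
#'
#' Marker positions are uniform over the chromosomes; null scores are
#' \eqn{-\log_{10} U(0,1)}; features inside planted regions get the
#' configured score offset added (and genes a log2 fold-change pushed beyond
#' 1 in magnitude).
#'
#' @param config A [sim_config()].
#' @return A named list: `gwas`, `de`, `candidates`, `custom` (list of two
#'   tagged tables), `polygwas` (list `scores`, `thresholds`), and
#'   `config`. All tables are plain tibbles ready for [validate_table()] or
#'   CSV export.
#' @examples
#' sim <- simulate_dataset(sim_config(n_markers = 100, n_genes = 50))
#' head(sim$gwas)
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    gt_config_error("`config` must come from sim_config()")
  }
  withr::with_seed(config$seed, {
    chroms <- as.character(seq_len(config$n_chromosomes))
    regions <- config$planted_regions

    # GWAS markers.
    g_chr <- sample(chroms, config$n_markers, replace = TRUE)
    g_pos <- floor(runif(config$n_markers, 1, config$chrom_length + 1))
    g_score <- -log10(runif(config$n_markers))
    g_score <- g_score + config$effect * in_planted(g_chr, g_pos, regions)
    gwas <- tibble(chromosome = g_chr, position = g_pos, score = g_score)

    # DE genes: intervals, padj path, fold-changes.
    d_chr <- sample(chroms, config$n_genes, replace = TRUE)
    d_start <- floor(runif(config$n_genes, 1, config$chrom_length - 2e4))
    d_len <- floor(runif(config$n_genes, 1e3, 2e4))
    d_end <- d_start + d_len
    d_mid <- (d_start + d_end) / 2
    d_hit <- in_planted(d_chr, d_mid, regions)
    d_padj <- 10^(-(-log10(runif(config$n_genes)) + config$effect * d_hit))
    d_l2fc <- rnorm(config$n_genes, 0, 0.5)
    d_l2fc <- ifelse(d_hit, sign(d_l2fc + (d_l2fc == 0)) * (abs(d_l2fc) + 1.5), d_l2fc)
    de <- tibble(chromosome = d_chr, start = d_start, end = d_end,
                 padj = d_padj, log2FoldChange = d_l2fc)

    # Candidate genes: one at each planted centre, the rest scattered.
    n_extra <- max(config$n_candidates - nrow(regions), 0)
    c_chr <- c(regions$chromosome, sample(chroms, n_extra, replace = TRUE))
    c_mid <- c(regions$centre,
               floor(runif(n_extra, 2e4, config$chrom_length - 2e4)))
    c_half <- floor(runif(length(c_chr), 2e3, 1e4))
    c_name <- paste0("CAND_", seq_along(c_chr))
    if (n_extra > 0) {
      blank <- nrow(regions) + which(seq_len(n_extra) %% 5 == 0)
      c_name[blank] <- NA_character_
    }
    candidates <- tibble(chromosome = c_chr, start = c_mid - c_half,
                         end = c_mid + c_half, name = c_name)

    # Custom tracks: sparse named QTL peaks and a dense unnamed DMR track.
    qtl <- tibble(
      chromosome = c(regions$chromosome, sample(chroms, 3, replace = TRUE)),
      position = c(regions$centre,
                   floor(runif(3, 1, config$chrom_length + 1))),
      score = c(rep(config$effect + 2, nrow(regions)), -log10(runif(3))),
      name = c(paste0("QTL_", regions$chromosome, "_", seq_len(nrow(regions))),
               rep(NA_character_, 3))
    )
    n_dmr <- max(round(config$n_markers / 25), 20)
    m_chr <- sample(chroms, n_dmr, replace = TRUE)
    m_pos <- floor(runif(n_dmr, 1, config$chrom_length + 1))
    dmr <- tibble(chromosome = m_chr, position = m_pos,
                  score = -log10(runif(n_dmr)) +
                    config$effect * in_planted(m_chr, m_pos, regions))
    attr(qtl, "aes_type") <- "qtl"
    attr(dmr, "aes_type") <- "dmr"

    # Polyploid GWAS export on a shared marker map: signal planted for the
    # first trait under the first two genetic models only.
    p_chr <- sample(chroms, config$n_markers, replace = TRUE)
    p_pos <- floor(runif(config$n_markers, 1, config$chrom_length + 1))
    marker <- paste0("mrk_", seq_len(config$n_markers))
    combos <- tidyr::expand_grid(trait = config$traits, model = config$models)
    signal_models <- head(config$models, 2)
    pg_scores <- purrr::pmap(combos, function(trait, model) {
      s <- -log10(runif(config$n_markers))
      if (trait == config$traits[1] && model %in% signal_models) {
        s <- s + config$effect * in_planted(p_chr, p_pos, regions)
      }
      tibble(trait = trait, model = model, marker = marker,
             chromosome = p_chr, position = p_pos, score = s)
    }) |> bind_rows()
    pg_thr <- combos |>
      mutate(threshold = -log10(0.05 / config$n_markers))

    list(gwas = gwas, de = de, candidates = candidates,
         custom = list(qtl = qtl, dmr = dmr),
         polygwas = list(scores = pg_scores, thresholds = pg_thr),
         config = config)
  })
}

#' Default aesthetics for the simulated custom tracks
#'
#' Matching [track_aes()] entries for the `"qtl"` and `"dmr"` tags produced
#' by [simulate_dataset()].
#'
#' @return A named list of `track_aes`.
#' @export
sim_custom_aes <- function() {
  list(
    qtl = track_aes(y_label = "QTL regions", line_colour = "darkgoldenrod2",
                    point_shape = 18, show_name = TRUE, fill_scale = NULL),
    dmr = track_aes(y_label = "Diff. methylated regions",
                    line_colour = "orchid", point_shape = 24,
                    show_name = FALSE, fill_scale = "rocket")
  )
}

#' Write a simulated dataset as CSV fixtures
#'
#' Writes every table of a [simulate_dataset()] result in the CSV dialects
#' the package reads: `gwas.csv`, `de.csv`, `candidates.csv`,
#' `custom_<tag>.csv`, `polygwas_scores.csv`, `polygwas_thresholds.csv`, and
#' a `chrom_lengths.csv` with the true simulated chromosome lengths.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    gt_io_error(paste0("cannot create directory: ", dir))
  }
  w <- function(df, name) readr::write_csv(df, file.path(dir, name), na = "NA")
  w(sim$gwas, "gwas.csv")
  w(sim$de, "de.csv")
  w(sim$candidates, "candidates.csv")
  for (tag in names(sim$custom)) {
    w(sim$custom[[tag]], paste0("custom_", tag, ".csv"))
  }
  w(sim$polygwas$scores, "polygwas_scores.csv")
  w(sim$polygwas$thresholds, "polygwas_thresholds.csv")
  w(tibble(chromosome = as.character(seq_len(sim$config$n_chromosomes)),
           length = sim$config$chrom_length),
    "chrom_lengths.csv")
  invisible(dir)
}
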