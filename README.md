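# genotracks

Integrated chromosome-track visualisation of GWAS results, differential
expression results, candidate genes, and arbitrary genomic-feature tracks —
one static, genome-wide figure in which co-located evidence lines up.

## Who this is for

Geneticists and breeders who have, for one trait, some combination of:

* genome-wide association (GWAS) results — a significance score per marker,
* differential-expression (DE) results — a score and fold-change per gene,
* a hand-curated list of candidate genes from the literature,
* any other positionally mapped data (QTL regions, differentially
  methylated regions, accessibility peaks, ...),

and who want one figure showing *where along the genome these lines of
evidence agree*. Manhattan and volcano plots cannot be aligned against each
other, and circular multi-layer plots make positional comparison imprecise;
here every chromosome is a facet, position is the shared x axis, each input
table is a horizontal track, and each drawn feature casts a vertical guide
line across all tracks.

## The method

Features are selected by significance. Scores are on the
−log₁₀ p-value scale: a table may supply `score` directly or an adjusted
p-value `padj`, from which `score = −log₁₀(padj)` (so padj 0.05 ↔ score
≈ 1.3, p 10⁻⁴ ↔ score 4). DE tables likewise supply `log2FoldChange` or
positive `foldChange`. A feature is drawn iff

```
score ≥ score_thr        (GWAS, DE, custom tracks)
|log2FC| ≥ log2fc_thr    (DE tracks, additionally)
```

with closed comparisons, missing values excluded, and candidate genes
always shown. Interval features are plotted at the `(start + end)/2`
midpoint; facet ranges come from the per-chromosome maximum feature
position (or user-supplied lengths), optionally cropped to per-chromosome
`[min, max]` windows; chromosomes left empty after filtering can be
dropped. Polyploid GWAS output organised by trait × genetic model enters
through a CSV bridge, one track per combination, each filtered by its own
tool-calibrated threshold.

The layout is built as a declarative, renderer-independent `plot_spec`
(deterministic, JSON-serialisable), then rendered with ggplot2/cairo to
PNG, PDF or byte-reproducible SVG.

## Worked example

The package ships a synthetic-data generator emulating a compact
autotetraploid crop genome — 12 chromosomes × 60 Mb, 5,000 markers, 2,000
genes — with two planted trait-associated regions (chromosome 3 at 30 Mb,
chromosome 7 at 10 Mb) whose features get a score offset of 6:

```r
library(genotracks)

sim <- simulate_dataset(sim_config())
spec <- genome_tracks(
  gwas        = sim$gwas,        # chromosome, position, score
  de          = sim$de,          # chromosome, start, end, padj, log2FoldChange
  candidates  = sim$candidates,  # chromosome, start, end, name
  score_thr_gwas = 4,            # keep markers with p <= 1e-4
  score_thr_de   = 1.3,          # keep genes with padj <= 0.05
  log2fc_thr     = 0,            # no fold-change filtering
  remove_empty_chrom = TRUE
)
spec
#> <plot_spec>: 12 chromosome facet(s) x 3 track(s); 142 point(s), 10 label(s)
#> tracks (top to bottom): GWAS peaks | DE genes | Candidate genes
head(tidy(spec), 5)
#> # A tibble: 5 × 6
#>   chromosome track      kind         x value family
#>   <chr>      <chr>      <chr>    <dbl> <dbl> <chr>
#> 1 7          GWAS peaks gwas  10952658  6.31 gwas
#> 2 3          GWAS peaks gwas  29205140  6.40 gwas
#> 3 7          GWAS peaks gwas   9885378  6.19 gwas
#> 4 7          GWAS peaks gwas   9260376  7.05 gwas
#> 5 3          GWAS peaks gwas  29396726  6.51 gwas
```

142 features pass the thresholds (DE genes with padj ≤ 0.05 occur on every
chromosome, so all 12 facets stay); the planted markers on chromosomes 3
and 7 carry scores above 6 and stack above the co-located DE genes and
named candidate genes, with guide lines at matching positions. Write the
figure with:

```r
render_spec(spec, "figure.png")            # or .pdf / .svg
autoplot(spec)                             # as a ggplot object
```

Custom tracks take per-type aesthetics keyed by an `aes_type` tag:

```r
spec <- genome_tracks(
  gwas = sim$gwas, custom = sim$custom, score_thr_custom = 2,
  custom_aes = list(
    qtl = track_aes(y_label = "QTL regions", line_colour = "darkgoldenrod2",
                    point_shape = 18, show_name = TRUE),
    dmr = track_aes(y_label = "Diff. methylated regions",
                    line_colour = "orchid", point_shape = 24,
                    fill_scale = "rocket")
  )
)
```

And polyploid trait × model results come in from CSV:

```r
export <- read_polygwas_export("scores.csv", "thresholds.csv")
spec <- polygwas_tracks(export, traits = "trait_A",
                        models = c("general", "additive"),
                        remove_empty_chrom = TRUE,
                        chrom_limits = list("5" = c(2e6, 2.5e6)))
```

## Command line

A thin wrapper over the same functions, installed at `exec/genotracks`:

```sh
genotracks make-fixtures --out-dir data --seed 1
genotracks plot --gwas data/gwas.csv --de data/de.csv --can data/candidates.csv \
    --score-thr-gwas 4 --score-thr-de 1.3 --log2fc-thr 0 \
    --remove-empty-chrom --output figure.png
genotracks polygwas-plot --scores data/polygwas_scores.csv \
    --thresholds data/polygwas_thresholds.csv --traits trait_A --output pg.svg
genotracks validate --file data/gwas.csv --kind gwas
```

Logs go to stderr, the figure path to stdout; exit codes are 0 (success),
2 (schema/usage), 3 (nothing to plot), 4 (I/O).

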