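---
title: "Integrated genome-track figures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated genome-track figures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 8,
                      fig.height = 5, dpi = 72)
library(genotracks)
```

## The problem

A genome-wide association study (GWAS) yields one significance score per
genomic marker; a differential-expression (DE) analysis yields a score and a
fold-change per gene; prior literature contributes a hand-curated list of
candidate genes. The question a geneticist actually asks — *which genomic
regions are supported by more than one line of evidence?* — is poorly served
by the classic displays: a Manhattan plot and a volcano plot cannot be
aligned against each other, and circular multi-layer layouts make positional
comparison across layers imprecise.

genotracks answers it with a single static figure: one facet per chromosome,
physical position on the x axis, and one horizontal track per input table.
Only features passing user-set significance thresholds are drawn, coloured
by score, and every drawn feature emits a thin vertical guide line spanning
all tracks, so cross-track co-location is read directly off the figure. The
design extends to any feature type that maps to a genomic position (QTL
intervals, differentially methylated regions, chromatin accessibility
peaks) via custom tracks with user-controlled aesthetics, and to polyploid
GWAS output organised by trait × genetic model.

## Input model and normalisation

Four table kinds are accepted, each with mandatory, case-sensitive columns
(anything else is carried along untouched and ignored):

| kind      | mandatory columns                                            |
|-----------|--------------------------------------------------------------|
| gwas      | `chromosome`, `position`, `score` and/or `padj`               |
| de        | `chromosome`, `start`, `end`, `score` and/or `padj`, `log2FoldChange` and/or `foldChange` |
| candidate | `chromosome`, `start`, `end`, `name`                          |
| custom    | `chromosome`, `position`, `score` (+ an `aes_type` tag)       |

Normalisation derives three quantities:

* **score** — the significance scale is \(-\log_{10}\) of the (adjusted)
  p-value. A supplied `score` is used as-is and takes precedence over
  `padj`; otherwise `score = -log10(padj)`. Precedence is resolved per
  record, so a table may mix the two columns; a row with both uses its
  score. `padj` is validated to \([0, 1]\) rather than silently clamped.
* **log2 fold-change** — `log2FoldChange` takes precedence over
  `foldChange`; otherwise `log2(foldChange)` with `foldChange > 0`
  enforced.
* **position** — interval features are plotted at the fractional midpoint
  `(start + end) / 2`, not rounded: sub-bp plotting resolution is harmless
  and avoids a tie-break rule. A pre-existing `position` column on interval
  kinds is overwritten, since `start`/`end` are the mandatory source of
  truth.

Coordinates are treated as 1-based inclusive bp, the convention of typical
GWAS and annotation exports; position 0 is accepted, and the chromosome id
`"0"` is the usual bin for unplaced features. Chromosome ids are strings in
natural order: numeric-looking ids sort numerically (`"2"` before `"10"`),
all others lexicographically after them.

Two degenerate cases get explicit policies. `padj = 0` resolves to an
infinite score: the record always passes thresholds, and the colour scale
caps at the largest finite score of its family, so the strongest signals
are drawn at the top of the gradient instead of being dropped. Duplicate
markers are kept and both plotted — deduplication is an upstream decision
the plot should not make silently.

## Filtering semantics

`apply_threshold()` retains exactly the records with
`score >= score_thr` and, for DE tables, `|log2fc| >= log2fc_thr`. Points
of note:

* the comparison is **closed** (`>=`), so a feature exactly at the
  threshold is shown, and `log2fc_thr = 0` means no fold-change filtering;
* the fold-change threshold applies to the **absolute** log2 fold-change,
  retaining down-regulated genes symmetrically, as in standard volcano-plot
  practice;
* records with missing scores — or DE records missing a log2 fold-change,
  even when their score is present — are excluded;
* candidate tables carry no score and always pass through.

Filtering is idempotent at fixed thresholds, monotone in them, and returns
an unmodified, order-preserving subset of its input; the test suite asserts
all three as properties over simulated data.

Chromosome lengths (facet x-ranges) are the per-chromosome maximum of
positions and interval ends, computed on the **unfiltered** inputs so facet
widths do not shrink as thresholds tighten and figures remain comparable
across threshold choices. User-supplied lengths override inferred ones
entirely for the chromosomes they list; if an override is shorter than the
largest plotted position the package warns and honours it — the user has
claimed better knowledge of the assembly than the data. Per-chromosome
`[min, max]` display limits crop records to a closed window (boundary
features kept, mirroring the threshold convention) and narrow the facet
axis; `remove_empty_chromosomes()` optionally drops facets in which no
track retained a single record.

Custom tracks get their own `score_thr_custom` rather than sharing the GWAS
or DE threshold: custom data types (methylation scores, QTL LOD-like
scores) live on their own scales, and a separate knob avoids silently
coupling them.

## Layout

`build_plot_spec()` produces a *declarative, renderer-independent*
description of the figure — tibbles of facets, tracks, points, guide
lines, labels, and per-family colour scales — rather than a graphics
object. Two builds from equal inputs are `identical()`, and the spec
serialises to JSON (`plot_spec_json()`) for snapshot testing or external
renderers.

Design choices that were genuinely open:

* **Track order** is GWAS on top, then DE, then custom tracks, then
  candidate genes, following the order in which an analyst cites the
  evidence (association signal → expression support → prior knowledge).
  Within a kind, input order is preserved, so multi-trait comparisons stack
  the way the user listed them.
* **Guide lines** span the full facet height, one per plotted feature, in
  the originating track's line colour, drawn beneath the points. When a
  GWAS peak and a DE gene coincide, two lines overplot at the same x; we
  prefer honest overplotting to a merging rule that would hide which track
  produced the line.
* **Colour scales**: one sequential, perceptually-uniform gradient per
  score *family* (GWAS, DE, each custom `aes_type`), each with its own
  legend and a domain equal to the family's finite score range; candidate
  genes carry no score and use a single fixed colour. DE points can be
  recoloured by log2 fold-change with `colour_de_by_log2fc`.
* **Label placement** is a deterministic greedy search, not a
  force-directed repel: candidate positions are three stacked rows in the
  band above the track, scanned with increasing sideways displacement, and
  the first collision-free slot wins. Label boxes are sized from text
  length (one character ≈ 1.3% of the facet's axis range). A label with no
  free slot is thinned with a warning — the point stays, only the text
  goes. The placement is reproducible byte-for-byte, which a physical
  simulation would not be.

## Rendering

`autoplot()` materialises the spec with ggplot2: `facet_wrap` over
chromosomes with free x scales pinned to each chromosome's range by blank
sentinels, Mb tick labels, tracks at integer y positions. Point colours are
resolved *from the spec's palettes* into literal colours
(`scale_fill_identity`), which is what allows several independent colour
scales to coexist in one panel; per-family colourbar legends are rebuilt
from the scale definitions and composed beside the panel with cowplot. The
colourbars are drawn as vector rectangles rather than embedded rasters so
that repeated renders of one spec are byte-identical — `render_spec()`
writes PNG, PDF or SVG through the cairo devices, and the test suite
asserts SVG byte-identity and PNG pixel-identity across renders.

Default figure size is 11 inches wide by \((1 + 0.8 \cdot
n_\mathrm{tracks})\) inches per facet row (two facet columns by default):
height grows with track count so candidate labels stay legible, and with
facet rows so a 12-chromosome genome does not compress into unreadable
strips.

## Polyploid GWAS bridge

Association studies in autotetraploids score each marker under several
genetic models — `general`, `additive`, simplex dominant with the reference
or alternate allele — and compute a significance threshold per trait ×
model combination. The bridge ingests a two-file CSV exchange
(`trait, model, marker, chromosome, position, score` plus
`trait, model, threshold`; language-neutral, diffable, and trivially
exported from any GWAS tool with one `write.csv()` call) and builds one
GWAS track per combination, labelled `"trait, model"`. Each track carries
its *own* threshold, which the pipeline always uses in place of the global
GWAS threshold — a marker exceeding the global but not its track's
threshold is not shown, since the per-track threshold is the one the GWAS
tool calibrated. Every `(trait, model)` pair present in the scores must
have a threshold entry; duplicated `(trait, model, marker)` rows are
rejected rather than silently averaged.

## The synthetic-data generator

`simulate_dataset()` defines the conditions under which the package is
exercised and validated. Defaults emulate a compact autotetraploid crop
genome: 12 chromosomes of 60 Mb, 5,000 markers, 2,000 genes, and two
planted trait-associated regions (chromosome 3 at 30 Mb, chromosome 7 at
10 Mb, half-width 1 Mb) whose features receive a score offset of 6 — far
above the working thresholds of 1.3 and 4, so planted signal survives
filtering by construction. Null scores are \(-\log_{10} U(0,1)\), i.e.
scores of uniformly distributed p-values, chosen because the tail
probability \(P(\mathrm{score} \ge t) = 10^{-t}\) is available in closed
form and makes the calibration tests exact. The polyploid export plants
signal for the first trait under the first two genetic models only, giving
the model-comparison display real structure; per-pair thresholds are
Bonferroni-style, \(-\log_{10}(0.05 / n_\mathrm{markers})\).

What the generator does *not* emulate — and therefore what passing tests do
not demonstrate about real data: linkage disequilibrium (marker scores are
independent, so planted "peaks" lack the shoulders of real association
signals), allele-frequency structure, correlated expression, genomic
inflation, or batch effects. The generator validates the *visualisation
pipeline* (filtering semantics, layout invariants, recovery of planted
co-location), not any statistical property of GWAS itself.

One stochastic caveat is inherent to the null: with 5,000 markers at
threshold 4, the expected number of null exceedances is 0.5, so for some
seeds a chromosome outside the planted set survives
`remove_empty_chromosomes()`. That is correct behaviour of the null model,
not a recovery failure — the planted chromosomes are recovered by
construction at effect 6; the fixed-seed tests use the generator's default
seed.

## Problem sizes and tolerances

The test suite runs the full pipeline on 600 markers / 250 genes (fast
enough to iterate on), the null-tail calibration on 20,000 markers with a
three-binomial-standard-deviation band at \(t \in \{1, 2, 3\}\), and the
recovery check at the generator's default 5,000 markers. The analytic
transform checks use an absolute tolerance of \(10^{-5}\) on
\(-\log_{10}(0.05) = 1.30103\); CSV round-trips are compared at
double-precision read-back tolerance (`1e-9` relative).

## Known limitations

* One figure per call; no multi-page output, no interactive zoom or hover
  (a genome browser is the right tool there), no circular layout.
* Label thinning under extreme crowding favours early input rows; if every
  label matters, zoom with `chrom_limits` instead.
* Native serialised R objects from GWAS tools are not read directly; the
  documented CSV exchange is the supported path.
* PDF output embeds a creation timestamp (a property of the PDF format);
  byte-level determinism is guaranteed for SVG and pixel-level for PNG.
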