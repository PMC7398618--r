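# chromatlas

Integrative analysis of a developmental chromatin atlas, reimplemented as a
tested R package.

Chromatin state maps (ChromHMM-style segmentations from combinatorial
histone-modification patterns), ATAC-seq accessibility and RNA expression
profiled across fetal tissues and developmental stages support a family of
bespoke integrative analyses: choosing the number of chromatin states,
collapsing replicate segmentations into consensus maps, classifying genes as
Polycomb (PcG) targets, building a catalogue of developmentally accessible
chromatin regions (d-TACs) with temporal dynamics and TAD-constrained
correlation structure, linking enhancers to target genes by expression
correlation with chromosome-wide empirical nulls, clustering dynamic
enhancers with matched-background motif enrichment, calling super-enhancers
by the rank–signal tangent cutoff, and modelling in vivo validation rate as
a function of epigenomic rank. chromatlas packages each of those steps as a
documented, unit-tested function, and ships a synthetic-data generator with
recorded ground truth so the whole pipeline is exercised end-to-end without
any external downloads.

Who it is for: computational biologists who want to apply these analyses to
their own segmentations/peak/expression tables, and anyone who wants a
transparent, testable reference implementation of the methods.

At its core are a few well-defined statistics:

* state-number selection by the mean Between-SS/Total-SS ratio of k-means
  over pooled emission vectors (optimal k = smallest k reaching 95% of the
  ratio at k_max), and by median best-match emission correlations;
* per-TSS PcG classification: repressed ⇔ window ∩ state 13 ≠ ∅ and window
  ∩ {active states} = ∅;
* fold enrichment with Pearson χ² on a 2×2 table:
  `(a⁺/a)/(b⁺/b)` with `χ² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`;
* exact two-sided rate-ratio tests for differential accessibility, a
  moderated (empirical-Bayes) t for differential enhancer signal;
* Spearman-correlation linking with `z = (SCC − μ₀)/σ₀` and an empirical
  p = #{null ≥ observed}/N over the chromosome-wide null;
* a df-2 smoothing spline for validation rate vs rank.

## Worked example

Simulate a desk-scale world, recover the planted enhancer–gene links, and
test the printed PcG contingency table:

```r
library(chromatlas)

world <- gen_annotation_and_tads(n_genes = 400, seed = 101)
sim   <- gen_signal_grid(world, n_enhancers = 500, n_links = 300,
                         link_strength = 0.9, seed = 102)

maps <- lapply(1:2, function(r) {
  cols <- sim$h3k27ac$samples$replicate == r
  link_by_correlation(
    log2_with_zero_floor(grid_subset_samples(sim$h3k27ac, cols)),
    log2_with_zero_floor(grid_subset_samples(sim$expression, cols)),
    world$annotation)
})
final <- intersect_replicate_maps(maps[[1]], maps[[2]])
truth <- paste(sim$truth$true_links$enh_id, sim$truth$true_links$gene_id)
got   <- paste(final$enh_id, final$gene_id)
c(precision = mean(got %in% truth), recall = mean(truth %in% got))
#> precision    recall
#> 0.9803922 1.0000000

two_by_two_enrichment(150, 225, 349, 744)[c("fold", "p")]
#> $fold
#> [1] 1.421203
#> $p
#> [1] 2.034171e-07
```

The map intersected across replicate series recovers all 300 planted links
with 98% precision; the 2×2 statistic reproduces the published 1.42-fold
enrichment of PcG repression among Mendelian-disease transcription factors
at P ≈ 2 × 10⁻⁷.

## Layout

* `R/intervals.R`, `R/io.R`, `R/transforms.R`, `R/signal-grid.R` — interval
  algebra (BED convention, 0-based half-open), plain-text format IO, shared
  matrix transforms.
* `R/synthetic.R` — the generators and `simulate_atlas()`.
* `R/model-selection.R`, `R/states.R`, `R/pcg.R`, `R/dtac.R`,
  `R/enhancer-gene.R`, `R/dynamic-enhancers.R`, `R/validation.R` — the
  analysis modules.
* `inst/cli/chromatlas` — a small command-line front end
  (`simulate`, `select-states`, `pcg-enrich`).
* `vignettes/chromatlas-methods.Rmd` — models, parameters, numerical
  choices and known limitations.
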