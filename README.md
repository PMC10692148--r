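# ribotag

Cell-type-specific translatome analysis for paired Ribotag/TRAP RNA-seq.

## The problem

Ribotag (and TRAP) experiments immunoprecipitate epitope-tagged ribosomes
from a Cre-defined cell type, so that the recovered mRNAs approximate that
cell type's actively translated transcriptome. Each immunoprecipitated (IP)
library is paired with the bulk-tissue "total" RNA it was purified from.
Two quantities then describe every gene:

- **enrichment**, `log2FC(Total)` — the log2 ratio of a gene's abundance in
  the IP fraction over its paired total-RNA input; and
- **differential enrichment** across conditions,
  `Δlog2FC(OL/total) = log2FC(OL/total)_injury − log2FC(OL/total)_naive`,
  the fraction-by-condition interaction term.

After tissue injury, inflammatory cell types surge and their highly abundant
mRNAs co-purify with the tagged ribosomes. A transcript that looks "injury
upregulated" in the IP fraction may therefore be contamination. The package
implements a contamination-aware analysis for this design:

1. **Count model** — relative log expression (median-of-ratios) size
   factors, gene-wise negative-binomial GLMs
   (`counts ~ pair + fraction + condition + fraction:condition`, log link,
   size-factor offsets), Wald contrasts on the log2 scale, a full-vs-reduced
   likelihood-ratio test for the interaction, and Benjamini–Hochberg FDR.
   Gene-wise dispersions come from method-of-moments estimates, optionally
   (and by default inside `enrichment_profile()`) moderated by a
   Cox–Reid-adjusted likelihood shrunk towards a mean–dispersion trend.
2. **Two-arm filtration** of injury-regulated IP transcripts
   (`|log2FC(naive)| > 1`, `q < 0.05`): arm 1 keeps genes whose enrichment
   itself changed concordantly (`|Δlog2FC| > 1`, `q < 0.05`, sign matching
   the direction of regulation); arm 2 keeps constitutively cell-type-
   enriched genes (`log2FC(Total) > 1`, `q < 0.05` in naive and at the focal
   timepoint). Everything else is treated as probable contamination.
3. **Gene-set statistics** — marker-overlap diagnostics (representation
   factor `k/(n1·n2/N)` with the exact hypergeometric tail) and a
   resampling z-score for regulon ("operon") overlap against random sets of
   expressed genes, with analytic hypergeometric moments alongside.
4. **ΔΔCT qPCR quantification** — multi-reference normalization,
   fold-of-paired-total `2^(−ΔΔCt)`, and an exact two-sided Mann–Whitney
   test.
5. **A synthetic-data generator** that emulates the study design (4
   conditions × 3 pairs × 2 fractions, ~15–20k genes, cell-type mixtures
   with an inflammatory contaminant surge, ambient IP admixture, planted
   cell-type-specific effects) with full ground truth, so the whole chain is
   testable without any download.

## Worked example

```r
library(ribotag)

cfg <- run_config(
  simulation = sim_config_contamination(n_genes = 800, seed = 1),
  seed = 42, out_dir = "run1"
)
manifest <- run_pipeline(cfg)
writeLines(readLines(write_report(manifest)))
```

```
Ribotag translatome pipeline report
====================================

DEG counts (raw -> high confidence):
  dpi10    down    125 ->    24
  dpi10    up      209 ->   109
  dpi2     down    153 ->    68
  dpi2     up      209 ->   109
  dpi42    down    125 ->    30
  dpi42    up      136 ->    62

Marker over-representation flags: 3 of 48 panel cells
  raw_dpi10_up                 microglia    RF=3.83 q=1.37e-30
  raw_dpi2_up                  microglia    RF=3.83 q=1.37e-30
  raw_dpi42_up                 microglia    RF=2.82 q=2.13e-06

Top operon overlap z-scores:
  operon01     k= 48 null=14.0+/-2.45 z=13.88
  operon02     k= 48 null=13.2+/-3.33 z=10.46
  operon05     k= 15 null=12.9+/-2.18 z=0.96
  operon03     k= 16 null=13.8+/-2.62 z=0.84
  operon09     k= 15 null=13.7+/-4.00 z=0.32

Filtration vs planted truth:
  dpi2     retention=1.000 contaminant removal=1.000 (raw up: 209 true, 50 contaminant)
  dpi10    retention=1.000 contaminant removal=1.000 (raw up: 209 true, 50 contaminant)
  dpi42    retention=1.000 contaminant removal=1.000 (raw up: 136 true, 24 contaminant)

PCA: PC1 61.2%, PC2 27.4% of variance
```

Reading it: before filtration the upregulated DEG lists are contaminated —
microglia markers are over-represented (representation factor 3.8, i.e.
3.8× more overlap than chance) because the simulated injury makes microglial
mRNAs surge in the tissue and 25% of each IP library is ambient RNA. After
the two-arm filtration the flag disappears, every planted contaminant-driven
DEG is removed, and every genuinely OL-regulated DEG survives. The two
operons that were built to overlap the planted upregulated genes stand out
at z ≈ 14 and z ≈ 10 against 10 random expressed-gene sets; the unenriched
operons sit near z ≈ 1.

The same stages are exported individually (`filter_low_counts()`,
`estimate_size_factors()`, `estimate_dispersions()`, `fit_nb_glm()`,
`wald_contrast()`, `lrt_interaction()`, `enrichment_profile()`,
`call_sci_degs()`, `two_arm_filter()`, `acute_candidates()`,
`summarize_geneset()`, `hypergeom_overlap()`, `operon_zscore()`,
`marker_contamination_panel()`, `ddct_fold()`,
`mann_whitney_two_sided()`, …) and a thin shell wrapper lives at
`inst/scripts/ribotag-pipeline.R`. See the vignette
(`vignettes/translatome-analysis.Rmd`) for the model, its assumptions and
the numerical choices.

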