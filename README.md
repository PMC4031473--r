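# chipcoop

Integrative analysis of transcription-factor / chromatin-regulator ChIP-seq
peak sets with knockdown expression data, in R.

Many chromatin regulators bind thousands of promoters, and binding alone
does not say whether a factor activates or represses its targets. `chipcoop`
is for analysts who have (a) called peaks for one or more factors
(narrowPeak/BED), (b) a gene annotation (refFlat/BED12), and optionally
(c) expression measured after knocking the primary factor down. It answers
two questions:

1. **Co-occupancy** — which genes does each factor target (peak summit
   within a window of a TSS, 3 kb by default), how strongly do the target
   sets overlap (upper-tail hypergeometric p over a gene universe), and
   which of the primary factor's peaks are co-bound ("ensemble") vs not
   ("solo")?
2. **Regulatory direction** — after knockdown, are the genes that *decrease*
   (candidate activated targets) bound closer to the factor's sites than
   background genes? The test is a one-sided Kolmogorov–Smirnov comparison
   of peak-to-TSS distance ECDFs:

   D⁺ = supₓ [F_set(x) − F_bg(x)],  p = exp(−2·n_eff·D⁺²),  n_eff = mn/(m+n)

   applied separately to the decreased-after-knockdown and
   increased-after-knockdown gene sets; evidence for both means the factor
   both activates and represses. A regulatory-potential score
   RP = Σᵢ exp(−(0.5 + 4dᵢ/Δ)) ranks genes by promoter-proximal binding,
   and known-motif (PWM) enrichment in 600-bp summit windows against
   seeded random windows checks for a partner factor's sequence element.

Differential expression follows the standard microarray route: *half*
background correction, quantile normalization between arrays (both via
limma), pooled-variance Student t-tests per gene and Benjamini–Hochberg
adjustment.

A seeded synthetic-data generator (`generate_synthetic()`) builds a toy
genome, annotation, multi-factor peak sets with a controlled co-binding
fraction, coverage tracks, a knockdown expression matrix with
distance-decaying planted effects, and planted motifs — with full ground
truth — so every stage is testable without any external download.

## Worked example

Generate a synthetic dual-role factor study and run the whole pipeline:

```r
library(chipcoop)

ds <- generate_synthetic(synthetic_config(seed = 1))
dir <- tempfile(); write_synthetic(ds, dir)

cfg <- pipeline_config(de_alpha = 0.05, expression_threshold = 6,
                       top_n = 100, rng_seed = 2)
report <- run_pipeline(list(
  peaks      = c(A = file.path(dir, "peaks_A.narrowPeak"),
                 B = file.path(dir, "peaks_B.narrowPeak"),
                 C = file.path(dir, "peaks_C.narrowPeak")),
  genes      = file.path(dir, "genes.refflat"),
  expression = file.path(dir, "expression.tsv"),
  conditions = file.path(dir, "conditions.yaml"),
  coverage   = c(A = file.path(dir, "coverage_A.bedGraph")),
  genome     = file.path(dir, "genome.fa")), cfg)
report
```

```
run_report
  genes: 500; expressed: 490
  factor A: 300 peaks (284 after fold filter), 168 target genes
  factor B: 300 peaks (284 after fold filter), 160 target genes
  factor C: 300 peaks (288 after fold filter), 172 target genes
  target overlap A vs B: hypergeometric p = 9.4e-07
  partition: 80 ensemble / 204 solo
  DE: 39 decreased, 39 increased (alpha 0.05)
  KS decreased-set p = 3.59e-18
  KS increased-set p = 1.69e-19
  activator evidence: TRUE; repressor evidence: TRUE
  motif enrichment: OR = 144.53, p = 5.83e-26
```

Reading it: factor A's filtered peaks hit 168 of 500 genes; its target set
overlaps factor B's far beyond chance (hypergeometric p ≈ 9e-07); 80 of
its peaks are co-bound by B. After knockdown, 39 genes decreased and 39
increased (BH-adjusted p < 0.05); **both** sets sit dramatically closer to
A's binding sites than background genes (one-sided KS p ≈ 4e-18 and
2e-19), so A shows activator *and* repressor evidence — exactly the
dual-role structure the generator planted. The REST-consensus motif is
strongly enriched in ensemble-peak windows versus random windows
(Fisher OR ≈ 145).

Individual stages are plain functions if you prefer to compose them
yourself: `read_peaks()`, `assign_targets()`, `partition_solo_ensemble()`,
`target_overlap_significance()`, `profile_matrix()`,
`run_differential_expression()`, `nearest_peak_distance()`,
`ks_one_sided()`, `regulatory_potential()`, `motif_enrichment_test()`.

## Vignette

`vignettes/chipcoop-methods.Rmd` documents the statistical model, every
tunable parameter with its default and rationale, the synthetic study
design (including what it does and does not emulate), and the numerical
choices (KS tail accuracy, tie-breaking, degenerate cases).
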