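---
title: "Methods: co-occupancy analysis and activator/repressor inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy analysis and activator/repressor inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcoop)
```

# The analysis

`chipcoop` integrates ChIP-seq peak sets for several DNA-binding factors
with expression data measured after knocking one of them down, to answer
two questions: *do the factors co-occupy promoters*, and *does the
knocked-down factor activate or repress the genes it binds*?

The workflow mirrors how such studies are done at full scale:

1. **Target assignment.** A gene is a target of a factor when at least one
   peak summit lies within a window (default 3 kb) of one of its
   transcripts' TSSs. The distance is summit-to-TSS, signed in gene
   orientation, with an inclusive boundary. The summit is used rather than
   the whole peak interval because it is the best point estimate of the
   binding position; the window rule itself is configurable.
2. **Co-occupancy.** Peaks pass a fold-enrichment filter (strictly greater
   than 10 by default, the MACS fold-enrichment field). Target-set overlap
   between factors is scored with the upper-tail hypergeometric
   probability against a gene universe; the primary factor's peaks are
   partitioned into *ensemble* (overlapping a partner peak by at least
   1 bp) and *solo* groups, with a seeded random solo subsample to match
   the ensemble group size for profile comparisons.
3. **Signal profiles.** Coverage is binned around anchors (TSSs or peak
   summits) into equal-width bins over a 6-kb window; minus-strand anchors
   are flipped so bins read 5' to 3'. The default is 120 bins (50 bp each):
   fine enough to see promoter shape, coarse enough to be stable at desk
   scale. Heatmap rows are ordered by mean signal in the central ±500 bp;
   ties break lexicographically so ordering is reproducible. The expression
   sidebar uses a valid-mode sliding mean with window 100 and step 1; a
   step option exists because a "step" of 100 could equally denote stride,
   but the window-100/stride-1 reading produces the smooth trend such
   figures show.
4. **Differential expression.** Intensities are background-corrected with
   the *half* rule (subtract, floor at 0.5, via limma), quantile-normalized
   between arrays (limma), optionally collapsed probe-to-gene by median,
   then tested per gene with a pooled-variance two-sample Student t-test
   and adjusted by Benjamini–Hochberg (the field default where no procedure
   is otherwise specified; Bonferroni is available). Genes with adjusted
   p below alpha split into *decreased after knockdown* and *increased
   after knockdown* sets by the sign of the knockdown-minus-control mean
   difference. The deliberately clunky labels avoid the ambiguity of
   "up-/down-regulated", which flips meaning depending on whether it
   describes the gene or the factor.
5. **Activator/repressor inference.** For every gene the distance from its
   TSS to the nearest peak summit of the knocked-down factor is computed
   (genes with no peak on their chromosome carry an `Inf` sentinel and are
   excluded from ECDFs rather than imputed, which would distort the tail).
   Each DE set's distance ECDF is compared against background genes
   (expressed genes outside both DE sets, by default) with a one-sided
   Kolmogorov–Smirnov test: `D+ = sup_x [F_set(x) - F_bg(x)]`, positive
   when the set sits *closer* to the binding sites, with asymptotic
   p-value `exp(-2 n_eff D+^2)`, `n_eff = m n/(m+n)`. Evidence that the
   decreased set is closer supports an activator role; the increased set,
   a repressor role; both can hold. A permutation p-value is available for
   small samples.
6. **Regulatory potential and top targets.** Each gene's regulatory
   potential is `RP = sum_i exp(-(0.5 + 4 d_i/Delta))` over peaks within a
   100-kb horizon, with decay scale `Delta = 100 kb`. Only monotone decay
   and additivity matter for how RP is used (ranking); the exponential
   form is smooth, additive, and config-exposed. Top regulated targets per
   direction combine the DE-significance rank and the RP rank by rank
   product, with gene-id tie-breaks for determinism.
7. **Motif enrichment.** 600-bp summit-centred windows of ensemble peaks
   are scanned with a PWM (log2-odds in bits; `N` bases contribute 0; both
   strands; hit threshold 80% of the maximum achievable score, the common
   practice default) and compared against an equal number of seeded random
   same-width windows with a one-sided Fisher exact test (Haldane-corrected
   odds ratio when a cell is zero). Only known-motif enrichment is
   implemented — de novo discovery is a different tool's job. The bundled
   REST/NRSE and E2F1 matrices are consensus-derived synthetic PWMs (85%
   probability on the consensus base), clearly labelled as such; real
   JASPAR matrices can be supplied as files.

## Coordinate convention

Internally everything lives in `GenomicRanges` containers, i.e. 1-based
closed intervals — the R/Bioconductor convention. All on-disk formats
(BED, narrowPeak, bedGraph, refFlat) are 0-based half-open and are
converted on read and back on write, so round-trips are exact and all
distances and window-membership decisions are identical to what a 0-based
implementation would produce. Chromosome names match by exact string
equality; no "chr"-prefix aliasing is performed, because silent aliasing
hides data bugs.

# The synthetic study

Because raw ChIP-seq and microarray data are not part of the package, a
seeded generator (`generate_synthetic()`) builds complete inputs with
known ground truth. Its defaults are the study conditions all stochastic
tests run under:

| parameter | default | meaning |
|---|---|---|
| genome | 2 chromosomes × 5 Mb | toy genome, desk scale |
| genes | 500, ≥ 10 kb spacing | 3-exon models with UTRs, random strand |
| peaks/factor | 300, width 400 bp | factor A knocked down; B partner; C independent |
| promoter_binding_fraction | 0.6 | summits placed within ±3 kb of a TSS, distance ~ truncated Normal(0, 1.2 kb) |
| cobinding_fraction | 0.3 | exact fraction of A peaks with a B summit within ±100 bp |
| activator_effect / repressor_effect | 2.0 / 2.0 log2 | knockdown shift at distance 0, decaying `exp(-d/2 kb)` |
| expression_noise_sd | 0.5 | per-sample iid Gaussian, log2 scale |
| samples | 4 control + 4 knockdown | |
| motif plant rates | 0.8 fg / 0.1 bg | REST consensus under ensemble summits vs random windows |

Fractions are *controlled*: `round(fraction * n)` items are chosen, so the
planted structure is exact rather than merely expected. Placement rules
guarantee that the only physical overlaps between A and B peaks are the
planted co-bound pairs (independent peaks keep ≥ 1 kb from the other
factor's summits), which is why ensemble/solo classification accuracy is
exactly 1 on unfiltered peaks — a construction guarantee the tests assert,
not an empirical achievement. Coverage uses triangular kernels (half-width
300 bp, height = fold enrichment) rather than read-level simulation: the
profile module consumes only coverage, and a discrete triangle has an
exactly known mass (`300 × fold`), which makes conservation testable to
tight tolerance. Expression is generated directly on the log2 scale so
effect sizes stay interpretable; the background-correction stage is tested
on its own fixtures instead.

What the generator does *not* emulate: read-count noise, fragment-length
effects, probe-level microarray artifacts, correlated expression between
genes, GC or mappability bias, and enhancer-mediated long-range
regulation. Passing tests therefore demonstrate that the statistical
machinery recovers planted structure under clean assumptions, not that the
pipeline is robust to every artifact of real data.

## Why the desk-scale DE alpha is 0.05

The full-scale default threshold for differential expression is adjusted
p < 0.001. With 4 + 4 samples, however, a pooled-variance t-test has 6
degrees of freedom and its two-sided p at the maximum planted effect
(2.0 log2 units against sd 0.5) is about 1.3e-3 — an adjusted-p < 0.001
set is empty *by arithmetic*, regardless of biology. The synthetic
recovery study therefore defines its DE sets at adjusted p < 0.05. This is
a power calculation made from the study design, not a tuning decision; the
full-scale default in `pipeline_config()` remains 0.001.

## Null calibration and recovery

Under the null (no planted effects, noise sd 1), per-gene t-test p-values
are exactly uniform, so the count of raw p < 0.001 over 50 seeds × 500
genes is binomial with mean 25 — the calibration test asserts the count
inside the central 99.9% binomial interval, and that no activator or
repressor label is claimed in ≥ 90% of replicates. With the planted
activator (effect 2.0, decay 2 kb), the decreased set concentrates at
small TSS distances while background genes sit tens of kb from the nearest
peak, so the one-sided KS p falls far below 0.01; the recovery test
requires this in ≥ 95% of 100 seeded replicates.

## Numerical notes

- The one-sided KS asymptotic tail `exp(-2 n_eff D+^2)` is the leading
  term of the exact distribution; at n = 10–30 it deviates from the exact
  tail by up to ~0.02 in absolute probability (equal-n lattice formula:
  n = 10, d = 0.3 gives exact 0.4196 vs asymptotic 0.4066). The test
  comparing it against a 10,000-permutation null therefore allows 3
  Monte-Carlo standard deviations plus 0.02.
- `D+` is evaluated over the pooled sample points; both ECDFs are
  right-continuous step functions, so the supremum is attained there.
- Degenerate t-tests (zero pooled variance) return t = 0, p = 1 when the
  means agree and p = 0 otherwise, keeping the DE caller total.
- Quantile normalization of a single row returns the row mean in every
  column (the one-quantile limit).
- All random choices (solo subsampling, background windows, the entire
  generator) run under `withr::with_seed`, so the global RNG state is
  never disturbed and identical seeds give byte-identical outputs.

## Problem sizes used by the test-suite and acceptance script

Module tests run on miniature genomes (2 × 400 kb, 20–40 genes/peaks);
the stochastic studies use the full default generator (500 genes, 300
peaks/factor) with 50 null and 100 recovery replicates; the acceptance
script performs one complete pipeline run at defaults plus a 20-replicate
recovery study. These sizes were chosen so the whole validation cycle
completes in minutes on a laptop while keeping every statistical check at
meaningful power.

# Known limitations

- The hypergeometric universe for target-set overlap defaults to all
  annotated genes; restricting to expressed genes is supported but the
  choice materially changes p-values and should be reported alongside
  results.
- Target assignment ignores enhancer-gene looping; genes regulated only
  through distal elements are invisible to the 3-kb window rule.
- The KS-based direction call detects *proximity enrichment* of responsive
  genes, not causality; a confounded factor co-binding with the true
  regulator inherits its signal.
- PWM scanning with a fixed 80% threshold trades sensitivity for
  precision; marginal motif matches are not counted.
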