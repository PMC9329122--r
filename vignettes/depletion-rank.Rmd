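---
title: "Depletion Rank: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depletion Rank: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscan)
```

## The model

Purifying selection removes deleterious alleles, so constrained sequence
segregates fewer variants than mutationally equivalent neutral sequence.
`drscan` turns that observation into a per-window score in three steps.

**Mutation opportunities and context rates.** Mutation rate in the germline
depends strongly on local sequence context — most dramatically the roughly
order-of-magnitude elevation of C>T transitions at methylated CpG
dinucleotides. The package models context with the 7-bp window centred on
each base (a heptamer). Strand symmetry is imposed by mapping every site
onto its canonical heptamer, the orientation whose central base is A or C;
a site and its reverse complement therefore share one context and
substitutions collapse into seven classes: T>A, T>C, T>G, C>A, C>G, and C>T
split into CpG>TpG and C>T(non-CpG). For every canonical heptamer we count
its qualifying occurrences H (full 7-mer inside the chromosome, N-free,
central base reliable) and the number of those occurrences carrying at
least one qualifying SNV at the centre, S. The ratio S/H is the empirical
per-site variant rate of that context *in this cohort at this sample size*
— it is not a per-generation mutation rate, and it already reflects the
cohort's saturation level, which is what makes it the right yardstick for
"how many variants should this window have".

**Window scoring.** Windows of 500 bp are laid every 50 bp along each
chromosome, anchored at coordinate 0 (the method gives no reason to prefer
another phase; the 10× overlap makes the choice immaterial in practice).
A window is retained only if at least 450 of its bases are reliable, where
reliable means per-base coverage statistics across individuals of mean ≥ 20
and s.d. ≤ 12 (inclusive on both boundaries, as the thresholds are stated
as "at least"/"at most"; positions without coverage data count as depth 0).
For each retained window, `O` counts qualifying variant records at reliable
bases and `E` sums the context rate over the window's qualifying centres.
The depletion score is `(O − E)/√E`, i.e. a Poisson-standardized residual;
windows whose variants average a quality score below 0.85 are excluded, as
are windows with `E = 0` (unscorable rather than infinitely depleted).

**Ranking.** Scores are only comparable after standardization, and their
distribution is skewed, so the final statistic is a rank: the window with
the *i*-th lowest score of *n* gets `DR = 100(i − 0.5)/n`. DR is a
percentile in (0, 100); its mean is exactly 50, and it is invariant under
any strictly monotone transform of the scores. Exactly tied scores receive
the mean of their positional DRs, which keeps the assignment deterministic
and permutation-invariant without perturbing the mean beyond rounding.

## Partitioning by C>G-enriched regions

Regional mutational processes (notably maternal-age-associated C>G
clusters) make one genome-wide rate table too coarse. When a C>G-enriched
region track is supplied, H and S are tallied separately inside and outside
those regions and each position draws its rate from its own partition. A
heptamer unseen in one partition falls back to the pooled rate across
partitions; a heptamer unseen everywhere contributes 0 to E (the count of
such positions is recorded). With rates fitted and evaluated on the same
data, the per-partition sums of E over the non-overlapping fitting tiling
equal the per-partition sums of S identically — the package tests enforce
this to 10⁻⁶ relative.

One design point deserves a note: the rate-fitting tiling. Rates are fitted
on the non-overlapping subset of the window grid, which the package takes
to be the partition of each chromosome into consecutive 500-bp chunks
including the trailing partial chunk — every qualifying centre counts
exactly once and no window-level filter applies to the tally. This is the
only convention that remains well defined for chromosomes shorter than one
window.

## Quality scores

Variants carry a caller-assigned probability of being a true positive
(`aa_score`). Two thresholds appear: a per-variant inclusion threshold
(`aa_score > 0.5`, strict) applied when tallying S and O, and a per-window
mean-quality filter (mean ≥ 0.85). Zero-variant windows pass the mean
filter: absence of variants is the signal being measured, not evidence of
bad calling. Both thresholds are arguments, not constants.

## Sites versus alleles

S counts *sites* with at least one SNV, so rates are probabilities in
[0, 1] and admit a clean interpretation as the chance that a context
carries any variant. O counts variant *records* (alt alleles) by default,
matching how variant totals per window are usually tabulated;
`count = "sites"` mirrors the S
definition instead. The conservation identity ΣE = ΣS holds exactly in
site mode and remains a very close approximation in allele mode because
multi-allelic sites are rare at simulated rates.

## Methylation calling

Germline methylation is called from bisulfite counts of two testis-like and
three ovary-like samples. Methylation is treated as strand-symmetric:
counts from both strands of a CpG pool together, per tissue, before the
ratio is formed. A CpG is methylated when the ratio is at least 0.7 in both
tissues and pooled depth reaches the tissue threshold. The depth threshold
combines a fixed per-tissue floor with a per-sample component as
`threshold = max(fixed floor, 10 × n_samples)`; with 2 and 3 samples the
floors (20, 30) and the 10×n branch coincide, so the two readings cannot be
distinguished at the reference design — both are selectable
(`depth_rule`). Each methylated dinucleotide contributes exactly two
CpG>TpG opportunities, one per strand.

## Statistical conventions

* Saturation CIs use the normal approximation to the binomial, treating
  each site as independent, clipped to [0, 1]. Calibration is checked by
  simulation (coverage 95% ± 2% over 1,000 binomial draws).
* Tail-enrichment folds are tested by a bootstrap over windows, 2,500
  replicates by default, so the smallest attainable two-sided P is 0.0004;
  the replicate count is an argument. The resampling unit is the window,
  which ignores residual correlation between overlapping windows — use
  non-overlapping windows (step = size) when calibrated nulls matter.
* Odds ratios use the Wald CI with the Haldane–Anscombe 0.5 correction when
  any cell is empty; tables with an empty margin are reported missing.
* Gene-level aggregation of DR is the unweighted mean over windows
  overlapping a gene's exons (median selectable); distance profiles treat
  genes, not windows, as the independent unit for CIs.
* Published-style percentages are rounded half-up at the printed precision
  (2 decimals for overlap tables, 1 for recurrence); machine outputs retain
  full precision. Displayed floats in TSVs use `%.6g`.
* Dataset overlap assigns each variant one annotation by the fixed
  precedence coding > splice > 5′ UTR > 3′ UTR > proximal > intergenic,
  after left-align/trim normalization of alleles; percentages are relative
  to the union of the two sets.

## The synthetic-data generator

The generators exist so every operation above is testable with known truth.
They emulate the *statistical shape* of cohort WGS data:

* iid background sequence at a target GC fraction (default 0.41) with
  CpG islands (default 1% of the genome, 300 bp) carrying elevated CpG
  density;
* independent per-site variant occurrence at `base_mutation_rate`
  (default 0.02 — a desk-scale stand-in for the per-site variant density
  of a large cohort, *not* a human mutation rate), multiplied by 10 at CpG
  dinucleotide bases and by the planted constraint multiplier in [0, 1];
* alternate alleles drawn with transition probability 2/3 (a 2:1
  transition:transversion draw before saturation effects);
* carrier counts from a discretized 1/k spectrum truncated at
  `n_individuals` (default 1,000), reproducing the singleton excess of
  neutral site-frequency spectra;
* quality scores from Beta(9, 1), putting ~98% of variants above the 0.5
  threshold;
* coverage statistics fluctuating around mean 30 / s.d. 6 with near-zero
  means inside dropout patches;
* bisulfite counts with per-CpG true methylation ratios near 0.9
  (methylated, default 80% of CpGs) or 0.1, Poisson read depth per strand
  (default mean 15);
* gene annotations on a regular grid, and gene LOEUF/GERP scores with a
  configurable correlation (default 0.5).

All randomness flows from one integer seed through fixed per-generator
substreams: identical configurations give byte-identical outputs, and the
generators can be called in any order.

What the simulator does **not** model: linkage disequilibrium and haplotype
structure, demography, mapping artefacts, regional mutation-rate variation
beyond the CpG/constraint/partition multipliers, indel processes, and
read-level errors. Passing tests on synthetic data therefore demonstrate
correctness of the estimator and its implementation, not robustness to the
full messiness of real cohort data.

## Problem sizes in the test-suite experiments

The validation experiments use sizes chosen to make their statistical
assertions sharp while remaining quick to run: oracle-equivalence checks
use 100 genomes of 0.8–4 kb against literal per-position string scans;
planted-constraint recovery uses one 5-Mb chromosome with 5% of its length
at multiplier 0.5 (about 4,200 fully constrained windows of ~100,000), on
which at least 80% of constrained windows must fall in the bottom DR
quartile; calibration uses 1,000 binomial replicates and 100 null
enrichment runs of 500 windows each.

## Known limitations

* Rates are cohort-saturation-bound: S/H from a small cohort is not
  transferable to a cohort of a different size, and the package makes no
  attempt to convert between them. Cohort-restricted DR (`cohort_dr()`)
  refits rates within the cohort for exactly this reason.
* Windows with E = 0 (e.g. fully masked or all-N contexts) are dropped, so
  DR tracks need not tile the genome.
* The 500-bp/50-bp geometry means neighbouring windows share 90% of their
  sequence; DR values of nearby windows are strongly dependent, and any
  downstream test that assumes independent windows should thin to the
  non-overlapping subset.
* chrX is ranked together with the autosomes using jointly fitted rates;
  saturation reports split chrX, but DR does not by default.
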