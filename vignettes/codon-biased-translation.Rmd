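---
title: "Analysing codon-biased translation with codonbias"
author: "codonbias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing codon-biased translation with codonbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

# The scientific question

Wobble-position tRNA modifications tune how efficiently specific codons
are decoded. When such a modification is lost — the motivating case is a
yeast strain lacking the methyltransferase that completes mcm⁵U/mcm⁵s²U
on the tRNAs reading AGA and GAA — translation of transcripts that rely
heavily on those codons can become selectively impaired. The signature
one expects, and that this package is built to detect, has three parts:

1. proteins from genes *enriched* in the affected codons are
   preferentially down-regulated in the mutant;
2. the affected codons occur in *physical clusters* (runs) along those
   transcripts more often than their composition alone predicts; and
3. transcripts with enhanced ribosome density (pausing) in
   modification-deficient cells overlap with both of the above.

Each part has obvious confounds — mRNA-level changes, protein abundance,
co-enrichment of other codons, overall codon content — and most of the
package's machinery exists to control for them.

# Models and procedures

## Gene-specific codon enrichment

For gene *g* with *n* sense codons, of which *k* are the focal codon, and
a genome pool with *K* of *N* codons focal, enrichment is modelled by the
hypergeometric distribution: drawing *n* codons without replacement from
the pool. We report

$$Z = \frac{k - nK/N}{\sqrt{n \frac{K}{N}\left(1-\frac{K}{N}\right)\frac{N-n}{N-1}}}$$

together with the exact inclusive tails $P(X \ge k)$ and $P(X \le k)$.
Calls use the exact tails at strict p < 0.01; the Z-score, whose
denominator is the finite-population-corrected hypergeometric standard
deviation, is kept for ranking and heat-map-style visualisation. Where
the variance degenerates (n = N, K = 0 or K = N) Z is NA but tails are
still valid. Two modelling choices deserve note:

* **The focal gene stays in the pool.** At genome scale (millions of
  codons) its contribution to K/N is negligible, and a gene-independent
  pool can be computed once and reused.
* **Stop codons are excluded everywhere**: the universe is the 61 sense
  codons, and the terminal stop is stripped at parse time. Sequences with
  internal stops, frame violations or ambiguous bases are rejected
  per-gene (and reported), not fatal.

## Differential proteomics

Replicate protein ratios (each the arithmetic mean of its peptide
ratios) enter an equal-variance two-sided Student t-test on the log2
scale, n ≥ 2 replicates per strain. The log2 transform makes ratio noise
approximately symmetric and the equal-variance form is the literal
Student test appropriate at n = 3 vs 3. The fold change is computed from
linear-scale replicate means, and the 1.2 threshold is applied
two-sidedly and strictly (> 1.2 up, < 1/1.2 down), so the down rule
mirrors the up rule exactly. Whether to test paired or on linear ratios
was genuinely open; unpaired-on-log2 is this package's choice because
replicates are not structurally paired across strains.

## Group statistics and resampling nulls

A codon group's effect size is summarised two ways: percent of members
down-regulated, and the D/U ratio (down-count over up-count). D/U is
undefined when nothing is up-regulated; it is then flagged rather than
coerced, because 0-denominator groups are common in strongly suppressed
simulations. The selectivity test draws, typically 100,000 times, a
random group of the same size from the non-enriched complement pool
(never from all proteins — the group must be compared against what it is
not) and reports the inclusive empirical p, the fraction of draws at
least as extreme. Draws with undefined D/U count as "at least as
extreme", which is conservative for the down-regulation direction of
inference. Both statistics are computed from the same draws.

Three controls wrap this test:

* **Co-enrichment exclusion** removes members also enriched for a second
  codon (and vice versa) and recomputes the statistics.
* **mRNA filtering** removes significantly changed proteins whose mRNA
  moved in the same direction with |fold| > 1.2 and p < 0.05. "Explained
  by mRNA" has no canonical definition; this rule mirrors the
  protein-level significance rule for symmetry.
* **Abundance matching** bins group and pool together into 10 expression
  bins at quantile breaks and forces every draw to preserve the group's
  bin histogram exactly. Tied breaks are collapsed so that flat abundance
  degenerates gracefully to plain resampling — with strict equal-count
  binning, fully tied abundance would split group and pool into
  different bins by bookkeeping order, which is not a meaningful
  stratification. A bin the pool cannot fill is an error naming the bin.

Frequency-binned D/U (left-closed bins of 10 codons/1000, last bin
open-ended) and a Spearman rank correlation between codon frequency and
protein log2 change complete the per-codon report.

## Codon clustering

The window profile slides a 15-**codon** window (step 1, fully inside
the gene) and subtracts the gene-wide target fraction, so positive
values mark local clusters. The window unit is codons, not nucleotides:
the analysis is codon-level throughout, and a 15-nt window would not
tile the reading frame.

Run counting uses overlapping windows: a stretch of m consecutive target
codons contributes m − k + 1 k-runs. This is the simplest definition
consistent across k = 3, 4, 5 and makes counts monotone non-increasing
in k, a property the tests assert. The null preserves each gene's codon
composition exactly by permuting its codon list (implemented by permuting
the target-membership mask, which is equivalent for counting). Each gene
gets an independently seeded shuffle stream derived from the master seed,
so per-gene results are reproducible regardless of iteration order. The
closed-form expected run count under shuffling,
$(L-k+1)\prod_{j=0}^{k-1}\frac{m-j}{L-j}$, is also reported and doubles
as an independent check on the simulated null in the tests.

For the actual-versus-randomised comparison across a gene set, the
"randomised" member for each gene is its per-gene mean over shuffles, so
the two compared vectors have the same length as the gene set; the
comparison is a two-sided Mann-Whitney U with tie-corrected normal
approximation (appropriate for heavily tied count data; with complete
ties the p-value is defined as 1).

## Ribosome pausing

FP/T (footprint over mRNA rpkm) proxies per-gene ribosome density;
pausing is a strict > 1.2 mutant/wild-type fold increase of FP/T. Genes
with mRNA rpkm below a floor (default 1.0) in either strain are excluded
with a reason — FP/T explodes as T → 0. Pausing calls are invariant to
per-strain rescaling, so the upstream library-size normalisation method
does not affect them; inputs are assumed rpkm-normalised.

Associations use the Pearson chi-square **without** continuity
correction. That choice is verifiable: the package's tests reconstruct
published 2×2 examples ([[75, 217], [156, 774]] and
[[226, 1025], [598, 3755]]) and recover their printed p-values
(6.92e-4, 1.39e-4) to within 1% only without the Yates correction.
Distributional comparisons use the two-sample Kolmogorov–Smirnov test
(asymptotic p; ties tolerated) and Mann-Whitney for run counts, with the
run-count comparison repeated restricted to enriched genes to control
for the enrichment–run-count correlation.

# The synthetic-data generator

`synthetic_config()` fixes the simulated study conditions; its defaults
are the conditions under which the package validates itself:

| parameter | default | meaning |
|---|---|---|
| n_genes | 5000 | yeast-scale gene count |
| gene length | lognormal(log 400, 0.4), min 60 | codons; yeast-like median CDS |
| baseline codon weights | uniform over 61 | supply a yeast table if desired |
| enriched_fraction | 0.10 | genes with boosted AGA/GAA |
| enrichment_boost | 3 | frequency multiplier in enriched genes |
| run_plant_length | 5 | one contiguous planted target run |
| de_slope | 0.01 | log2 down-shift per centered codon/1000 |
| de_null_fraction | 0.5 | genes with zero true protein effect |
| replicate_sd | 0.1 | log2 replicate noise (median RSD ≈ 0.07) |
| mrna_matched_fraction | 0.04 | true effects mirrored at mRNA level |
| pausing_boost | 0.3 | FP/T inflation per planted run |
| fp_noise_sd | 0.05 | log-scale FP measurement noise |

The generator emulates the *statistical structure* the analyses assume —
codon-content-linked down-regulation, planted clustering, run-linked
pausing, largely decoupled mRNA — and deliberately not the mechanics of
real data: no peptide-level missingness structure, no MS intensity-
dependent noise, no read-level footprinting biases, no codon
autocorrelation beyond the planted runs. Passing recovery tests
therefore demonstrates that the pipeline detects these effects when
present and stays calibrated when absent; it does not certify behaviour
under real-data pathologies. All generators are pure functions of
(config, master_seed), with per-gene sub-seeds so single genes can be
regenerated in isolation; planted runs overwrite a random interior
window, preserving length but (intentionally) shifting composition.

# Numerical and reproducibility choices

* Exact hypergeometric tails come from `phyper`; tests verify them
  against direct pmf enumeration (from binomial coefficients) to 1e-12
  for all pool sizes ≤ 30.
* Empirical p-values are plain inclusive fractions (#extreme /
  #samplings), zero is a reportable value, and shuffle/sampling counts
  are always reported alongside so add-one smoothing can be applied
  downstream if desired.
* Every random procedure takes a seed and restores the caller's RNG
  state; the pipeline report logs its configuration, and re-running a
  logged configuration reproduces the report byte-for-byte (asserted in
  the tests).
* Degenerate inputs are flagged, not silently patched: undefined D/U,
  degenerate contingency strata, empty exclusion groups, excluded
  low-mRNA genes and unparseable CDS records all surface in outputs.

## Problem sizes used by the test-suite simulations

The validation suite exercises the full stack at reduced but
statistically adequate sizes, chosen once as this package's own test
design: null calibration of the group-resampling p runs 50 genomes of
800 genes with 2,000 samplings; joint planted-effect recovery runs 20
genomes of 1,500 genes with 10,000 samplings, with shuffle-null means
estimated from 300 shuffles per gene (null-mean estimation for an
aggregate comparison needs far fewer shuffles than a per-gene empirical
p). The acceptance script runs a 2,000-gene genome with 10,000 samplings
and 1,000 shuffles per enriched gene.

# Limitations

* The unit of analysis is the gene: no codon-resolution ribosome
  occupancy, no positional pausing inference.
* Raw-data processing (peptide identification, read mapping, rpkm
  computation) is upstream; the package consumes tables.
* Enrichment calls use raw per-codon p-values, matching the analysis the
  package reproduces; no multiplicity correction across the 61 codon
  groups is applied (p-values are exported, so one can be).
* The uniform baseline codon table is a simulation convenience; real
  genomes have strongly non-uniform usage, which changes pool rates but
  not the validity of the hypergeometric comparison.
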