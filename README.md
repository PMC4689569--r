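# codonbias

Tools for asking whether a cell's translational output is biased by
gene-specific codon usage — the situation that arises when a tRNA wobble
modification (for example, the Trm9-dependent mcm⁵U/mcm⁵s²U modifications
of tRNA-Arg(UCU) and tRNA-Glu(UUC) in budding yeast) is lost and the
decoding of its cognate codons, AGA and GAA, becomes inefficient. The
package is aimed at analysts integrating quantitative proteomics,
transcriptomics and ribosome-footprinting tables at the gene level.

## What it computes

**Gene-specific codon enrichment.** For each gene *g* of *n* codons and
each of the 61 sense codons, the observed count *k* is scored against the
genome-wide codon pool (*K* occurrences among *N* codons) with a
hypergeometric model:

    Z = (k − nK/N) / sqrt( n (K/N)(1 − K/N)(N − n)/(N − 1) )

and exact inclusive tail probabilities P(X ≥ k), P(X ≤ k) under
Hypergeometric(N, K, n). A gene is called *over*- or *under*-represented
for a codon at p < 0.01 (strict, exact tails; the Z-score is reported for
ranking and visualisation).

**Differential proteomics.** Protein SILAC ratios (mean of peptide
ratios, quantified in ≥ 2 replicates per strain) are compared between
strains with an equal-variance Student t-test on log2 ratios; a protein
is *down* if its mutant/wild-type fold change is < 1/1.2 with p < 0.05,
*up* if > 1.2 with p < 0.05. Each codon-enriched group is summarised by
its percentage of down-regulated members and its D/U ratio
(down-count / up-count).

**Resampling nulls with confound controls.** Whether a codon-enriched
group is *more* down-regulated than chance is tested by drawing
equally-sized random groups from the non-enriched complement
(default 100,000 samplings) and reporting the inclusive empirical
p-value. Controls: removal of members co-enriched for another codon,
removal of proteins whose mRNA changed in the same direction
(|fold| > 1.2, p < 0.05), and abundance-matched sampling that preserves
the group's expression-bin histogram in every draw. Frequency-binned D/U
trends and Spearman rank correlations complete the per-codon picture.

**Codon clustering.** Physical clustering of target codons (AGA/GAA) is
profiled with a 15-codon sliding window (window fraction minus the gene
mean) and quantified as overlapping runs of k = 3 (or 4, 5) consecutive
target codons, compared with composition-preserving codon shuffles
(default 10,000 per gene) and summarised with Mann-Whitney U tests.

**Ribosome pausing.** From a per-gene rpkm table (footprint FP and mRNA
T, two strains) the package forms FP/T ratios, calls pausing where the
mutant/wild-type FP/T fold strictly exceeds 1.2, and cross-tabulates
pausing against DE calls, codon enrichment and run counts (Pearson
chi-square without continuity correction, Kolmogorov–Smirnov,
Mann-Whitney).

**Synthetic data.** `synthetic_config()` / `simulate_dataset()` generate
a complete input universe — CDS FASTA, replicate ratio table, mRNA table,
rpkm table — with planted enrichment, codon runs, down-regulation and
pausing recorded in a truth table, so the whole pipeline is testable
end-to-end without any external data.

## Worked example

```r
library(codonbias)

cfg <- synthetic_config(n_genes = 1000, master_seed = 42)
g  <- generate_genome(cfg)
pr <- generate_proteomics(g$truth, cfg)

usage <- codon_usage_table(g$genome, alpha = 0.01)
de    <- differential_table(pr$proteomics, alpha = 0.05, fc = 1.2)

members <- codon_group(usage, "AGA", quantified = de$gene_id)
pool    <- setdiff(de$gene_id, members)
gs <- group_stats(members, de)

rs <- resample_null(members, pool, de, statistic = "percent_down",
                    n_samplings = 10000, seed = 7)

rn <- run_null(g$genome[[members[1]]], c("AGA", "GAA"), k = 3,
               n_shuffles = 10000, seed = 7)
```

Formatting the key fields of those results gives:

```
AGA-enriched group: n = 99, down = 48, up = 0 (48.5% down)
resampling null: 1.1% down expected by chance, empirical p = 0
first group gene: 4 observed 3-codon runs vs 0.65 expected, empirical p = 0.0093
```

Read: of the 99 quantified proteins from AGA-enriched genes, 48.5% are
down-regulated in the mutant, against ~1% for random same-sized groups of
non-enriched proteins — none of 10,000 samplings reached the observed
value. The first group gene carries 4 overlapping AGA/GAA triplet runs
where its own codon composition predicts 0.65, an excess matched by only
0.9% of composition-preserving shuffles.

The full pipeline (all stages, TSV tables and a consolidated JSON
report) runs from a single configuration:

```r
cfg <- run_config(fasta = "genes.fasta", proteomics = "proteomics.tsv",
                  mrna = "mrna.tsv", rpkm = "rpkm.tsv",
                  out_dir = "out", seed = 17)
run_pipeline(cfg)
```

A thin command-line wrapper lives at `inst/scripts/codonbias.R`
(subcommands `simulate` and `pipeline`).

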