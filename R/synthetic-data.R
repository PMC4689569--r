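# Synthetic-data generator: a yeast-like CDS set with planted codon
# enrichment and codon runs, replicate protein ratios whose down-shift
# tracks AGA/GAA content, mostly-null mRNA changes, and FP/T rpkm pairs
# whose inflation tracks planted runs. Every planted effect is recorded
# in a truth table for recovery tests.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the analyses assume: a genome of
#' 5000 genes with log-normal lengths around 400 codons, 10% of genes with
#' AGA/GAA usage boosted 3-fold and one planted contiguous run of 5 target
#' codons, protein down-regulation proportional to AGA+GAA frequency
#' (log2 fold change = -de_slope * centered per-1000 frequency, applied to
#' a non-null fraction of genes), replicate noise of 0.1 on the log2
#' scale (matching a median replicate RSD near 0.07), mostly-null mRNA
#' changes with a small fraction mirroring the protein change, and FP/T
#' ratios inflated by `pausing_boost` per planted run.
#'
#' @param n_genes Number of genes.
#' @param length_meanlog,length_sdlog Log-normal gene-length parameters
#'   (codons).
#' @param min_length Minimum gene length in codons.
#' @param baseline_freqs Named baseline codon sampling weights over the 61
#'   sense codons (default uniform).
#' @param target_codons Codons whose usage is planted (default AGA, GAA).
#' @param enriched_fraction Fraction of genes with boosted target usage.
#' @param enrichment_boost Multiplicative frequency boost for target
#'   codons in enriched genes.
#' @param run_plant_length Length (codons) of each planted contiguous run.
#' @param n_runs_planted Planted run blocks per enriched gene.
#' @param de_slope Down-regulation slope per unit of centered target
#'   frequency (per 1000).
#' @param de_null_fraction Fraction of genes with zero true protein
#'   effect regardless of codon content.
#' @param replicate_sd Log2-scale replicate noise SD.
#' @param n_replicates Replicates per strain.
#' @param abundance_meanlog,abundance_sdlog Log-normal protein abundance.
#' @param abundance_enrich_shift Log-scale abundance shift for enriched
#'   genes (exercises the abundance-matched control).
#' @param mrna_matched_fraction Fraction of true protein effects mirrored
#'   at the mRNA level.
#' @param mrna_null_sd SD of null mRNA log2 fold changes.
#' @param t_meanlog,t_sdlog Log-normal mRNA rpkm parameters.
#' @param base_fp_ratio Baseline FP/T ratio.
#' @param pausing_boost FP/T inflation per planted run in the mutant.
#' @param fp_noise_sd Log-scale FP measurement noise SD.
#' @param master_seed Master seed; all generators are pure functions of
#'   (config, master_seed).
#' @return List of class "synthetic_config".
#' @export
synthetic_config <- function(n_genes = 5000,
                             length_meanlog = log(400),
                             length_sdlog = 0.4,
                             min_length = 60,
                             baseline_freqs = NULL,
                             target_codons = c("AGA", "GAA"),
                             enriched_fraction = 0.10,
                             enrichment_boost = 3,
                             run_plant_length = 5,
                             n_runs_planted = 1,
                             de_slope = 0.01,
                             de_null_fraction = 0.5,
                             replicate_sd = 0.1,
                             n_replicates = 3,
                             abundance_meanlog = log(1e5),
                             abundance_sdlog = 1,
                             abundance_enrich_shift = 0.5,
                             mrna_matched_fraction = 0.04,
                             mrna_null_sd = 0.05,
                             t_meanlog = log(50),
                             t_sdlog = 1,
                             base_fp_ratio = 1,
                             pausing_boost = 0.3,
                             fp_noise_sd = 0.05,
                             master_seed = 1) {
  if (is.null(baseline_freqs)) {
    baseline_freqs <- stats::setNames(
      rep(1 / length(SENSE_CODONS), length(SENSE_CODONS)), SENSE_CODONS)
  }
  baseline_freqs <- baseline_freqs / sum(baseline_freqs)
  cfg <- list(n_genes = n_genes, length_meanlog = length_meanlog,
              length_sdlog = length_sdlog, min_length = min_length,
              baseline_freqs = baseline_freqs,
              target_codons = target_codons,
              enriched_fraction = enriched_fraction,
              enrichment_boost = enrichment_boost,
              run_plant_length = run_plant_length,
              n_runs_planted = n_runs_planted,
              de_slope = de_slope, de_null_fraction = de_null_fraction,
              replicate_sd = replicate_sd, n_replicates = n_replicates,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              abundance_enrich_shift = abundance_enrich_shift,
              mrna_matched_fraction = mrna_matched_fraction,
              mrna_null_sd = mrna_null_sd,
              t_meanlog = t_meanlog, t_sdlog = t_sdlog,
              base_fp_ratio = base_fp_ratio,
              pausing_boost = pausing_boost, fp_noise_sd = fp_noise_sd,
              master_seed = master_seed)
  if (enriched_fraction < 0 || enriched_fraction > 1 ||
      de_null_fraction < 0 || de_null_fraction > 1 ||
      mrna_matched_fraction < 0 || mrna_matched_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  boosted <- sum(baseline_freqs[target_codons]) * enrichment_boost
  if (boosted >= 1) stop("enrichment boost drives target frequency above 1")
  class(cfg) <- "synthetic_config"
  cfg
}

# boosted and renormalised codon weights for enriched genes
boosted_freqs <- function(cfg) {
  f <- cfg$baseline_freqs
  f[cfg$target_codons] <- f[cfg$target_codons] * cfg$enrichment_boost
  f / sum(f)
}

#' Generate a synthetic genome with planted codon enrichment and runs
#'
#' Draws each gene's codons independently from the baseline codon
#' weights; a random `enriched_fraction` of genes instead uses weights
#' with the target codons boosted `enrichment_boost`-fold and receives
#' `n_runs_planted` contiguous runs of `run_plant_length` target codons
#' overwriting random interior windows (length preserved; composition
#' deliberately shifted). Every gene starts with ATG and contains no
#' internal stop; gene streams are sub-seeded from the master seed so any
#' single gene is reproducible in isolation.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `genome` (named list of codon vectors) and `truth`
#'   (data.frame: gene_id, length, is_enriched, planted_runs,
#'   target_freq_per_1000).
#' @export
generate_genome <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  is_enriched <- with_seed(cfg$master_seed,
                           stats::runif(n) < cfg$enriched_fraction)
  bf <- cfg$baseline_freqs
  ef <- boosted_freqs(cfg)
  codon_names <- names(bf)
  genome <- vector("list", n)
  planted <- integer(n)
  for (i in seq_len(n)) {
    genome[[i]] <- with_seed(derive_seed(cfg$master_seed, i), {
      L <- max(cfg$min_length,
               round(stats::rlnorm(1, cfg$length_meanlog, cfg$length_sdlog)))
      w <- if (is_enriched[i]) ef else bf
      cd <- c("ATG", sample(codon_names, L - 1, replace = TRUE, prob = w))
      if (is_enriched[i] && cfg$n_runs_planted > 0) {
        for (r in seq_len(cfg$n_runs_planted)) {
          start <- sample(2:(L - cfg$run_plant_length + 1), 1)
          cd[start:(start + cfg$run_plant_length - 1)] <-
            sample(cfg$target_codons, cfg$run_plant_length, replace = TRUE)
        }
        planted[i] <- cfg$n_runs_planted
      }
      cd
    })
    attr(genome[[i]], "gene_id") <- ids[i]
  }
  names(genome) <- ids
  tf <- vapply(genome, function(cd) {
    1000 * sum(cd %in% cfg$target_codons) / length(cd)
  }, numeric(1))
  truth <- data.frame(gene_id = ids, length = lengths(genome),
                      is_enriched = is_enriched, planted_runs = planted,
                      target_freq_per_1000 = unname(tf),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Write a genome as FASTA
#'
#' Appends a terminal TAA stop codon to each gene (the parser strips it
#' back off). Output is byte-identical for a fixed configuration.
#'
#' @param genome Named list of codon vectors.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genome, function(cd) paste0(paste(cd, collapse = ""), "TAA"),
           character(1))
  )
  Biostrings::writeXStringSet(seqs, path, width = 70)
  invisible(path)
}

#' Generate replicate protein ratios with codon-linked down-regulation
#'
#' Each gene's true log2 fold change is `-de_slope` times its centered
#' AGA+GAA frequency (per 1000), zeroed for a `de_null_fraction` of genes;
#' replicate ratios are 2^(effect + noise) for the mutant and 2^noise for
#' the wild type, with log2 noise SD `replicate_sd`. Abundance is drawn
#' log-normally, shifted upward for enriched genes.
#'
#' @param truth Truth table from [generate_genome()].
#' @param cfg The same [synthetic_config()].
#' @return List with `proteomics` (data.frame: gene_id, wt_r*, mut_r*,
#'   abundance) and `truth` extended with is_de_null, true_log2fc,
#'   is_de_down.
#' @export
generate_proteomics <- function(truth, cfg) {
  n <- nrow(truth)
  res <- with_seed(derive_seed(cfg$master_seed, 1000003), {
    is_null <- stats::runif(n) < cfg$de_null_fraction
    centered <- truth$target_freq_per_1000 -
      mean(truth$target_freq_per_1000)
    true_lfc <- ifelse(is_null, 0, -cfg$de_slope * centered)
    k <- cfg$n_replicates
    W <- 2^matrix(stats::rnorm(n * k, 0, cfg$replicate_sd), n, k)
    M <- 2^(true_lfc + matrix(stats::rnorm(n * k, 0, cfg$replicate_sd), n, k))
    ab <- stats::rlnorm(n, cfg$abundance_meanlog +
                          cfg$abundance_enrich_shift * truth$is_enriched,
                        cfg$abundance_sdlog)
    list(is_null = is_null, true_lfc = true_lfc, W = W, M = M, ab = ab)
  })
  k <- cfg$n_replicates
  prot <- data.frame(gene_id = truth$gene_id, res$W, res$M,
                     abundance = res$ab, stringsAsFactors = FALSE)
  names(prot) <- c("gene_id", paste0("wt_r", seq_len(k)),
                   paste0("mut_r", seq_len(k)), "abundance")
  truth$is_de_null <- res$is_null
  truth$true_log2fc <- res$true_lfc
  truth$is_de_down <- res$true_lfc < -log2(1.2)
  list(proteomics = prot, truth = truth)
}

#' Generate a mostly-null mRNA fold-change table
#'
#' mRNA log2 fold changes are null noise for almost all genes; a
#' `mrna_matched_fraction` of genes with a non-zero true protein effect
#' instead mirror that effect with a small p-value, exercising the
#' mRNA-level filter downstream.
#'
#' @param truth Truth table extended by [generate_proteomics()].
#' @param cfg The same [synthetic_config()].
#' @return List with `mrna` (data.frame: gene_id, log2fc, p) and `truth`
#'   extended with mrna_matched.
#' @export
generate_mrna <- function(truth, cfg) {
  if (is.null(truth$true_log2fc)) {
    stop("run generate_proteomics before generate_mrna")
  }
  n <- nrow(truth)
  res <- with_seed(derive_seed(cfg$master_seed, 2000003), {
    lfc <- stats::rnorm(n, 0, cfg$mrna_null_sd)
    p <- stats::runif(n)
    matched <- truth$true_log2fc != 0 &
      stats::runif(n) < cfg$mrna_matched_fraction
    lfc[matched] <- truth$true_log2fc[matched]
    p[matched] <- stats::runif(sum(matched), 0, 0.01)
    list(lfc = lfc, p = p, matched = matched)
  })
  truth$mrna_matched <- res$matched
  list(mrna = data.frame(gene_id = truth$gene_id, log2fc = res$lfc,
                         p = res$p, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate an FP/T rpkm table with run-linked pausing
#'
#' mRNA (T) rpkm is log-normal per strain; footprint (FP) rpkm is T times
#' a baseline ratio with log-scale noise, inflated in the mutant by
#' `1 + pausing_boost * planted_runs`. With positive boost and planted
#' runs, the mutant FP/T fold exceeds the pausing cutoff.
#'
#' @param truth Truth table (needs planted_runs).
#' @param cfg The same [synthetic_config()].
#' @return List with `rpkm` (data.frame: gene_id, fp_wt, t_wt, fp_mut,
#'   t_mut) and `truth` extended with is_paused (planted expectation at
#'   zero noise, fold cutoff 1.2).
#' @export
generate_footprints <- function(truth, cfg) {
  n <- nrow(truth)
  res <- with_seed(derive_seed(cfg$master_seed, 3000003), {
    t_wt <- stats::rlnorm(n, cfg$t_meanlog, cfg$t_sdlog)
    t_mut <- stats::rlnorm(n, cfg$t_meanlog, cfg$t_sdlog)
    boost <- 1 + cfg$pausing_boost * truth$planted_runs
    fp_wt <- t_wt * cfg$base_fp_ratio *
      exp(stats::rnorm(n, 0, cfg$fp_noise_sd))
    fp_mut <- t_mut * cfg$base_fp_ratio * boost *
      exp(stats::rnorm(n, 0, cfg$fp_noise_sd))
    list(t_wt = t_wt, t_mut = t_mut, fp_wt = fp_wt, fp_mut = fp_mut,
         boost = boost)
  })
  truth$is_paused <- res$boost > 1.2
  list(rpkm = data.frame(gene_id = truth$gene_id, fp_wt = res$fp_wt,
                         t_wt = res$t_wt, fp_mut = res$fp_mut,
                         t_mut = res$t_mut, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs the four generators and writes genes.fasta, proteomics.tsv,
#' mrna.tsv, rpkm.tsv and truth.tsv into `out_dir`. Pure function of the
#' configuration (including its master seed): rerunning writes identical
#' files.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_genome(cfg)
  p <- generate_proteomics(g$truth, cfg)
  m <- generate_mrna(p$truth, cfg)
  f <- generate_footprints(m$truth, cfg)
  paths <- list(
    fasta = file.path(out_dir, "genes.fasta"),
    proteomics = file.path(out_dir, "proteomics.tsv"),
    mrna = file.path(out_dir, "mrna.tsv"),
    rpkm = file.path(out_dir, "rpkm.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_genome_fasta(g$genome, paths$fasta)
  write_tsv_table(p$proteomics, paths$proteomics)
  write_tsv_table(m$mrna, paths$mrna)
  write_tsv_table(f$rpkm, paths$rpkm)
  write_tsv_table(f$truth, paths$truth)
  invisible(list(genome = g$genome, truth = f$truth,
                 proteomics = p$proteomics, mrna = m$mrna, rpkm = f$rpkm,
                 paths = paths))
}
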