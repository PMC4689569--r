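small_cfg <- function(...) {
  synthetic_config(n_genes = 120, length_meanlog = log(150),
                   length_sdlog = 0.3, min_length = 60, master_seed = 42,
                   ...)
}

test_that("generators are pure functions of the configuration", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  p1 <- generate_proteomics(g1$truth, cfg)
  p2 <- generate_proteomics(g2$truth, cfg)
  expect_identical(p1$proteomics, p2$proteomics)
  f1 <- generate_footprints(p1$truth, cfg)
  f2 <- generate_footprints(p2$truth, cfg)
  expect_identical(f1$rpkm, f2$rpkm)
  # a written bundle is byte-identical on regeneration
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("genes.fasta", "proteomics.tsv", "mrna.tsv", "rpkm.tsv",
              "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("every generated gene is a clean ORF and parses with no rejects", {
  cfg <- small_cfg()
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, d)
  expect_no_warning(g <- read_cds_fasta(sim$paths$fasta))
  expect_length(g, cfg$n_genes)
  expect_true(all(vapply(g, function(cd) cd[1] == "ATG", logical(1))))
})

test_that("the enriched fraction lands near its planned rate", {
  cfg <- synthetic_config(n_genes = 1000, length_meanlog = log(100),
                          min_length = 60, master_seed = 5)
  tr <- generate_genome(cfg)$truth
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lt(abs(mean(tr$is_enriched) - 0.1), 4 * se)
  # planted runs only in enriched genes
  expect_true(all(tr$planted_runs[tr$is_enriched] == 1))
  expect_true(all(tr$planted_runs[!tr$is_enriched] == 0))
  # enriched genes carry visibly boosted AGA/GAA usage
  expect_gt(mean(tr$target_freq_per_1000[tr$is_enriched]),
            2 * mean(tr$target_freq_per_1000[!tr$is_enriched]))
})

test_that("a frequency boost above the simplex is rejected", {
  expect_error(synthetic_config(enrichment_boost = 40), "above 1")
  expect_error(synthetic_config(enriched_fraction = 1.5), "\\[0, 1\\]")
})

test_that("planted enrichment is recovered by the usage scoring", {
  # long genes at boost 3: the hypergeometric call should find nearly all
  cfg <- synthetic_config(n_genes = 300, length_meanlog = log(700),
                          length_sdlog = 0.1, min_length = 500,
                          enriched_fraction = 0.1, enrichment_boost = 3,
                          master_seed = 9)
  g <- generate_genome(cfg)
  usage <- codon_usage_table(g$genome)
  over_aga <- codon_group(usage, "AGA")
  enriched <- g$truth$gene_id[g$truth$is_enriched]
  expect_gt(length(enriched), 10)
  recovery <- mean(enriched %in% over_aga)
  expect_gte(recovery, 0.9)
})

test_that("noiseless proteomics hits exact fold changes", {
  cfg <- small_cfg(replicate_sd = 0, de_null_fraction = 0,
                   de_slope = 0.02)
  g <- generate_genome(cfg)
  p <- generate_proteomics(g$truth, cfg)
  tab <- differential_table(p$proteomics)
  lfc_true <- p$truth$true_log2fc[match(tab$gene_id, p$truth$gene_id)]
  expect_equal(log2(tab$fold_change), lfc_true, tolerance = 1e-9)
  strong <- lfc_true < -log2(1.2)
  expect_true(all(tab$call[strong] == "down"))
})

test_that("a zero slope produces DE calls at the false-positive rate", {
  cfg <- synthetic_config(n_genes = 2000, length_meanlog = log(100),
                          min_length = 60, de_slope = 0,
                          master_seed = 31)
  g <- generate_genome(cfg)
  p <- generate_proteomics(g$truth, cfg)
  tab <- differential_table(p$proteomics, alpha = 0.05, fc = 1)
  rate <- mean(tab$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("mRNA matching spans its two limits", {
  cfg0 <- small_cfg(mrna_matched_fraction = 0, de_null_fraction = 0,
                    replicate_sd = 0.05, de_slope = 0.02)
  g <- generate_genome(cfg0)
  p <- generate_proteomics(g$truth, cfg0)
  m0 <- generate_mrna(p$truth, cfg0)
  de <- differential_table(p$proteomics)
  expect_equal(mrna_filter(de, m0$mrna)$n_removed, 0)
  # matched fraction 1 with noiseless strong effects: every significant
  # protein change is a true effect mirrored at the mRNA level
  cfg1 <- small_cfg(mrna_matched_fraction = 1, de_null_fraction = 0,
                    replicate_sd = 0, de_slope = 0.02)
  g1 <- generate_genome(cfg1)
  p1 <- generate_proteomics(g1$truth, cfg1)
  m1 <- generate_mrna(p1$truth, cfg1)
  de1 <- differential_table(p1$proteomics)
  changed <- de1[de1$call != "unchanged", ]
  mf <- mrna_filter(de1, m1$mrna)
  expect_gt(nrow(changed), 0)
  expect_equal(mf$n_removed, nrow(changed))
  # an intermediate fraction removes about its share of true effects
  cfg04 <- small_cfg(mrna_matched_fraction = 0.3, de_null_fraction = 0,
                     replicate_sd = 0, de_slope = 0.02)
  g04 <- generate_genome(cfg04)
  p04 <- generate_proteomics(g04$truth, cfg04)
  m04 <- generate_mrna(p04$truth, cfg04)
  de04 <- differential_table(p04$proteomics)
  n_changed <- sum(de04$call != "unchanged")
  removed <- mrna_filter(de04, m04$mrna)$n_removed
  expect_lt(abs(removed / n_changed - 0.3),
            3 * sqrt(0.3 * 0.7 / n_changed) + 1e-9)
})

test_that("footprint generation links pausing to planted runs", {
  # strong boost, no noise: exactly the genes with planted runs pause
  cfg <- small_cfg(pausing_boost = 2, fp_noise_sd = 0)
  g <- generate_genome(cfg)
  f <- generate_footprints(g$truth, cfg)
  pz <- call_pausing(f$rpkm, t_floor = 0)$pausing
  planted <- g$truth$planted_runs[match(pz$gene_id,
                                        g$truth$gene_id)] >= 1
  expect_equal(pz$paused, planted)
  # zero boost: pausing only from measurement noise, and rarely
  cfg0 <- small_cfg(pausing_boost = 0)
  f0 <- generate_footprints(generate_genome(cfg0)$truth, cfg0)
  pz0 <- call_pausing(f0$rpkm, t_floor = 0)$pausing
  expect_lt(mean(pz0$paused), 0.05)
})
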