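# Gene-level ribosome pausing from footprint (FP) and mRNA (T) abundance
# and its association with differential expression, codon enrichment and
# codon runs.

#' Call per-gene ribosomal pausing from FP/T ratios
#'
#' The FP/T ratio (footprint rpkm over mRNA rpkm) proxies per-gene
#' ribosome density; a gene is called paused when the mutant/wild-type
#' fold change of that ratio strictly exceeds `fold_cutoff`. Genes whose
#' mRNA abundance falls below `t_floor` in either strain are excluded
#' (unstable ratios) and reported rather than silently dropped.
#'
#' @param rpkm data.frame with gene_id, fp_wt, t_wt, fp_mut, t_mut
#'   columns (library-size-normalised rpkm).
#' @param fold_cutoff Strict pausing threshold on the FP/T fold change.
#' @param t_floor Minimum mRNA rpkm in both strains.
#' @return List with `pausing` (data.frame: gene_id, ratio_wt, ratio_mut,
#'   fold, paused) and `excluded` (data.frame: gene_id, reason).
#' @export
call_pausing <- function(rpkm, fold_cutoff = 1.2, t_floor = 1.0) {
  if (any(rpkm[, c("fp_wt", "t_wt", "fp_mut", "t_mut")] < 0)) {
    stop("rpkm values must be non-negative")
  }
  low <- rpkm$t_wt < t_floor | rpkm$t_mut < t_floor
  excluded <- data.frame(
    gene_id = rpkm$gene_id[low],
    reason = rep(sprintf("mRNA rpkm below floor %g", t_floor), sum(low)),
    stringsAsFactors = FALSE
  )
  kept <- rpkm[!low, , drop = FALSE]
  ratio_wt <- kept$fp_wt / kept$t_wt
  ratio_mut <- kept$fp_mut / kept$t_mut
  fold <- ratio_mut / ratio_wt
  list(
    pausing = data.frame(gene_id = kept$gene_id, ratio_wt = ratio_wt,
                         ratio_mut = ratio_mut, fold = fold,
                         paused = fold > fold_cutoff,
                         stringsAsFactors = FALSE),
    excluded = excluded
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square with one degree of freedom and no continuity
#' correction (the variant that reproduces the printed contingency-table
#' p-values from the printed counts).
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return List with statistic, p_value, expected.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal: chi-square undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       expected = ht$expected)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided two-sample K-S test with asymptotic p-value (ties tolerated,
#' as expected for count data).
#'
#' @param x,y Numeric vectors (non-empty).
#' @return List with statistic (D) and p_value.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# 2x2 table of pausing (rows: paused TRUE/FALSE) against a logical outcome
pausing_table <- function(paused, outcome) {
  m <- matrix(c(sum(paused & outcome), sum(paused & !outcome),
                sum(!paused & outcome), sum(!paused & !outcome)),
              nrow = 2, byrow = TRUE,
              dimnames = list(paused = c("paused", "not_paused"),
                              outcome = c("yes", "no")))
  m
}

# run a chi-square, flagging degenerate tables instead of erroring
safe_chisq <- function(tab) {
  res <- tryCatch(chi_square_2x2(tab), error = identity)
  if (inherits(res, "error")) {
    list(table = tab, degenerate = TRUE, statistic = NA_real_,
         p_value = NA_real_)
  } else {
    list(table = tab, degenerate = FALSE, statistic = res$statistic,
         p_value = res$p_value)
  }
}

#' Cross-tabulations of pausing against expression, enrichment and runs
#'
#' Builds the three gene-level association analyses between ribosomal
#' pausing and (i) differential-expression calls (chi-square on the
#' paused-by-down table, K-S on the log2 fold-change distributions),
#' (ii) AGA/GAA codon enrichment (chi-square on the paused-by-enriched
#' table, K-S on the target-codon usage distributions), and (iii) codon
#' run counts (Mann-Whitney and K-S between paused and unpaused genes,
#' repeated restricted to enriched genes). Genes present in only one data
#' layer are dropped from the corresponding joint analysis, with counts
#' reported.
#'
#' @param pausing Pausing table from [call_pausing()] (`$pausing`).
#' @param calls DE call table with gene_id, fold_change, call.
#' @param enriched Character vector of gene ids enriched for the target
#'   codons.
#' @param usage_freq Named numeric vector: per-gene summed target-codon
#'   frequency per 1000 (defines the enrichment-analysis universe).
#' @param run_counts Named integer vector of per-gene k-run counts.
#' @return Nested list with `de`, `enrichment`, `runs`,
#'   `runs_enriched_only` sections and `n_joint` overlap counts.
#' @export
pausing_cross_tabs <- function(pausing, calls, enriched, usage_freq,
                               run_counts) {
  ## pausing x DE (restricted to genes in both layers)
  de_ids <- intersect(pausing$gene_id, calls$gene_id)
  pz <- pausing$paused[match(de_ids, pausing$gene_id)]
  cl <- calls$call[match(de_ids, calls$gene_id)]
  fc <- calls$fold_change[match(de_ids, calls$gene_id)]
  de <- safe_chisq(pausing_table(pz, cl == "down"))
  de$ks_fold <- if (any(pz) && any(!pz)) {
    ks_two_sample(log2(fc[pz]), log2(fc[!pz]))
  } else NULL

  ## pausing x enrichment (all genes with usage information)
  en_ids <- intersect(pausing$gene_id, names(usage_freq))
  pz2 <- pausing$paused[match(en_ids, pausing$gene_id)]
  is_en <- en_ids %in% enriched
  en <- safe_chisq(pausing_table(pz2, is_en))
  en$ks_usage <- if (any(pz2) && any(!pz2)) {
    ks_two_sample(usage_freq[en_ids][pz2], usage_freq[en_ids][!pz2])
  } else NULL

  ## pausing x run counts
  rn_ids <- intersect(pausing$gene_id, names(run_counts))
  pz3 <- pausing$paused[match(rn_ids, pausing$gene_id)]
  rc <- run_counts[rn_ids]
  run_section <- function(ids, paused, counts) {
    if (!any(paused) || !any(!paused)) {
      return(list(degenerate = TRUE, n_paused = sum(paused),
                  n_not = sum(!paused)))
    }
    list(degenerate = FALSE,
         n_paused = sum(paused), n_not = sum(!paused),
         mann_whitney = compare_run_vectors(counts[paused], counts[!paused]),
         ks = ks_two_sample(counts[paused], counts[!paused]))
  }
  runs <- run_section(rn_ids, pz3, rc)
  keep_en <- rn_ids %in% enriched
  runs_en <- run_section(rn_ids[keep_en], pz3[keep_en], rc[keep_en])

  list(de = de, enrichment = en, runs = runs,
       runs_enriched_only = runs_en,
       n_joint = list(de = length(de_ids), enrichment = length(en_ids),
                      runs = length(rn_ids)))
}
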