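# End-to-end orchestration: configuration, stage sequencing, and the
# consolidated JSON report.

#' Pipeline run configuration
#'
#' Bundles the analysis thresholds (enrichment alpha 0.01, DE alpha 0.05,
#' fold threshold 1.2, pausing cutoff 1.2, 15-codon window, run order 3,
#' 100,000 resamplings, 10,000 shuffles per gene, 10 abundance bins, 7
#' frequency bins of width 10, mRNA rpkm floor 1), the master seed, and
#' the input/output paths.
#'
#' @param fasta,proteomics Paths to the CDS FASTA and replicate ratio
#'   table (required for [run_pipeline()]).
#' @param mrna,rpkm Optional paths to the mRNA fold-change table and the
#'   FP/T rpkm table; the matching stages are skipped when absent.
#' @param out_dir Output directory.
#' @param target_codons Codons analysed for enrichment, runs and pausing.
#' @param alpha_enrich,alpha_de,fc,pausing_cutoff,window,run_k,n_samplings,n_shuffles,n_bins_abundance,n_bins_freq,freq_bin_width,t_floor
#'   Analysis thresholds; see above for defaults.
#' @param seed Master seed for all random procedures.
#' @param run_scope "enriched" restricts per-gene shuffle nulls to genes
#'   enriched for a target codon; "all" shuffles every gene.
#' @return List of class "run_config".
#' @export
run_config <- function(fasta = NULL, proteomics = NULL, mrna = NULL,
                       rpkm = NULL, out_dir = "codonbias_out",
                       target_codons = c("AGA", "GAA"),
                       alpha_enrich = 0.01, alpha_de = 0.05, fc = 1.2,
                       pausing_cutoff = 1.2, window = 15, run_k = 3,
                       n_samplings = 100000, n_shuffles = 10000,
                       n_bins_abundance = 10, n_bins_freq = 7,
                       freq_bin_width = 10, t_floor = 1.0, seed = 1,
                       run_scope = c("enriched", "all")) {
  run_scope <- match.arg(run_scope)
  num <- c(alpha_enrich, alpha_de, fc, pausing_cutoff, window, run_k,
           n_samplings, n_shuffles, n_bins_abundance, n_bins_freq,
           freq_bin_width, t_floor)
  if (any(num <= 0)) stop("all thresholds must be positive")
  cfg <- list(fasta = fasta, proteomics = proteomics, mrna = mrna,
              rpkm = rpkm, out_dir = out_dir,
              target_codons = target_codons,
              alpha_enrich = alpha_enrich, alpha_de = alpha_de, fc = fc,
              pausing_cutoff = pausing_cutoff, window = window,
              run_k = run_k, n_samplings = n_samplings,
              n_shuffles = n_shuffles,
              n_bins_abundance = n_bins_abundance,
              n_bins_freq = n_bins_freq, freq_bin_width = freq_bin_width,
              t_floor = t_floor, seed = seed, run_scope = run_scope)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as a plain key-value file
#'
#' One `key = value` line per field; character vectors are
#' comma-separated. Round-trips losslessly through [read_run_config()].
#'
#' @param cfg A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    val <- if (is.null(v)) "" else paste(format(v, digits = 15), collapse = ",")
    paste0(nm, " = ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration from a key-value file
#'
#' @param path Path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  args <- stats::setNames(vector("list", length(keys)), keys)
  char_keys <- c("fasta", "proteomics", "mrna", "rpkm", "out_dir",
                 "target_codons", "run_scope")
  for (i in seq_along(keys)) {
    v <- vals[i]
    if (v == "") {
      args[keys[i]] <- list(NULL)
    } else if (keys[i] %in% char_keys) {
      args[[keys[i]]] <- strsplit(v, ",")[[1]]
    } else {
      args[[keys[i]]] <- as.numeric(strsplit(v, ",")[[1]])
    }
  }
  do.call(run_config, args)
}

# JSON-serialisable summary of a resampling result (drops the bulky null
# draws; keeps everything needed to interpret and reproduce it)
resampling_summary <- function(rs) {
  list(n = rs$observed$n, n_down = rs$observed$n_down,
       n_up = rs$observed$n_up,
       percent_down = rs$observed$percent_down,
       du = if (rs$observed$du_defined) rs$observed$du else NULL,
       du_defined = rs$observed$du_defined,
       n_samplings = rs$n_samplings,
       null_mean_percent_down = mean(rs$null_percent_down),
       empirical_p_percent_down = rs$empirical_p_percent_down,
       empirical_p_du = rs$empirical_p_du,
       seed = rs$seed)
}

#' Run the full codon-biased-translation pipeline
#'
#' Executes, in order: CDS parsing and codon-usage scoring, differential
#' proteomics, per-target-codon group statistics with resampling nulls
#' (plain, mRNA-filtered when an mRNA table is given, and
#' abundance-matched), frequency-binned D/U and rank correlation,
#' per-gene codon-run shuffle nulls, and (when an rpkm table is given)
#' pausing calls with the pausing cross-tabulations. Writes per-stage TSV
#' tables and a consolidated JSON report into `cfg$out_dir`; the report
#' records every seed, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param cfg A [run_config()] with at least `fasta` and `proteomics` set.
#' @return Invisibly, the report list (also written as report.json).
#' @export
run_pipeline <- function(cfg) {
  stage <- "setup"
  fail <- function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    if (is.null(cfg$fasta) || is.null(cfg$proteomics)) {
      stop("config must provide 'fasta' and 'proteomics' paths")
    }
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "codon_usage"
    genome <- read_cds_fasta(cfg$fasta)
    usage <- codon_usage_table(genome, alpha = cfg$alpha_enrich)
    write_tsv_table(usage, file.path(cfg$out_dir, "usage.tsv"))

    stage <- "differential_expression"
    quants <- read_tsv_table(cfg$proteomics)
    de <- differential_table(quants, alpha = cfg$alpha_de, fc = cfg$fc)
    write_tsv_table(de, file.path(cfg$out_dir, "de.tsv"))
    whole <- group_stats(de$gene_id, de)

    stage <- "mrna_filter"
    mrna_section <- NULL
    de_mrna <- de
    if (!is.null(cfg$mrna)) {
      mrna <- read_tsv_table(cfg$mrna)
      mf <- mrna_filter(de, mrna, fc = cfg$fc, alpha = cfg$alpha_de)
      de_mrna <- mf$calls
      mrna_section <- list(n_removed = mf$n_removed,
                           n_changed = sum(de$call != "unchanged"))
    }

    stage <- "enrichment"
    quantified <- de$gene_id
    groups <- lapply(cfg$target_codons, function(cd) {
      codon_group(usage, cd, quantified)
    })
    names(groups) <- cfg$target_codons
    abundance <- if ("abundance" %in% names(de)) {
      stats::setNames(de$abundance, de$gene_id)
    } else NULL
    enr <- list()
    for (j in seq_along(cfg$target_codons)) {
      cd <- cfg$target_codons[j]
      members <- groups[[cd]]
      pool <- setdiff(quantified, members)
      sec <- list(codon = cd, stats = group_stats(members, de))
      sec$resampling <- resampling_summary(
        resample_null(members, pool, de, statistic = "du",
                      n_samplings = cfg$n_samplings,
                      seed = derive_seed(cfg$seed, 100 + j)))
      if (!is.null(mrna_section)) {
        m2 <- intersect(members, de_mrna$gene_id)
        p2 <- intersect(pool, de_mrna$gene_id)
        sec$resampling_mrna_filtered <- resampling_summary(
          resample_null(m2, p2, de_mrna, statistic = "du",
                        n_samplings = cfg$n_samplings,
                        seed = derive_seed(cfg$seed, 200 + j)))
      }
      if (!is.null(abundance)) {
        sec$resampling_abundance_matched <- resampling_summary(
          abundance_matched_null(members, pool, abundance, de,
                                 statistic = "du",
                                 n_bins = cfg$n_bins_abundance,
                                 n_samplings = cfg$n_samplings,
                                 seed = derive_seed(cfg$seed, 300 + j)))
      }
      other <- setdiff(cfg$target_codons, cd)
      if (length(other) == 1L) {
        ex <- exclusion_analysis(cd, other, groups, de)
        sec$exclusion <- list(
          other = other,
          n_remaining = length(ex$focal_minus_other$members),
          stats = ex$focal_minus_other$stats,
          emptied = ex$focal_minus_other$emptied)
      }
      bins <- bin_by_frequency(de, usage, cd,
                               bin_width = cfg$freq_bin_width,
                               n_bins = cfg$n_bins_freq)
      write_tsv_table(bins,
                      file.path(cfg$out_dir, paste0("bins_", cd, ".tsv")))
      u <- usage[usage$codon == cd, ]
      freq <- u$freq_per_1000[match(de$gene_id, u$gene_id)]
      sec$correlation <- freq_change_correlation(freq,
                                                 log2(de$fold_change))
      enr[[cd]] <- sec
    }

    stage <- "codon_runs"
    run_genes <- if (cfg$run_scope == "enriched") {
      unique(unlist(lapply(cfg$target_codons, function(cd) {
        codon_group(usage, cd)
      })))
    } else names(genome)
    runs <- run_null_table(genome[run_genes], cfg$target_codons,
                           k = cfg$run_k, n_shuffles = cfg$n_shuffles,
                           seed = derive_seed(cfg$seed, 400))
    write_tsv_table(runs, file.path(cfg$out_dir, "runs.tsv"))
    run_cmp <- compare_run_vectors(runs$actual, runs$null_mean)
    run_section <- list(
      n_genes = nrow(runs), k = cfg$run_k, n_shuffles = cfg$n_shuffles,
      mean_actual = mean(runs$actual), mean_null = mean(runs$null_mean),
      frac_actual_above_null = mean(runs$actual > runs$null_mean),
      mann_whitney_U = run_cmp$U, mann_whitney_p = run_cmp$p_value)

    stage <- "pausing"
    pausing_section <- NULL
    if (!is.null(cfg$rpkm)) {
      rpkm <- read_tsv_table(cfg$rpkm)
      pz <- call_pausing(rpkm, fold_cutoff = cfg$pausing_cutoff,
                         t_floor = cfg$t_floor)
      write_tsv_table(pz$pausing, file.path(cfg$out_dir, "pausing.tsv"))
      enriched_ids <- unique(unlist(groups))
      tgt_usage <- usage[usage$codon %in% cfg$target_codons, ]
      freq_sum <- tapply(tgt_usage$freq_per_1000, tgt_usage$gene_id, sum)
      usage_freq <- stats::setNames(as.numeric(freq_sum), names(freq_sum))
      run_counts <- vapply(genome, count_runs, numeric(1),
                           targets = cfg$target_codons, k = cfg$run_k)
      ct <- pausing_cross_tabs(pz$pausing, de, enriched_ids, usage_freq,
                               run_counts)
      pausing_section <- list(
        n_paused = sum(pz$pausing$paused),
        n_tested = nrow(pz$pausing),
        n_excluded = nrow(pz$excluded),
        cross_tabs = ct)
    }

    stage <- "report"
    report <- list(
      config = unclass(cfg),
      n_genes = length(genome),
      n_quantified = nrow(de),
      whole_proteome = whole,
      mrna_control = mrna_section,
      enrichment = enr,
      runs = run_section,
      pausing = pausing_section
    )
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(report)
  }, error = fail)
}
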