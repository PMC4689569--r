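# Group statistics for codon-enriched protein sets and resampling nulls
# with co-enrichment, mRNA-level and abundance-matched controls.

#' Members of a codon-enriched group
#'
#' Genes called over-represented for `codon` in the usage table,
#' intersected with the quantified proteome.
#'
#' @param usage Usage table from [codon_usage_table()].
#' @param codon Focal codon.
#' @param quantified Character vector of quantified gene ids (optional; if
#'   omitted the group is not intersected).
#' @return Character vector of member gene ids.
#' @export
codon_group <- function(usage, codon, quantified = NULL) {
  members <- usage$gene_id[usage$codon == codon & usage$call == "over"]
  if (!is.null(quantified)) members <- intersect(members, quantified)
  members
}

#' Down/up group statistics
#'
#' Counts significantly down- and up-regulated proteins in a group and
#' derives the percentage down-regulated and the D/U ratio (number down
#' divided by number up; NA with `du_defined = FALSE` when nothing is
#' up-regulated).
#'
#' @param members Character vector of gene ids.
#' @param calls data.frame with gene_id and call columns (from
#'   [differential_table()]).
#' @return List with n, n_down, n_up, percent_down, du, du_defined.
#' @export
group_stats <- function(members, calls) {
  cl <- calls$call[match(members, calls$gene_id)]
  if (anyNA(cl)) stop("every group member must have a DE call")
  n <- length(members)
  n_down <- sum(cl == "down")
  n_up <- sum(cl == "up")
  list(n = n, n_down = n_down, n_up = n_up,
       percent_down = if (n > 0) 100 * n_down / n else NA_real_,
       du = if (n_up > 0) n_down / n_up else NA_real_,
       du_defined = n_up > 0)
}

# group statistic from counts (used on resampled draws)
stat_from_counts <- function(n_down, n_up, n, statistic) {
  if (statistic == "percent_down") {
    100 * n_down / n
  } else {
    ifelse(n_up > 0, n_down / n_up, Inf)  # undefined D/U treated as extreme
  }
}

#' Resampling null for a group statistic
#'
#' Draws `n_samplings` random groups of the observed group's size, without
#' replacement, from the non-enriched complement pool, and computes the
#' percent-down and D/U statistics for each draw (both statistics come
#' from the same draws). The empirical p-value is the inclusive fraction
#' of draws whose statistic is at least the observed one; draws with an
#' undefined D/U (zero up-regulated proteins drawn) are counted as at
#' least as extreme.
#'
#' @param members Group gene ids.
#' @param pool Complement pool of gene ids (disjoint from the group, at
#'   least as large).
#' @param calls DE call table.
#' @param statistic "du" or "percent_down" (selects which null drives
#'   `empirical_p`; both nulls are returned).
#' @param n_samplings Number of random samplings.
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @return List with observed ([group_stats()]), statistic, n_samplings,
#'   null_values (the selected statistic, Inf marking undefined D/U),
#'   null_percent_down, null_du, empirical_p, empirical_p_percent_down,
#'   empirical_p_du, seed.
#' @export
resample_null <- function(members, pool, calls,
                          statistic = c("du", "percent_down"),
                          n_samplings = 100000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(intersect(members, pool)) > 0L) {
    stop("pool must be disjoint from the group")
  }
  if (length(pool) < length(members)) {
    stop("pool smaller than group: cannot sample without replacement")
  }
  obs <- group_stats(members, calls)
  cl <- calls$call[match(pool, calls$gene_id)]
  if (anyNA(cl)) stop("every pool member must have a DE call")
  down <- cl == "down"
  up <- cl == "up"
  m <- length(members)
  draw <- function() {
    nd <- integer(n_samplings)
    nu <- integer(n_samplings)
    P <- length(pool)
    for (s in seq_len(n_samplings)) {
      idx <- sample.int(P, m)
      nd[s] <- sum(down[idx])
      nu[s] <- sum(up[idx])
    }
    list(nd = nd, nu = nu)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  null_pd <- stat_from_counts(d$nd, d$nu, m, "percent_down")
  null_du <- stat_from_counts(d$nd, d$nu, m, "du")
  obs_pd <- obs$percent_down
  obs_du <- if (obs$du_defined) obs$du else Inf
  p_pd <- mean(null_pd >= obs_pd)
  p_du <- mean(null_du >= obs_du)
  list(observed = obs, statistic = statistic, n_samplings = n_samplings,
       null_values = if (statistic == "du") null_du else null_pd,
       null_percent_down = null_pd, null_du = null_du,
       empirical_p = if (statistic == "du") p_du else p_pd,
       empirical_p_percent_down = p_pd, empirical_p_du = p_du,
       seed = seed)
}

#' Co-enrichment exclusion analysis
#'
#' Removes, from the focal codon's group, proteins also enriched for a
#' second codon, and vice versa, then recomputes group statistics for both
#' reduced groups. Used to ask whether a group's down-regulation signal
#' survives removal of members whose effect could be attributed to
#' co-enrichment with the other codon.
#'
#' @param focal,other Distinct codons, both present in `groups`.
#' @param groups Named list of member gene-id vectors (one per codon).
#' @param calls DE call table.
#' @return List with `focal_minus_other` and `other_minus_focal`, each
#'   holding members, stats ([group_stats()] or NULL) and an `emptied`
#'   flag.
#' @export
exclusion_analysis <- function(focal, other, groups, calls) {
  if (focal == other) stop("focal and other codon must differ")
  f_members <- setdiff(groups[[focal]], groups[[other]])
  o_members <- setdiff(groups[[other]], groups[[focal]])
  side <- function(members) {
    list(members = members,
         stats = if (length(members) > 0L) group_stats(members, calls) else NULL,
         emptied = length(members) == 0L)
  }
  list(focal_minus_other = side(f_members),
       other_minus_focal = side(o_members))
}

# expression bins over the union of group and pool: quantile breaks with
# tied breaks collapsed, so identical abundances share a bin (and fully
# tied abundance degenerates to a single bin)
abundance_bins <- function(ids, abundance, n_bins) {
  a <- abundance[ids]
  if (anyNA(a)) stop("abundance missing for some proteins")
  breaks <- unique(stats::quantile(a, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2L) return(rep(1L, length(a)))
  cut(a, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

#' Abundance-matched resampling null
#'
#' As [resample_null()], but each random group preserves the observed
#' group's abundance-bin composition exactly: proteins are binned into
#' `n_bins` expression bins at quantile breaks of the union of group and
#' pool (tied breaks collapsed, so fully tied abundance degenerates to
#' one bin and plain resampling), and every sampling draws, per bin,
#' exactly the group's bin count from pool members of that bin.
#'
#' @inheritParams resample_null
#' @param abundance Named numeric vector of protein abundances covering
#'   group and pool.
#' @param n_bins Number of expression bins.
#' @return As [resample_null()], plus `bin_counts` (the group's preserved
#'   per-bin histogram).
#' @export
abundance_matched_null <- function(members, pool, abundance, calls,
                                   statistic = c("du", "percent_down"),
                                   n_bins = 10, n_samplings = 100000,
                                   seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(intersect(members, pool)) > 0L) {
    stop("pool must be disjoint from the group")
  }
  obs <- group_stats(members, calls)
  all_ids <- c(members, pool)
  bins <- abundance_bins(all_ids, abundance, n_bins)
  g_bins <- bins[seq_along(members)]
  p_bins <- bins[length(members) + seq_along(pool)]
  g_counts <- tabulate(g_bins, nbins = n_bins)
  p_counts <- tabulate(p_bins, nbins = n_bins)
  short <- which(p_counts < g_counts)
  if (length(short) > 0L) {
    stop(sprintf("abundance bin %d has %d pool proteins but %d group proteins",
                 short[1L], p_counts[short[1L]], g_counts[short[1L]]))
  }
  cl <- calls$call[match(pool, calls$gene_id)]
  if (anyNA(cl)) stop("every pool member must have a DE call")
  down <- cl == "down"
  up <- cl == "up"
  by_bin <- lapply(seq_len(n_bins), function(b) which(p_bins == b))
  m <- length(members)
  draw <- function() {
    nd <- integer(n_samplings)
    nu <- integer(n_samplings)
    for (s in seq_len(n_samplings)) {
      idx <- unlist(lapply(seq_len(n_bins), function(b) {
        if (g_counts[b] == 0L) return(integer(0))
        pb <- by_bin[[b]]
        pb[sample.int(length(pb), g_counts[b])]
      }), use.names = FALSE)
      nd[s] <- sum(down[idx])
      nu[s] <- sum(up[idx])
    }
    list(nd = nd, nu = nu)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  null_pd <- stat_from_counts(d$nd, d$nu, m, "percent_down")
  null_du <- stat_from_counts(d$nd, d$nu, m, "du")
  obs_du <- if (obs$du_defined) obs$du else Inf
  p_pd <- mean(null_pd >= obs$percent_down)
  p_du <- mean(null_du >= obs_du)
  list(observed = obs, statistic = statistic, n_samplings = n_samplings,
       null_values = if (statistic == "du") null_du else null_pd,
       null_percent_down = null_pd, null_du = null_du,
       empirical_p = if (statistic == "du") p_du else p_pd,
       empirical_p_percent_down = p_pd, empirical_p_du = p_du,
       bin_counts = g_counts, seed = seed)
}

#' Remove proteins whose change is explained by mRNA-level change
#'
#' A significantly changed protein is removed when its mRNA changed in the
#' same direction with |fold| > `fc` and p < `alpha` (mirroring the
#' protein-level significance rule). Proteins absent from the mRNA table
#' pass through.
#'
#' @param calls DE call table.
#' @param mrna data.frame with gene_id, log2fc, p columns.
#' @param fc,alpha mRNA-level fold and significance thresholds.
#' @return List with `calls` (filtered table), `n_removed`, `removed_ids`.
#' @export
mrna_filter <- function(calls, mrna, fc = 1.2, alpha = 0.05) {
  i <- match(calls$gene_id, mrna$gene_id)
  lfc <- mrna$log2fc[i]
  p <- mrna$p[i]
  sig <- !is.na(lfc) & !is.na(p) & abs(lfc) > log2(fc) & p < alpha
  same_dir <- (calls$call == "down" & lfc < 0) |
              (calls$call == "up" & lfc > 0)
  remove <- calls$call != "unchanged" & sig & !is.na(same_dir) & same_dir
  list(calls = calls[!remove, , drop = FALSE],
       n_removed = sum(remove),
       removed_ids = calls$gene_id[remove])
}

#' Group statistics in codon-frequency bins
#'
#' Bins quantified proteins by a codon's frequency per 1000 codons into
#' left-closed bins [0,10), [10,20), ... with the last bin open-ended, and
#' computes down/up group statistics per bin.
#'
#' @param calls DE call table.
#' @param usage Usage table from [codon_usage_table()].
#' @param codon Focal codon.
#' @param bin_width Bin width in codons per 1000.
#' @param n_bins Number of bins (last bin open-ended).
#' @return data.frame with bin, freq_lo, freq_hi, mean_freq, n, n_down,
#'   n_up, percent_down, du (NA where undefined).
#' @export
bin_by_frequency <- function(calls, usage, codon, bin_width = 10,
                             n_bins = 7) {
  u <- usage[usage$codon == codon, c("gene_id", "freq_per_1000")]
  freq <- u$freq_per_1000[match(calls$gene_id, u$gene_id)]
  keep <- !is.na(freq)
  calls <- calls[keep, , drop = FALSE]
  freq <- freq[keep]
  bin <- pmin(floor(freq / bin_width) + 1L, n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    gs <- if (any(sel)) group_stats(calls$gene_id[sel], calls) else NULL
    data.frame(
      bin = b,
      freq_lo = (b - 1) * bin_width,
      freq_hi = if (b < n_bins) b * bin_width else Inf,
      mean_freq = if (any(sel)) mean(freq[sel]) else NA_real_,
      n = if (is.null(gs)) 0L else gs$n,
      n_down = if (is.null(gs)) 0L else gs$n_down,
      n_up = if (is.null(gs)) 0L else gs$n_up,
      percent_down = if (is.null(gs)) NA_real_ else gs$percent_down,
      du = if (is.null(gs) || !gs$du_defined) NA_real_ else gs$du
    )
  })
  do.call(rbind, rows)
}

#' Spearman correlation between codon frequency and protein change
#'
#' Rank correlation between a codon's per-gene frequency and the per-gene
#' protein log2 fold change, with a two-sided p-value from the t
#' approximation.
#'
#' @param freq Per-gene codon frequency (per 1000).
#' @param log2fc Per-gene protein log2 fold change (paired with `freq`).
#' @return List with rho and p_value.
#' @export
freq_change_correlation <- function(freq, log2fc) {
  ok <- !is.na(freq) & !is.na(log2fc)
  freq <- freq[ok]
  log2fc <- log2fc[ok]
  if (length(freq) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(freq) == 0 || stats::sd(log2fc) == 0) {
    stop("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(freq, log2fc, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
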