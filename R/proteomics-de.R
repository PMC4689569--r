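# SILAC-style differential proteomics: peptide-to-protein aggregation,
# replicate filtering, and two-strain differential-expression calls.

#' Protein ratio from peptide ratios
#'
#' A protein's SILAC ratio in one replicate is the arithmetic mean of all
#' peptide ratios assigned to it.
#'
#' @param peptide_ratios Numeric vector of positive peptide ratios.
#' @return Mean ratio, or NA if the vector is empty (missing replicate).
#' @export
protein_ratio <- function(peptide_ratios) {
  if (length(peptide_ratios) == 0L) return(NA_real_)
  if (any(peptide_ratios <= 0)) stop("peptide ratios must be positive")
  mean(peptide_ratios)
}

#' Relative standard deviation
#'
#' |sample standard deviation / mean|, the replicate-reproducibility
#' measure used for SILAC ratios.
#'
#' @param values Numeric vector (>= 2 values, mean != 0).
#' @return Non-negative RSD.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero: RSD undefined")
  abs(stats::sd(values) / m)
}

# column helpers for the wide replicate-table layout
wt_cols <- function(df) grep("^wt_r", names(df), value = TRUE)
mut_cols <- function(df) grep("^mut_r", names(df), value = TRUE)

#' Filter proteins by replicate support
#'
#' Retains proteins quantified (non-missing ratio) in at least `min_reps`
#' replicates of each strain.
#'
#' @param quants data.frame with a gene_id column and replicate ratio
#'   columns named wt_r1..wt_rk and mut_r1..mut_rk (NA = missing).
#' @param min_reps Minimum replicates per strain.
#' @return Filtered data.frame.
#' @export
replicate_filter <- function(quants, min_reps = 2) {
  nw <- rowSums(!is.na(quants[, wt_cols(quants), drop = FALSE]))
  nm <- rowSums(!is.na(quants[, mut_cols(quants), drop = FALSE]))
  quants[nw >= min_reps & nm >= min_reps, , drop = FALSE]
}

#' Differential-expression call for one protein
#'
#' Two-sample, two-sided, equal-variance Student t-test on the log2
#' replicate ratios, with the fold change computed from the linear-scale
#' replicate means (mut/wt). The call is "down" if fold_change < 1/fc and
#' p < alpha, "up" if fold_change > fc and p < alpha, else "unchanged";
#' both fold thresholds are strict.
#'
#' @param ratios_wt,ratios_mut Positive replicate ratios (>= 2 each).
#' @param alpha Significance cutoff.
#' @param fc Fold-change threshold (> 1).
#' @return List with fold_change, p_value, call.
#' @export
differential_call <- function(ratios_wt, ratios_mut, alpha = 0.05,
                              fc = 1.2) {
  ratios_wt <- ratios_wt[!is.na(ratios_wt)]
  ratios_mut <- ratios_mut[!is.na(ratios_mut)]
  if (length(ratios_wt) < 2L || length(ratios_mut) < 2L) {
    stop("need >= 2 replicates per strain (apply replicate_filter first)")
  }
  fold <- mean(ratios_mut) / mean(ratios_wt)
  x <- log2(ratios_wt)
  y <- log2(ratios_mut)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
  } else {
    p <- stats::t.test(y, x, var.equal = TRUE)$p.value
  }
  call <- if (p < alpha && fold < 1 / fc) "down"
          else if (p < alpha && fold > fc) "up"
          else "unchanged"
  list(fold_change = fold, p_value = p, call = call)
}

#' Differential-expression table for a quantified proteome
#'
#' Vectorised equivalent of [differential_call()] applied to every row of
#' a replicate-ratio table (equal-variance t on log2 ratios; linear-scale
#' fold change; strict two-sided fold thresholds).
#'
#' @param quants data.frame with gene_id, wt_r*/mut_r* ratio columns and
#'   optionally an abundance column (carried through).
#' @param alpha Significance cutoff.
#' @param fc Fold-change threshold.
#' @param min_reps Replicate filter applied before testing.
#' @return data.frame with gene_id, fold_change, p_value, call (plus
#'   abundance if present in the input).
#' @export
differential_table <- function(quants, alpha = 0.05, fc = 1.2,
                               min_reps = 2) {
  quants <- replicate_filter(quants, min_reps)
  W <- as.matrix(quants[, wt_cols(quants), drop = FALSE])
  M <- as.matrix(quants[, mut_cols(quants), drop = FALSE])
  fold <- rowMeans(M, na.rm = TRUE) / rowMeans(W, na.rm = TRUE)
  X <- log2(W)
  Y <- log2(M)
  n1 <- rowSums(!is.na(X))
  n2 <- rowSums(!is.na(Y))
  m1 <- rowMeans(X, na.rm = TRUE)
  m2 <- rowMeans(Y, na.rm = TRUE)
  v1 <- apply(X, 1, stats::var, na.rm = TRUE)
  v2 <- apply(Y, 1, stats::var, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate: zero pooled variance
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  call <- ifelse(p < alpha & fold < 1 / fc, "down",
          ifelse(p < alpha & fold > fc, "up", "unchanged"))
  out <- data.frame(gene_id = quants$gene_id, fold_change = fold,
                    p_value = p, call = call, stringsAsFactors = FALSE)
  if ("abundance" %in% names(quants)) out$abundance <- quants$abundance
  rownames(out) <- NULL
  out
}
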