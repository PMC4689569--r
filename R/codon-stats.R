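# Gene-specific codon usage: parsing, counting, and hypergeometric
# enrichment against the genome-wide codon pool.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons
#'
#' All 64 DNA triplets minus the three stop codons (TAA, TAG, TGA), in
#' alphabetical order. Stop codons are excluded from counting and from the
#' codon universe throughout the package; the terminal stop is stripped at
#' parse time.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, STOP_CODONS))
}

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, STOP_CODONS))
})

#' Parse a coding sequence into in-frame codons
#'
#' Splits a nucleotide string into consecutive triplets, strips a terminal
#' stop codon if present, and validates that what remains is a clean open
#' reading frame over the 61 sense codons.
#'
#' @param sequence Single nucleotide string (alphabet ACGT).
#' @param gene_id Identifier used in error messages and as the `gene_id`
#'   attribute of the result.
#' @return Character vector of 3-letter sense codons with attribute
#'   `gene_id`.
#'
#' Fails with an informative error (naming the gene) if the length is not a
#' multiple of 3, the alphabet contains anything but ACGT, an internal stop
#' codon is present, or no sense codon remains after stop removal.
#' @examples
#' parse_codons("ATGAGAGAATAA", "demo")  # ATG AGA GAA, stop dropped
#' @export
parse_codons <- function(sequence, gene_id = "gene") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    stop(sprintf("gene '%s': sequence length %d is not a multiple of 3",
                 gene_id, n))
  }
  if (grepl("[^ACGT]", sequence)) {
    stop(sprintf("gene '%s': sequence contains characters outside ACGT",
                 gene_id))
  }
  codons <- substring(sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  k <- length(codons)
  if (codons[k] %in% STOP_CODONS) codons <- codons[-k]
  if (length(codons) == 0L) {
    stop(sprintf("gene '%s': no sense codons after stop removal", gene_id))
  }
  if (any(codons %in% STOP_CODONS)) {
    stop(sprintf("gene '%s': internal stop codon at codon position %d",
                 gene_id, which(codons %in% STOP_CODONS)[1L]))
  }
  attr(codons, "gene_id") <- gene_id
  codons
}

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA of coding sequences and parses each record
#' with [parse_codons()]. The record identifier up to the first whitespace
#' is the gene id. Records that fail validation (out-of-frame length,
#' internal stop, ambiguous bases) are dropped with one summary warning
#' rather than aborting the run.
#'
#' @param path Path to a FASTA file.
#' @return Named list of codon vectors, one element per accepted gene.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- as.character(seqs)
  out <- vector("list", length(chars))
  ok <- logical(length(chars))
  msgs <- character(0)
  for (i in seq_along(chars)) {
    res <- tryCatch(parse_codons(chars[[i]], ids[[i]]), error = identity)
    if (inherits(res, "error")) {
      msgs <- c(msgs, conditionMessage(res))
    } else {
      out[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (length(msgs) > 0L) {
    warning(sprintf("dropped %d of %d records: %s", length(msgs),
                    length(chars), paste(msgs, collapse = "; ")))
  }
  stats::setNames(out[ok], ids[ok])
}

#' Count a codon in a gene
#'
#' @param codons Codon vector from [parse_codons()].
#' @param codon A single sense codon.
#' @return List with `count` and `freq_per_1000` (1000 * count / length).
#' @export
codon_frequency <- function(codons, codon) {
  if (!codon %in% SENSE_CODONS) {
    stop(sprintf("'%s' is not a sense codon", codon))
  }
  k <- sum(codons == codon)
  list(count = k, freq_per_1000 = 1000 * k / length(codons))
}

# genes x 61 count matrix; rows named by gene
codon_count_matrix <- function(genome) {
  m <- t(vapply(genome, function(cd) {
    tabulate(match(cd, SENSE_CODONS), nbins = length(SENSE_CODONS))
  }, integer(length(SENSE_CODONS))))
  colnames(m) <- SENSE_CODONS
  m
}

#' Aggregate the genome-wide codon pool
#'
#' Sums sense-codon counts over all genes (including any focal gene later
#' scored against the pool, so the pool is gene-independent and cacheable).
#'
#' @param genome Named list of codon vectors.
#' @return List with `N` (total codons) and `K` (named per-codon totals
#'   over the 61 sense codons).
#' @export
build_pool <- function(genome) {
  if (length(genome) == 0L) stop("empty genome: cannot build codon pool")
  m <- codon_count_matrix(genome)
  K <- colSums(m)
  list(N = sum(K), K = K)
}

#' Hypergeometric enrichment score
#'
#' Scores an observed codon count `k` in a gene of `n` codons against a
#' genome pool of `N` codons of which `K` are the focal codon. The Z-score
#' is the deviation from the expected count n*K/N divided by the
#' hypergeometric (finite-population-corrected) standard deviation; the
#' tail probabilities are exact inclusive hypergeometric tails,
#' P(X >= k) and P(X <= k).
#'
#' All arguments may be vectors (recycled to a common length).
#'
#' @param k Observed count(s) of the codon in the gene.
#' @param n Gene length(s) in codons.
#' @param K Pool count(s) of the codon.
#' @param N Pool total codon count(s).
#' @return List with numeric `z` (NA where the variance is degenerate,
#'   i.e. n = N, K = 0 or K = N), `p_over`, `p_under`.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  if (any(n > N)) stop("need n <= N")
  if (any(K > N)) stop("need K <= N")
  mu <- n * K / N
  v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  z <- ifelse(v > 0, (k - mu) / sqrt(v), NA_real_)
  z[v > 0 & k == mu] <- 0  # exact zero when observed equals expectation
  p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_under <- stats::phyper(k, K, N - K, n)
  list(z = z, p_over = p_over, p_under = p_under)
}

#' Call over/under-representation from tail probabilities
#'
#' @param p_over,p_under Inclusive upper/lower tail probabilities.
#' @param alpha Significance cutoff; the comparison is strict (`p < alpha`).
#' @return Character vector of calls: "over", "under" or "none".
#' @export
call_enrichment <- function(p_over, p_under, alpha = 0.01) {
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  over <- p_over < alpha
  under <- p_under < alpha
  if (any(over & under)) {
    stop("both tails significant: inconsistent tail probabilities")
  }
  ifelse(over, "over", ifelse(under, "under", "none"))
}

#' Per-gene, per-codon usage and enrichment table
#'
#' Computes, for every gene and every sense codon, the count, the
#' frequency per 1000 codons, the hypergeometric Z-score and exact tail
#' probabilities against the genome pool, and the enrichment call at
#' `alpha`.
#'
#' @param genome Named list of codon vectors (see [read_cds_fasta()]).
#' @param alpha Enrichment cutoff applied strictly to each tail.
#' @param pool Optional precomputed pool from [build_pool()]; defaults to
#'   the pool of `genome` itself.
#' @return data.frame with columns gene_id, codon, count, length,
#'   freq_per_1000, z, p_over, p_under, call.
#' @export
codon_usage_table <- function(genome, alpha = 0.01, pool = NULL) {
  if (length(genome) == 0L) stop("empty genome")
  if (is.null(pool)) pool <- build_pool(genome)
  m <- codon_count_matrix(genome)
  lens <- lengths(genome)
  nc <- length(SENSE_CODONS)
  k <- as.vector(t(m))                        # gene-major order
  n <- rep(lens, each = nc)
  K <- rep(pool$K[SENSE_CODONS], times = length(genome))
  h <- hypergeom_enrichment(k, n, K, pool$N)
  data.frame(
    gene_id = rep(names(genome), each = nc),
    codon = rep(SENSE_CODONS, times = length(genome)),
    count = k,
    length = n,
    freq_per_1000 = 1000 * k / n,
    z = h$z,
    p_over = h$p_over,
    p_under = h$p_under,
    call = call_enrichment(h$p_over, h$p_under, alpha),
    stringsAsFactors = FALSE
  )
}
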