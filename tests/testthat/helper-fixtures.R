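# Shared fixture builders; everything is generated in code.

# DE call table with fixed down/up counts (remaining genes unchanged)
make_calls <- function(n, n_down, n_up, prefix = "p") {
  ids <- paste0(prefix, seq_len(n))
  call <- c(rep("down", n_down), rep("up", n_up),
            rep("unchanged", n - n_down - n_up))
  data.frame(gene_id = ids, call = call, stringsAsFactors = FALSE)
}

# random gene as a codon vector, codons drawn uniformly from the 61
random_gene <- function(len, seed = NULL) {
  draw <- function() sample(sense_codons(), len, replace = TRUE)
  if (is.null(seed)) draw() else codonbias:::with_seed(seed, draw())
}

# named list of random genes
random_genome <- function(n_genes, len = 100, seed = 1) {
  codonbias:::with_seed(seed, {
    g <- lapply(seq_len(n_genes), function(i) {
      sample(sense_codons(), len, replace = TRUE)
    })
    names(g) <- sprintf("g%03d", seq_len(n_genes))
    g
  })
}

# exact hypergeometric tail probabilities by pmf enumeration over all
# outcomes, built from choose() only (independent of phyper)
enum_hyper_tails <- function(k, n, K, N) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  xs <- lo:hi
  pmf <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  list(p_over = sum(pmf[xs >= k]), p_under = sum(pmf[xs <= k]))
}
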