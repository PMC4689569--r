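# Shared internal helpers: seed handling and table I/O.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed for stream `i` derived from a master seed,
# so any single gene's stream is reproducible in isolation.
derive_seed <- function(master_seed, i) {
  (as.double(master_seed) * 48271 + as.double(i) * 10007) %% 2147483629
}

#' Write a tab-separated table
#'
#' Plain TSV writer used for all tabular outputs. Any coordinates in the
#' written tables are 0-based codon indices with half-open windows, stated
#' in a leading comment line.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param comment Optional comment line (written prefixed with "# ").
#' @export
write_tsv_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path; lines starting with "#" are ignored.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
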