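# In-code fixtures shared across test files.

# deterministic ACGT string for clone i (no randomness; unique per i)
fake_cdr3 <- function(i, len = 30L) {
  stopifnot(len %% 3L == 0L)
  digits <- integer(len - 3L)
  x <- i
  for (k in seq_along(digits)) { digits[k] <- x %% 3L; x <- x %/% 3L }
  # base-3 body over {A,C,G}: stop codons all need a T, so always in frame
  paste0("TGT", paste(c("A", "C", "G")[digits + 1L], collapse = ""))
}

# quick clonotype table builder: one chain, given counts; `offset` makes
# the CDR3 identities distinct from other tables built with this helper
make_clones <- function(counts, chain = "TRB", prefix = "c", offset = 0L,
                        v_gene = NULL, j_gene = NULL) {
  n <- length(counts)
  clonotype_table(
    clone_id = paste0(prefix, seq_len(n)),
    chain = chain,
    cdr3_nt = vapply(offset + seq_len(n), fake_cdr3, ""),
    read_count = counts,
    v_gene = if (is.null(v_gene)) paste0(chain, "V", (seq_len(n) %% 10) + 1)
             else v_gene,
    j_gene = if (is.null(j_gene)) paste0(chain, "J", (seq_len(n) %% 5) + 1)
             else j_gene
  )
}

make_sample <- function(counts, total_mapped_reads = 1e6, chain = "TRB",
                        sample_id = "S1", ...) {
  repertoire_sample(sample_id, make_clones(counts, chain = chain),
                    total_mapped_reads, ...)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
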