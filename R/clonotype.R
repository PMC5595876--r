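#' @keywords internal
"_PACKAGE"

TCR_CHAINS <- c("TRA", "TRB", "TRG", "TRD")
PRODUCTIVITY_LEVELS <- c("productive", "nonproductive", "unknown")
TARGET_CLASSES <- c("same_tcr_locus", "other_tcr_locus", "non_tcr")

#' Construct a clonotype table
#'
#' A clonotype is one CDR3-defined clone on one TCR chain with a read count,
#' V/(D)/J gene assignments and a productivity annotation. Clonotype tables
#' are plain data frames with a fixed column set; this constructor validates
#' the invariants every downstream operation assumes.
#'
#' @param clone_id character, unique clone identifiers.
#' @param chain character, one of `"TRA"`, `"TRB"`, `"TRG"`, `"TRD"`.
#' @param cdr3_nt character, CDR3 nucleotide sequences over A/C/G/T.
#' @param read_count positive integer read counts.
#' @param v_gene,j_gene character, gene assignments.
#' @param d_gene character, D assignment or `""`.
#' @param cdr3_aa character, amino-acid sequence or `""`.
#' @param productive one of `"productive"`, `"nonproductive"`, `"unknown"`;
#'   if `NA`, annotated from `cdr3_nt` via [annotate_productivity()].
#' @return A `data.frame` with class `c("clonotype_tbl", "data.frame")`.
#' @seealso [read_clonotype_table()], [annotate_productivity()]
#' @export
clonotype_table <- function(clone_id, chain, cdr3_nt, read_count,
                            v_gene, j_gene, d_gene = "", cdr3_aa = "",
                            productive = NA_character_) {
  n <- length(clone_id)
  df <- data.frame(
    clone_id = as.character(clone_id),
    chain = as.character(chain),
    cdr3_nt = toupper(as.character(cdr3_nt)),
    cdr3_aa = rep_len(as.character(cdr3_aa), n),
    v_gene = as.character(v_gene),
    d_gene = rep_len(as.character(d_gene), n),
    j_gene = as.character(j_gene),
    read_count = as.integer(read_count),
    productive = rep_len(as.character(productive), n),
    stringsAsFactors = FALSE
  )
  needs <- is.na(df$productive)
  if (any(needs)) {
    df$productive[needs] <- annotate_productivity(df$cdr3_nt[needs])
  }
  validate_clonotypes(df)
}

#' Validate a clonotype table
#'
#' Checks the clonotype invariants: positive read counts, CDR3 over the DNA
#' alphabet, known chains, and frame-consistency for clones flagged
#' productive.
#'
#' @param df a data.frame with the clonotype columns.
#' @return `df`, classed `clonotype_tbl`, invisibly unchanged otherwise.
#' @export
validate_clonotypes <- function(df) {
  required <- c("clone_id", "chain", "cdr3_nt", "v_gene", "j_gene",
                "read_count", "productive")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("clonotype table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$clone_id)) {
    stop("duplicate clone_id in clonotype table: ",
         paste(unique(df$clone_id[duplicated(df$clone_id)]), collapse = ", "))
  }
  bad_chain <- !df$chain %in% TCR_CHAINS
  if (any(bad_chain)) {
    stop("unknown chain(s): ", paste(unique(df$chain[bad_chain]), collapse = ", "))
  }
  if (any(df$read_count < 1L | is.na(df$read_count))) {
    stop("read_count must be a positive integer for every clonotype")
  }
  bad_nt <- !grepl("^[ACGT]+$", df$cdr3_nt)
  if (any(bad_nt)) {
    stop("non-ACGT CDR3 nucleotide sequence at row(s): ",
         paste(which(bad_nt), collapse = ", "))
  }
  bad_prod <- !df$productive %in% PRODUCTIVITY_LEVELS
  if (any(bad_prod)) {
    stop("productive must be one of ", paste(PRODUCTIVITY_LEVELS, collapse = "/"))
  }
  frame_bad <- df$productive == "productive" & nchar(df$cdr3_nt) %% 3L != 0L
  if (any(frame_bad)) {
    stop("clone(s) flagged productive with CDR3 length not a multiple of 3: ",
         paste(df$clone_id[frame_bad], collapse = ", "))
  }
  class(df) <- unique(c("clonotype_tbl", class(df)))
  df
}

#' Construct a repertoire sample
#'
#' Bundles one sample's clonotypes with its library size (total mapped reads,
#' the denominator of the RPM statistic) and the per-sample metadata used in
#' cohort summaries.
#'
#' @param sample_id sample identifier.
#' @param clonotypes a clonotype table (see [clonotype_table()]).
#' @param total_mapped_reads positive integer; total RNA-seq reads mapped to
#'   the genome. Must be at least the sum of clonotype read counts.
#' @param subtype sample subtype label (e.g. `"AITL"`, `"PTCL-NOS"`,
#'   `"normal"`).
#' @param mutation_positive optional logical; lymphoma-associated mutation
#'   status.
#' @param ebv_read_count optional non-negative integer of EBV-mapped reads.
#' @return An object of class `repertoire_sample`.
#' @export
repertoire_sample <- function(sample_id, clonotypes, total_mapped_reads,
                              subtype = "unknown", mutation_positive = NA,
                              ebv_read_count = NA_integer_) {
  clonotypes <- validate_clonotypes(clonotypes)
  total_mapped_reads <- as.double(total_mapped_reads)
  if (length(total_mapped_reads) != 1L || is.na(total_mapped_reads) ||
      total_mapped_reads < 1) {
    stop("total_mapped_reads must be a single positive integer")
  }
  if (total_mapped_reads < sum(clonotypes$read_count)) {
    stop("total_mapped_reads (", total_mapped_reads,
         ") is smaller than the sum of clonotype read counts (",
         sum(clonotypes$read_count), ")")
  }
  if (!is.na(ebv_read_count) && ebv_read_count < 0) {
    stop("ebv_read_count must be non-negative")
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      subtype = as.character(subtype),
      clonotypes = clonotypes,
      total_mapped_reads = total_mapped_reads,
      mutation_positive = as.logical(mutation_positive),
      ebv_read_count = as.integer(ebv_read_count)
    ),
    class = "repertoire_sample"
  )
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat("Repertoire sample", x$sample_id, "(", x$subtype, ")\n")
  cat("  clonotypes:", nrow(x$clonotypes), "on chain(s)",
      paste(sort(unique(x$clonotypes$chain)), collapse = ", "), "\n")
  cat("  total mapped reads:", format(x$total_mapped_reads, big.mark = ","), "\n")
  if (!is.na(x$mutation_positive))
    cat("  mutation positive:", x$mutation_positive, "\n")
  if (!is.na(x$ebv_read_count))
    cat("  EBV-mapped reads:", x$ebv_read_count, "\n")
  invisible(x)
}

#' Construct an alignment-hit table
#'
#' One row per query-to-target match, with the target classified relative to
#' the TCR locus the query was reported on, and the match fraction (matched
#' bases divided by query length).
#'
#' @param query_id character read or clone identifiers.
#' @param target_class one of `"same_tcr_locus"`, `"other_tcr_locus"`,
#'   `"non_tcr"`.
#' @param match_fraction numeric in \[0, 1\].
#' @return A `data.frame` classed `alignment_hits`.
#' @export
alignment_hits <- function(query_id, target_class, match_fraction) {
  df <- data.frame(
    query_id = as.character(query_id),
    target_class = as.character(target_class),
    match_fraction = as.double(match_fraction),
    stringsAsFactors = FALSE
  )
  bad <- !df$target_class %in% TARGET_CLASSES
  if (any(bad)) {
    stop("unknown target_class: ",
         paste(unique(df$target_class[bad]), collapse = ", "))
  }
  if (any(df$match_fraction < 0 | df$match_fraction > 1 |
          is.na(df$match_fraction))) {
    stop("match_fraction must lie in [0, 1]")
  }
  class(df) <- unique(c("alignment_hits", class(df)))
  df
}

#' Construct a V-gene usage vector
#'
#' Normalized expression (FPKM-style) of the V genes of one chain in one
#' sample, used by the V-usage clonality rule.
#'
#' @param sample_id sample identifier.
#' @param chain one of the four TCR chains.
#' @param values named non-negative numeric vector, names are V-gene names.
#' @return An object of class `vusage_vector`.
#' @export
vusage_vector <- function(sample_id, chain, values) {
  chain <- match.arg(chain, TCR_CHAINS)
  values <- unlist(values)
  if (length(values) && (is.null(names(values)) || any(!nzchar(names(values)))))
    stop("V-usage values must be named by gene")
  if (any(values < 0 | is.na(values))) stop("V-usage values must be >= 0")
  structure(
    list(sample_id = as.character(sample_id), chain = chain,
         values = values),
    class = "vusage_vector"
  )
}

# chain from V-gene name prefix; NA for anything that is not TRAV/TRBV/TRGV/TRDV
chain_from_vgene <- function(v_gene) {
  pre <- substr(v_gene, 1L, 4L)
  out <- rep(NA_character_, length(v_gene))
  hit <- pre %in% paste0(TCR_CHAINS, "V")
  out[hit] <- substr(pre[hit], 1L, 3L)
  out
}
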