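# Reading and writing of external representations: clonotype tables (native
# and MiXCR-style), alignment hit records (PSL or native), FPKM matrices,
# sample sheets, and the clonality report.

NATIVE_CLONE_COLS <- c("clone_id", "cdr3_nt", "cdr3_aa", "v_gene", "d_gene",
                       "j_gene", "read_count", "productive")
MIXCR_CLONE_COLS <- c("cloneCount", "nSeqCDR3", "aaSeqCDR3",
                      "allVHitsWithScore", "allJHitsWithScore")

# "TRBV20-1*00(1234.5)" / "TRBV20-1*00" / "TRBV20-1" -> "TRBV20-1"
strip_gene_hit <- function(x) {
  first <- vapply(strsplit(x, ",", fixed = TRUE), `[`, "", 1L)
  sub("\\*.*$", "", sub("\\(.*$", "", first))
}

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table in either the package's native
#' dialect (columns `clone_id`, `cdr3_nt`, `read_count`, `v_gene`, `j_gene`,
#' optionally `cdr3_aa`, `d_gene`, `productive`) or a MiXCR-style export
#' (`cloneCount`, `nSeqCDR3`, `aaSeqCDR3`, `allVHitsWithScore`,
#' `allJHitsWithScore`, ...). The dialect is detected from the header unless
#' forced. The chain of each clone is inferred from the V-gene name prefix
#' (TRAV/TRBV/TRGV/TRDV); rows whose V gene carries any other prefix are an
#' error. Rows with zero counts are dropped with a warning; productivity is
#' annotated from the nucleotide sequence when the table lacks a
#' `productive` column.
#'
#' @param path path to a TSV file.
#' @param dialect `"auto"` (default), `"native"` or `"mixcr"`.
#' @return A validated clonotype table (see [clonotype_table()]). Columns of
#'   the input not in the native schema are preserved as extra columns.
#' @export
read_clonotype_table <- function(path, dialect = c("auto", "native", "mixcr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("clonotype table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "auto") {
    dialect <- if (all(MIXCR_CLONE_COLS %in% names(raw))) "mixcr" else "native"
  }
  if (dialect == "mixcr") {
    miss <- setdiff(MIXCR_CLONE_COLS, names(raw))
    if (length(miss)) {
      stop("MiXCR clonotype table ", path, " is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    d_raw <- if ("allDHitsWithScore" %in% names(raw)) raw$allDHitsWithScore else ""
    d_raw[is.na(d_raw)] <- ""
    id <- if ("cloneId" %in% names(raw)) as.character(raw$cloneId)
          else sprintf("clone%04d", seq_len(nrow(raw)))
    df <- data.frame(
      clone_id = id,
      cdr3_nt = toupper(raw$nSeqCDR3),
      cdr3_aa = ifelse(is.na(raw$aaSeqCDR3), "", raw$aaSeqCDR3),
      v_gene = strip_gene_hit(raw$allVHitsWithScore),
      d_gene = ifelse(nzchar(d_raw), strip_gene_hit(d_raw), ""),
      j_gene = strip_gene_hit(raw$allJHitsWithScore),
      read_count = raw$cloneCount,
      productive = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    needed <- c("clone_id", "cdr3_nt", "read_count", "v_gene", "j_gene")
    miss <- setdiff(needed, names(raw))
    if (length(miss)) {
      stop("clonotype table ", path, " is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    df <- data.frame(
      clone_id = as.character(raw$clone_id),
      cdr3_nt = toupper(raw$cdr3_nt),
      cdr3_aa = if ("cdr3_aa" %in% names(raw)) as.character(raw$cdr3_aa) else "",
      v_gene = as.character(raw$v_gene),
      d_gene = if ("d_gene" %in% names(raw)) as.character(raw$d_gene) else "",
      j_gene = as.character(raw$j_gene),
      read_count = raw$read_count,
      productive = if ("productive" %in% names(raw))
        as.character(raw$productive) else NA_character_,
      stringsAsFactors = FALSE
    )
    extra <- setdiff(names(raw), NATIVE_CLONE_COLS)
    for (col in extra) df[[col]] <- raw[[col]]
  }
  df$d_gene[is.na(df$d_gene)] <- ""
  df$cdr3_aa[is.na(df$cdr3_aa)] <- ""

  zero <- df$read_count < 1 | is.na(df$read_count)
  if (any(zero)) {
    warning(sum(zero), " row(s) with zero or missing read count rejected in ",
            path)
    df <- df[!zero, , drop = FALSE]
  }
  df$read_count <- as.integer(round(df$read_count))

  bad_nt <- !grepl("^[ACGT]+$", df$cdr3_nt)
  if (any(bad_nt)) {
    stop("non-ACGT character in CDR3 at row(s) ",
         paste(which(bad_nt), collapse = ", "), " of ", path)
  }
  df$chain <- chain_from_vgene(df$v_gene)
  if (anyNA(df$chain)) {
    stop("cannot infer chain from V gene(s): ",
         paste(unique(df$v_gene[is.na(df$chain)]), collapse = ", "))
  }
  needs <- is.na(df$productive)
  if (any(needs)) df$productive[needs] <- annotate_productivity(df$cdr3_nt[needs])
  rownames(df) <- NULL
  validate_clonotypes(df)
}

#' Write a clonotype table in the native dialect
#'
#' @param clones a clonotype table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(clones, path) {
  clones <- validate_clonotypes(clones)
  cols <- c("clone_id", "chain", "cdr3_nt", "cdr3_aa", "v_gene", "d_gene",
            "j_gene", "read_count", "productive")
  utils::write.table(clones[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default TCR locus classification table
#'
#' Maps alignment target names to TCR loci by name pattern. Targets matching
#' no pattern are non-TCR. Coordinate-based rows (`chrom`, `start`, `end`,
#' 0-based half-open) may be added for PSL targets named by chromosome.
#'
#' @return A data.frame with columns `pattern` and `locus`.
#' @export
default_locus_table <- function() {
  data.frame(pattern = c("TRA", "TRB", "TRG", "TRD"),
             locus = c("TRA", "TRB", "TRG", "TRD"),
             stringsAsFactors = FALSE)
}

classify_target <- function(target_name, reported_locus, locus_table) {
  target_locus <- rep(NA_character_, length(target_name))
  for (i in seq_len(nrow(locus_table))) {
    hit <- is.na(target_locus) & grepl(locus_table$pattern[i], target_name)
    target_locus[hit] <- locus_table$locus[i]
  }
  out <- rep("non_tcr", length(target_name))
  is_tcr <- !is.na(target_locus)
  out[is_tcr] <- ifelse(target_locus[is_tcr] == reported_locus[is_tcr],
                        "same_tcr_locus", "other_tcr_locus")
  out
}

#' Read alignment hits
#'
#' Reads either a BLAT PSL file (tab format; `matches` in column 1, query
#' name/size in columns 10/11, target name in column 14) or the native
#' three-column TSV (`query_id`, `target_class`, `match_fraction`). For PSL
#' input the match fraction is matched bases divided by query size, and the
#' target class is derived from `locus_table` together with the locus each
#' query was reported on (`reported_locus`, a named vector); a query absent
#' from `reported_locus` has no same-locus targets.
#'
#' @param path input path.
#' @param reported_locus named character vector, query id to reported TCR
#'   locus; used for PSL input only.
#' @param locus_table see [default_locus_table()].
#' @return An [alignment_hits()] table.
#' @export
read_alignment_hits <- function(path, reported_locus = NULL,
                                locus_table = default_locus_table()) {
  if (!file.exists(path)) stop("alignment hit file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(fields) >= 3 && all(c("query_id", "target_class",
                                   "match_fraction") %in% fields)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(alignment_hits(df$query_id, df$target_class, df$match_fraction))
  }
  # PSL: skip the optional 5-line header block
  lines <- readLines(path)
  body <- grep("^[0-9]+\t", lines, value = TRUE)
  if (!length(body)) stop("no PSL records found in ", path)
  psl <- utils::read.delim(text = paste(body, collapse = "\n"), header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(psl) < 14) stop("malformed PSL record (need >= 14 fields) in ", path)
  matches <- psl[[1]]
  q_name <- as.character(psl[[10]])
  q_size <- psl[[11]]
  t_name <- as.character(psl[[14]])
  bad <- matches > q_size
  if (any(bad)) {
    warning(sum(bad), " PSL record(s) with matches > query size rejected")
    matches <- matches[!bad]; q_name <- q_name[!bad]
    q_size <- q_size[!bad]; t_name <- t_name[!bad]
  }
  rep_loc <- rep(NA_character_, length(q_name))
  if (!is.null(reported_locus)) rep_loc <- unname(reported_locus[q_name])
  alignment_hits(q_name,
                 classify_target(t_name, rep_loc, locus_table),
                 matches / q_size)
}

#' Write alignment hits in the native dialect
#'
#' @param hits an [alignment_hits()] table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignment_hits <- function(hits, path) {
  utils::write.table(hits[, c("query_id", "target_class", "match_fraction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an FPKM matrix into V-usage vectors
#'
#' Reads a genes-by-samples TSV of normalized expression (gene names in the
#' first column) and returns one [vusage_vector()] per sample per chain,
#' restricted to rows whose gene name starts with TRAV/TRBV/TRGV/TRDV.
#'
#' @param path path to the TSV.
#' @return A list of `vusage_vector` objects named `"<sample>.<chain>"`.
#' @export
read_fpkm_matrix <- function(path) {
  if (!file.exists(path)) stop("FPKM matrix not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 1L) stop("FPKM matrix has no columns: ", path)
  genes <- as.character(raw[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicated gene name(s) in FPKM matrix: ",
                        paste(dup, collapse = ", "))
  mat <- raw[, -1, drop = FALSE]
  if (ncol(mat) == 0L) return(list())
  if (any(vapply(mat, function(x) any(x < 0, na.rm = TRUE), TRUE))) {
    stop("negative expression value in FPKM matrix ", path)
  }
  chain <- chain_from_vgene(genes)
  out <- list()
  for (s in names(mat)) {
    for (ch in TCR_CHAINS) {
      keep <- !is.na(chain) & chain == ch
      if (!any(keep)) next
      vals <- stats::setNames(as.double(mat[[s]][keep]), genes[keep])
      out[[paste(s, ch, sep = ".")]] <- vusage_vector(s, ch, vals)
    }
  }
  out
}

#' Read a sample sheet
#'
#' Reads a cohort sample sheet from TSV or YAML. Required fields:
#' `sample_id`, `total_mapped_reads`, `clonotype_file`. Optional: `subtype`,
#' `mutation_positive`, `ebv_read_count`, `hits_file`, `fpkm_file`.
#'
#' @param path path to a `.tsv` or `.yaml`/`.yml` file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(raw$samples, function(s) {
      as.data.frame(s[lengths(s) == 1L], stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  needed <- c("sample_id", "total_mapped_reads", "clonotype_file")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("sample sheet is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  for (col in c("subtype", "mutation_positive", "ebv_read_count",
                "hits_file", "fpkm_file")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df
}

#' Write the clonality report
#'
#' Writes one row per sample per chain with the call, the triggering rule,
#' the biallelic flag and the diagnostic counts/ratios, in a deterministic
#' column and row order, plus a machine-readable JSON twin at
#' `<path>.json`.
#'
#' @param calls a list of `clonality_call` objects or a data.frame from
#'   [calls_to_frame()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(calls, path) {
  df <- if (is.data.frame(calls)) calls else calls_to_frame(calls)
  if (is.null(df) || !nrow(df)) {
    stop("refusing to write an empty clonality report")
  }
  df <- df[order(df$sample_id, df$chain), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
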