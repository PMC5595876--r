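# Three-step decontamination of CDR3 clonotype extraction from bulk
# RNA-seq, over domain types and independent of any external aligner:
#   1. drop reads matching non-TCR or different-TCR regions (> threshold)
#      with no alternative match to their reported locus,
#   2. drop clones whose CDR3 is nearly fully templated on the genome
#      (a genuine CDR3 carries nontemplated junction bases),
#   3. drop CDR3s recurring in more than a set number of patient cases.

new_filter_audit <- function(step, ids = character(0), reason = character(0)) {
  data.frame(step = rep(step, length(ids)), id = ids, reason = reason,
             stringsAsFactors = FALSE)
}

#' Step 1: filter reads (or clones) by alignment evidence
#'
#' A read is removed iff it has a hit on a non-TCR or different TCR region
#' with match fraction strictly above `read_mismatch_threshold` (default
#' 0.80) and no alternative hit on its reported TCR locus above
#' `alt_match_threshold`. Reads without hits are retained. When only
#' clone-level tables exist the same rule is applied to each clone's
#' representative CDR3-containing sequence (degraded mode; ids are then
#' clone ids).
#'
#' @param reads named character vector: read (or clone) id to reported TCR
#'   locus.
#' @param hits an [alignment_hits()] table; every `query_id` must appear in
#'   `reads`.
#' @param cfg a [filter_config()].
#' @return A list with `retained` (character ids) and `audit` (a
#'   `FilterAudit` data.frame).
#' @export
filter_reads_by_alignment <- function(reads, hits, cfg = filter_config()) {
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be a named vector (id -> reported locus)")
  unknown <- setdiff(hits$query_id, ids)
  if (length(unknown)) {
    stop("alignment hit(s) for unknown read id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  off <- hits$target_class %in% c("non_tcr", "other_tcr_locus") &
    hits$match_fraction > cfg$read_mismatch_threshold
  rescue <- hits$target_class == "same_tcr_locus" &
    hits$match_fraction > cfg$alt_match_threshold
  suspect <- unique(hits$query_id[off])
  rescued <- unique(hits$query_id[rescue])
  removed <- setdiff(suspect, rescued)
  reason <- vapply(removed, function(id) {
    h <- hits[hits$query_id == id & off, , drop = FALSE]
    h <- h[which.max(h$match_fraction), ]
    sprintf("%s match %.3f > %.2f with no alternative %s match",
            h$target_class, h$match_fraction, cfg$read_mismatch_threshold,
            reads[[id]])
  }, "")
  list(retained = setdiff(ids, removed),
       audit = new_filter_audit("read_alignment", removed, unname(reason)))
}

#' Step 2: filter clones with near-complete genomic matches
#'
#' A clone is removed iff any genome hit of its CDR3 — regardless of target
#' class — has match fraction strictly above `genome_match_threshold`
#' (default 0.90): CDR3 sequences are expected to consist of V and J
#' segment ends with several nontemplated bases in between, so a
#' near-complete contiguous genomic match indicates a non-TCR contaminant.
#' Clones without hits are retained.
#'
#' @param clones a clonotype table.
#' @param hits an [alignment_hits()] table keyed by clone id.
#' @param cfg a [filter_config()].
#' @return A list with `retained` (clonotype table) and `audit`.
#' @export
filter_clones_genomic <- function(clones, hits, cfg = filter_config()) {
  high <- hits$match_fraction > cfg$genome_match_threshold
  removed <- intersect(clones$clone_id, unique(hits$query_id[high]))
  reason <- vapply(removed, function(id) {
    f <- max(hits$match_fraction[hits$query_id == id & high])
    sprintf("near-complete genomic match %.3f > %.2f (expected V + N bases + J)",
            f, cfg$genome_match_threshold)
  }, "")
  keep <- !clones$clone_id %in% removed
  out <- clones[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(retained = out,
       audit = new_filter_audit("genomic_cdr3", removed, unname(reason)))
}

# identity key for recurrence counting; mode "full" = (chain, cdr3, V, J),
# mode "cdr3" = CDR3 nucleotide sequence alone
clone_identity_key <- function(clones, mode = c("full", "cdr3")) {
  mode <- match.arg(mode)
  if (mode == "full") {
    paste(clones$chain, clones$cdr3_nt, clones$v_gene, clones$j_gene,
          sep = "|")
  } else {
    clones$cdr3_nt
  }
}

#' Step 3: filter recurrent ("public") CDR3s across the cohort
#'
#' Counts, for each clone identity, the number of distinct samples in which
#' it is present (presence, not read depth; one sample per patient is
#' assumed unless `patient_of` maps replicates together). Identities present
#' in strictly more than `recurrence_patient_limit` patients (default 8) are
#' removed from every sample.
#'
#' @param cohort a named list: sample id to clonotype table.
#' @param cfg a [filter_config()].
#' @param identity `"full"` ((chain, CDR3, V, J), default) or `"cdr3"`
#'   (CDR3 nucleotide sequence alone).
#' @param patient_of optional named vector mapping sample id to patient id.
#' @return A list with `retained` (the filtered cohort) and `audit`.
#' @export
filter_recurrent <- function(cohort, cfg = filter_config(),
                             identity = c("full", "cdr3"),
                             patient_of = NULL) {
  identity <- match.arg(identity)
  if (!length(cohort)) stop("cohort must contain at least one sample")
  if (is.null(names(cohort)) || anyDuplicated(names(cohort))) {
    stop("cohort must be a uniquely named list of clonotype tables")
  }
  patients <- if (is.null(patient_of)) {
    stats::setNames(names(cohort), names(cohort))
  } else {
    unname(patient_of[names(cohort)])
  }
  key_patient <- unique(do.call(rbind, lapply(seq_along(cohort), function(i) {
    cl <- cohort[[i]]
    if (!nrow(cl)) return(NULL)
    data.frame(key = clone_identity_key(cl, identity),
               patient = unname(patients[i]), stringsAsFactors = FALSE)
  })))
  n_patients <- table(key_patient$key)
  public <- names(n_patients)[n_patients > cfg$recurrence_patient_limit]
  audits <- list()
  retained <- lapply(names(cohort), function(s) {
    cl <- cohort[[s]]
    if (!nrow(cl)) return(cl)
    hit <- clone_identity_key(cl, identity) %in% public
    if (any(hit)) {
      k <- clone_identity_key(cl, identity)[hit]
      audits[[s]] <<- new_filter_audit(
        "recurrence", paste(s, cl$clone_id[hit], sep = ":"),
        sprintf("CDR3 identity present in %d patient cases (> %d)",
                as.integer(n_patients[k]), cfg$recurrence_patient_limit))
    }
    out <- cl[!hit, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(retained) <- names(cohort)
  list(retained = retained,
       audit = if (length(audits)) do.call(rbind, unname(audits))
               else new_filter_audit("recurrence"))
}
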