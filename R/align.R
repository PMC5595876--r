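# Local-alignment stand-in used when PSL alignment records are not supplied:
# affine-gap (Gotoh) local alignment at match +1 / mismatch -1 / gap open -2 /
# gap extend -1 (a gap of length L costs 2 + L). The match fraction is the
# number of aligned identical bases on the optimal path divided by query
# length; among score-optimal paths the one with more matches is preferred,
# which makes the fraction deterministic. No claim is made that this
# reproduces BLAT's seeded heuristic bit-for-bit.

#' Build a labelled reference set
#'
#' @param name reference names.
#' @param seq nucleotide sequences.
#' @param locus locus label per reference: a TCR chain name or `"non_tcr"`.
#' @return A data.frame usable by [compute_match_fraction()].
#' @export
reference_set <- function(name, seq, locus) {
  ok <- locus %in% c(TCR_CHAINS, "non_tcr")
  if (any(!ok)) stop("reference locus must be a TCR chain or 'non_tcr'")
  data.frame(name = as.character(name), seq = toupper(as.character(seq)),
             locus = as.character(locus), stringsAsFactors = FALSE)
}

# returns list(score, matches) for the optimal local alignment of q vs t
.local_align <- function(q, t, match = 1, mismatch = -1,
                         gap_open = 2, gap_ext = 1) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  oe <- gap_open + gap_ext
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  mm <- mx <- my <- matrix(0L, n + 1L, m + 1L)
  M[1L, ] <- 0
  M[, 1L] <- 0
  best <- 0; best_matches <- 0L
  for (i in 2L:(n + 1L)) {
    qi <- qs[i - 1L]
    for (j in 2L:(m + 1L)) {
      s <- if (qi == ts[j - 1L]) match else mismatch
      add <- as.integer(s == match)
      # substitution state: extend the best predecessor or restart at 0
      cand_v <- c(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L], Iy[i - 1L, j - 1L]) + s
      cand_m <- c(mm[i - 1L, j - 1L], mx[i - 1L, j - 1L],
                  my[i - 1L, j - 1L]) + add
      cand_v <- c(cand_v, s)          # restart (local)
      cand_m <- c(cand_m, add)
      top <- max(cand_v)
      if (top < 0) { top <- 0; mcnt <- 0L }   # never carry a negative prefix
      else mcnt <- max(cand_m[cand_v == top])
      M[i, j] <- top; mm[i, j] <- mcnt

      cand_v <- c(M[i - 1L, j] - oe, Ix[i - 1L, j] - gap_ext,
                  Iy[i - 1L, j] - oe)
      cand_m <- c(mm[i - 1L, j], mx[i - 1L, j], my[i - 1L, j])
      top <- max(cand_v)
      Ix[i, j] <- top
      mx[i, j] <- if (top > NEG / 2) max(cand_m[cand_v == top]) else 0L

      cand_v <- c(M[i, j - 1L] - oe, Ix[i, j - 1L] - oe,
                  Iy[i, j - 1L] - gap_ext)
      cand_m <- c(mm[i, j - 1L], mx[i, j - 1L], my[i, j - 1L])
      top <- max(cand_v)
      Iy[i, j] <- top
      my[i, j] <- if (top > NEG / 2) max(cand_m[cand_v == top]) else 0L

      if (M[i, j] > best ||
          (M[i, j] == best && mm[i, j] > best_matches)) {
        best <- M[i, j]; best_matches <- mm[i, j]
      }
    }
  }
  list(score = best, matches = best_matches)
}

#' Best match fraction of a query against labelled references
#'
#' Aligns `query` locally against every reference and returns the hit with
#' the largest match fraction (aligned identical bases / query length); ties
#' are broken by reference input order. Scoring is fixed at match +1,
#' mismatch -1, gap open -2, gap extend -1.
#'
#' @param query nucleotide string, length >= 10.
#' @param references a [reference_set()] (non-empty).
#' @param query_id identifier recorded in the returned hit.
#' @param reported_locus the TCR locus the query was reported on, or `NA`;
#'   used to turn each reference's locus label into a target class.
#' @return A one-row [alignment_hits()] table with an extra `target_name`
#'   column.
#' @export
compute_match_fraction <- function(query, references, query_id = "query",
                                   reported_locus = NA_character_) {
  if (is.null(references) || !nrow(references)) {
    stop("reference collection is empty")
  }
  query <- toupper(query)
  if (nchar(query) < 10L) stop("query must be at least 10 nt")
  best_i <- 1L; best_frac <- -1
  for (i in seq_len(nrow(references))) {
    al <- .local_align(query, references$seq[i])
    frac <- al$matches / nchar(query)
    if (frac > best_frac) { best_frac <- frac; best_i <- i }
  }
  locus <- references$locus[best_i]
  cls <- if (locus == "non_tcr") "non_tcr"
         else if (!is.na(reported_locus) && locus == reported_locus)
           "same_tcr_locus" else "other_tcr_locus"
  out <- alignment_hits(query_id, cls, best_frac)
  out$target_name <- references$name[best_i]
  out
}
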