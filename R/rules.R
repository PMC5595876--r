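# The clonality decision engine: clone ranking, the dominant-fraction and
# top2/third ratio rules, the biallelic rule, the V-usage fallback rule,
# productivity annotation, and CDR3-precedence reconciliation.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Annotate CDR3 productivity
#'
#' A rearrangement is nonproductive when its CDR3 nucleotide length is not a
#' multiple of three (frameshift) or its in-frame translation contains a
#' stop codon (nonsense); productive otherwise. The `"unknown"` level is
#' reserved for tables parsed without sequence information and is never
#' returned here.
#'
#' @param cdr3_nt character vector of CDR3 nucleotide sequences over A/C/G/T.
#' @return Character vector, `"productive"` or `"nonproductive"`.
#' @export
annotate_productivity <- function(cdr3_nt) {
  if (any(!nzchar(cdr3_nt)) || anyNA(cdr3_nt)) {
    stop("empty CDR3 sequence cannot be annotated")
  }
  if (any(!grepl("^[ACGT]+$", cdr3_nt))) {
    stop("CDR3 sequences must be over {A, C, G, T}")
  }
  vapply(cdr3_nt, function(s) {
    len <- nchar(s)
    if (len %% 3L != 0L) return("nonproductive")
    codons <- substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
    if (any(codons %in% STOP_CODONS)) "nonproductive" else "productive"
  }, "", USE.NAMES = FALSE)
}

#' Rank clones of one chain
#'
#' Orders clonotypes by descending read count; ties are broken by CDR3
#' nucleotide sequence, then V gene (lexicographic), so the order is
#' deterministic regardless of input order.
#'
#' @param clones a clonotype table; all rows must share one chain.
#' @return The table in ranked order.
#' @export
rank_clones <- function(clones) {
  if (!nrow(clones)) return(clones)
  if (length(unique(clones$chain)) > 1L) {
    stop("rank_clones expects clones of a single chain, got: ",
         paste(unique(clones$chain), collapse = ", "))
  }
  ord <- order(-clones$read_count, clones$cdr3_nt, clones$v_gene,
               method = "radix")
  out <- clones[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_clonality_call <- function(sample_id, chain, status, rule_fired,
                               biallelic, c1, c2, c3, top2_fraction,
                               top2_to_third, dominant_clone_ids,
                               source = "cdr3", conflict = FALSE) {
  structure(
    list(sample_id = sample_id, chain = chain, status = status,
         rule_fired = rule_fired, biallelic = biallelic,
         c1 = c1, c2 = c2, c3 = c3,
         top2_fraction = top2_fraction, top2_to_third = top2_to_third,
         dominant_clone_ids = dominant_clone_ids,
         source = source, conflict = conflict),
    class = "clonality_call"
  )
}

#' @export
print.clonality_call <- function(x, ...) {
  cat(sprintf("%s %s [%s]: %s", x$sample_id, x$chain, x$source, x$status))
  if (x$status == "monoclonal") {
    cat(sprintf(" via %s%s", x$rule_fired,
                if (isTRUE(x$biallelic)) " (biallelic)" else ""))
  }
  cat(sprintf("\n  top counts %s/%s/%s, top2 fraction %.3f, top2/3rd %s%s\n",
              format(x$c1), format(x$c2), format(x$c3), x$top2_fraction,
              if (is.infinite(x$top2_to_third)) "Inf"
              else sprintf("%.2f", x$top2_to_third),
              if (isTRUE(x$conflict)) " [CDR3/V-usage conflict]" else ""))
  invisible(x)
}

#' Flatten clonality calls to a data.frame
#'
#' @param calls a list of `clonality_call` objects.
#' @return One row per call, dominant clone ids comma-joined.
#' @export
calls_to_frame <- function(calls) {
  if (inherits(calls, "clonality_call")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(x) {
    data.frame(sample_id = x$sample_id, chain = x$chain, status = x$status,
               rule_fired = x$rule_fired, biallelic = x$biallelic,
               c1 = x$c1, c2 = x$c2, c3 = x$c3,
               top2_fraction = x$top2_fraction,
               top2_to_third = x$top2_to_third,
               dominant_clone_ids = paste(x$dominant_clone_ids, collapse = ","),
               source = x$source, conflict = x$conflict,
               stringsAsFactors = FALSE)
  }))
}

# rule kernel on the top-three counts; shared by CDR3 and V-usage paths
.eval_rules <- function(c1, c2, c3, total, cfg) {
  top2 <- c1 + c2
  frac <- if (total > 0) top2 / total else 0
  ratio <- if (c3 > 0) top2 / c3 else if (c1 > 0) Inf else NaN
  fraction_fires <- total > 0 && frac > cfg$dominant_fraction_min
  ratio_fires <- (c3 > 0 && ratio >= cfg$ratio_top2_to_third_min) ||
                 (c3 == 0 && c1 > 0)
  list(top2_fraction = frac, top2_to_third = ratio,
       fraction_fires = fraction_fires, ratio_fires = ratio_fires)
}

#' Classify one chain from ranked CDR3 clones
#'
#' Applies the two monoclonality rules to the ranked clonotypes of a chain.
#' With \eqn{c_1 \ge c_2 \ge c_3} the top three read counts (absent clones
#' count 0) and `total` the chain's CDR3 read total: the fraction rule fires
#' when \eqn{(c_1 + c_2)/total} strictly exceeds the dominant-fraction
#' threshold (default 10\%); the ratio rule fires when
#' \eqn{(c_1 + c_2)/c_3} is at least the ratio threshold (default 10), or
#' when no third clone exists but reads are present (ratio recorded as
#' +Inf). The chain is monoclonal when either rule fires and the chain is
#' adequate, polyclonal when neither fires and it is adequate, and
#' `not_assessable` when inadequate (rules still evaluated for diagnostics).
#'
#' @param ranked ranked clonotype table from [rank_clones()].
#' @param total the chain's CDR3 read total; must equal the sum of
#'   `ranked$read_count`.
#' @param adequate logical; the chain's expression adequacy.
#' @param cfg a [rule_config()].
#' @param sample_id sample identifier recorded in the call.
#' @return A `clonality_call`.
#' @export
classify_chain_cdr3 <- function(ranked, total, adequate,
                                cfg = rule_config(),
                                sample_id = "sample") {
  chain <- if (nrow(ranked)) ranked$chain[1] else NA_character_
  counts <- ranked$read_count
  if (total != sum(counts)) {
    stop("chain read total (", total, ") does not equal the sum of ranked ",
         "clone counts (", sum(counts), ")")
  }
  c1 <- if (length(counts) >= 1L) counts[1] else 0L
  c2 <- if (length(counts) >= 2L) counts[2] else 0L
  c3 <- if (length(counts) >= 3L) counts[3] else 0L
  ev <- .eval_rules(c1, c2, c3, total, cfg)
  rule_fired <- if (ev$fraction_fires && ev$ratio_fires) "both"
                else if (ev$fraction_fires) "fraction_rule"
                else if (ev$ratio_fires) "ratio_rule" else "none"
  status <- if (!isTRUE(adequate)) "not_assessable"
            else if (rule_fired != "none") "monoclonal" else "polyclonal"
  dominant <- if (status == "monoclonal") ranked$clone_id[1] else character(0)
  new_clonality_call(sample_id, chain, status, rule_fired, FALSE,
                     c1, c2, c3, ev$top2_fraction, ev$top2_to_third, dominant)
}

#' Flag biallelic rearrangement on a monoclonal call
#'
#' A monoclonal chain is biallelic when the second largest clone is at least
#' `biallelic_second_to_third_min` times (default 5) the third largest; when
#' no third clone exists, any nonzero second clone counts as biallelic.
#'
#' @param call a monoclonal `clonality_call` from [classify_chain_cdr3()].
#' @param cfg a [rule_config()].
#' @param ranked optionally the ranked clones, to record the second dominant
#'   clone id.
#' @return The call with `biallelic` and `dominant_clone_ids` updated.
#' @export
detect_biallelic <- function(call, cfg = rule_config(), ranked = NULL) {
  if (call$status != "monoclonal") {
    stop("biallelic detection applies to monoclonal calls only (got ",
         call$status, ")")
  }
  call$biallelic <- (call$c3 > 0 &&
                       call$c2 / call$c3 >= cfg$biallelic_second_to_third_min) ||
                    (call$c3 == 0 && call$c2 > 0)
  if (call$biallelic && !is.null(ranked) && nrow(ranked) >= 2L) {
    call$dominant_clone_ids <- ranked$clone_id[1:2]
  }
  call
}

#' Classify one chain from V-gene usage
#'
#' The FPKM-only fallback rule: with \eqn{f_1 \ge f_2 \ge f_3} the top three
#' V-gene expression values of the chain (absent genes count 0), the chain
#' is monoclonal when \eqn{(f_1 + f_2)/f_3} is at least the V-usage ratio
#' threshold (default 10), or when fewer than three V genes are expressed
#' but the top one is nonzero; polyclonal otherwise. An empty vector yields
#' `not_assessable`.
#'
#' @param v a [vusage_vector()].
#' @param cfg a [rule_config()].
#' @return A `clonality_call` with `source = "vusage"`; `c1`..`c3` hold the
#'   FPKM values.
#' @export
classify_chain_vusage <- function(v, cfg = rule_config()) {
  vals <- sort(v$values, decreasing = TRUE)
  vals <- vals[vals > 0]
  if (!length(vals)) {
    return(new_clonality_call(v$sample_id, v$chain, "not_assessable", "none",
                              FALSE, 0, 0, 0, 0, NaN, character(0),
                              source = "vusage"))
  }
  f1 <- vals[1]
  f2 <- if (length(vals) >= 2L) vals[2] else 0
  f3 <- if (length(vals) >= 3L) vals[3] else 0
  ratio <- if (f3 > 0) (f1 + f2) / f3 else Inf
  mono <- (f3 > 0 && ratio >= cfg$vusage_top2_to_third_min) || f3 == 0
  status <- if (mono) "monoclonal" else "polyclonal"
  dominant <- if (mono) names(vals)[1] else character(0)
  new_clonality_call(v$sample_id, v$chain, status,
                     if (mono) "ratio_rule" else "none", FALSE,
                     f1, f2, f3,
                     if (sum(vals) > 0) (f1 + f2) / sum(vals) else 0,
                     ratio, dominant, source = "vusage")
}

#' Reconcile CDR3 and V-usage calls
#'
#' When both assessments are available, the CDR3 assessment takes
#' precedence; the V-usage call is used only when the CDR3 call is not
#' assessable. A disagreement between two assessable calls is flagged in
#' the result.
#'
#' @param cdr3_call,vusage_call `clonality_call`s of the same sample and
#'   chain; `vusage_call` may be `NULL`.
#' @return The adopted `clonality_call`, with `conflict` set when the two
#'   assessable calls disagreed and `source` naming the adopted evidence.
#' @export
reconcile <- function(cdr3_call, vusage_call = NULL) {
  if (is.null(vusage_call)) return(cdr3_call)
  if (cdr3_call$chain != vusage_call$chain ||
      cdr3_call$sample_id != vusage_call$sample_id) {
    stop("reconcile requires calls for the same sample and chain")
  }
  if (cdr3_call$status != "not_assessable") {
    cdr3_call$conflict <- vusage_call$status != "not_assessable" &&
      vusage_call$status != cdr3_call$status
    return(cdr3_call)
  }
  if (vusage_call$status != "not_assessable") return(vusage_call)
  cdr3_call
}

#' Case-level clonality from per-chain calls
#'
#' A case is monoclonal when any adequate chain is monoclonal (a dominant
#' clone on TCR-alpha alone suffices), polyclonal when at least one chain is
#' assessable and none is monoclonal, and not assessable otherwise.
#'
#' @param calls a non-empty list of `clonality_call`s for one sample.
#' @return A list with `sample_id`, `status`, and `supporting_chains` (the
#'   chains that carry the call).
#' @export
classify_sample <- function(calls) {
  if (inherits(calls, "clonality_call")) calls <- list(calls)
  if (!length(calls)) stop("classify_sample needs at least one chain call")
  status <- vapply(calls, `[[`, "", "status")
  chains <- vapply(calls, `[[`, "", "chain")
  sample_id <- calls[[1]]$sample_id
  if (any(status == "monoclonal")) {
    list(sample_id = sample_id, status = "monoclonal",
         supporting_chains = chains[status == "monoclonal"])
  } else if (any(status == "polyclonal")) {
    list(sample_id = sample_id, status = "polyclonal",
         supporting_chains = chains[status == "polyclonal"])
  } else {
    list(sample_id = sample_id, status = "not_assessable",
         supporting_chains = character(0))
  }
}
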