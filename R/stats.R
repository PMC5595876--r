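# Cohort-level descriptive and inferential statistics: top-k clonotype
# fraction profiles, V-gene usage tables, the mutation-clonality Fisher
# test, the productivity-stratified Welch test on C1/C2, and EBV positivity.

#' Top-k clonotype fraction profile
#'
#' Fractions of the k highest-ranked clonotypes of one chain, padded with
#' zeros when fewer than k clones exist, plus the remaining ("rest")
#' fraction.
#'
#' @param clones clonotype table of one chain (any order; ranked
#'   internally).
#' @param k number of ranked clones to report (default 10).
#' @param sample_id identifier recorded in the profile.
#' @return A list of class `topk_profile` with `sample_id`, `chain`,
#'   `fractions` (length k, non-increasing) and `rest_fraction`.
#' @export
top_k_fractions <- function(clones, k = 10L, sample_id = "sample") {
  if (k < 1L) stop("k must be >= 1")
  ranked <- rank_clones(clones)
  total <- sum(ranked$read_count)
  if (total <= 0) stop("chain CDR3 read total must be > 0")
  fr <- ranked$read_count / total
  fractions <- c(utils::head(fr, k), rep(0, max(0L, k - nrow(ranked))))
  structure(
    list(sample_id = sample_id, chain = ranked$chain[1],
         fractions = fractions,
         rest_fraction = if (nrow(ranked) > k) sum(fr[-seq_len(k)]) else 0),
    class = "topk_profile"
  )
}

#' V-gene usage frequencies per chain
#'
#' In `dominant_clones_only` mode, each monoclonal sample contributes one
#' unit of weight split equally across the V gene(s) of its dominant
#' clone(s) (two when biallelic); samples without a monoclonal call are
#' skipped. In `all_clones` mode every sample contributes one unit split
#' across its clones by clone fraction. Frequencies are normalized per
#' chain.
#'
#' @param cohort named list: sample id to clonotype table.
#' @param calls list of `clonality_call`s (required in dominant mode).
#' @param mode `"dominant_clones_only"` or `"all_clones"`.
#' @return A data.frame with columns `chain`, `v_gene`, `frequency`;
#'   frequencies sum to 1 within each chain.
#' @export
vgene_usage_table <- function(cohort, calls = NULL,
                              mode = c("dominant_clones_only", "all_clones")) {
  mode <- match.arg(mode)
  if (!length(cohort)) stop("cohort must be non-empty")
  weights <- list()
  add <- function(chain, gene, w) {
    key <- paste(chain, gene, sep = "|")
    weights[[key]] <<- (if (is.null(weights[[key]])) 0 else weights[[key]]) + w
  }
  if (mode == "dominant_clones_only") {
    if (is.null(calls)) stop("dominant_clones_only mode requires clonality calls")
    for (call in calls) {
      if (call$status != "monoclonal" || !length(call$dominant_clone_ids)) next
      cl <- cohort[[call$sample_id]]
      dom <- cl[cl$clone_id %in% call$dominant_clone_ids, , drop = FALSE]
      if (!nrow(dom)) next
      for (i in seq_len(nrow(dom))) {
        add(dom$chain[i], dom$v_gene[i], 1 / nrow(dom))
      }
    }
  } else {
    for (s in names(cohort)) {
      cl <- cohort[[s]]
      for (ch in unique(cl$chain)) {
        sub <- cl[cl$chain == ch, , drop = FALSE]
        fr <- sub$read_count / sum(sub$read_count)
        for (i in seq_len(nrow(sub))) add(ch, sub$v_gene[i], fr[i])
      }
    }
  }
  if (!length(weights)) {
    return(data.frame(chain = character(0), v_gene = character(0),
                      frequency = double(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(weights), "|", fixed = TRUE)
  df <- data.frame(chain = vapply(parts, `[`, "", 1L),
                   v_gene = vapply(parts, `[`, "", 2L),
                   weight = unlist(weights, use.names = FALSE),
                   stringsAsFactors = FALSE)
  df$frequency <- stats::ave(df$weight, df$chain, FUN = function(w) w / sum(w))
  df <- df[order(df$chain, -df$frequency, df$v_gene),
           c("chain", "v_gene", "frequency")]
  rownames(df) <- NULL
  df
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test at fixed margins; the two-sided p-value is the
#' sum of the probabilities of all tables no more probable than the
#' observed one (the standard probability-mass convention). Rows are
#' monoclonal/polyclonal, columns mutation-positive/negative in the
#' cohort-summary use.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) < 1) stop("table total must be >= 1")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Welch two-sample t-test on C1/C2 ratios by productivity
#'
#' Compares the top-two clone expression ratio (C1/C2) between biallelic
#' cases whose second allele is productive and those whose second allele is
#' nonproductive. Under nonsense-mediated decay the nonproductive group is
#' expected to show larger ratios. Ratios may be compared raw or on the log
#' scale (ratio distributions are right-skewed).
#'
#' @param ratios_productive,ratios_nonproductive numeric vectors of C1/C2
#'   ratios (each >= 1), at least two values per group.
#' @param scale `"raw"` (default) or `"log"`.
#' @return A list with `statistic`, `df`, `p.value`, and
#'   `higher_group` (`"nonproductive"`, `"productive"` or `"none"`).
#' @export
welch_c1c2_test <- function(ratios_productive, ratios_nonproductive,
                            scale = c("raw", "log")) {
  scale <- match.arg(scale)
  if (length(ratios_productive) < 2L || length(ratios_nonproductive) < 2L) {
    stop("each group needs at least two C1/C2 ratios")
  }
  if (any(c(ratios_productive, ratios_nonproductive) < 1)) {
    stop("C1/C2 ratios must be >= 1 (C1 is the larger clone)")
  }
  x <- ratios_nonproductive
  y <- ratios_productive
  if (scale == "log") { x <- log(x); y <- log(y) }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  diffm <- mean(x) - mean(y)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       higher_group = if (diffm > 0) "nonproductive"
                      else if (diffm < 0) "productive" else "none")
}

#' EBV positivity from virus-mapped read counts
#'
#' @param ebv_read_count non-negative integer count(s) of EBV-mapped reads.
#' @param threshold positivity threshold; a sample with `threshold` or more
#'   EBV-derived reads is positive (default 100).
#' @return Logical vector.
#' @export
classify_ebv <- function(ebv_read_count, threshold = 100L) {
  if (any(ebv_read_count < 0, na.rm = TRUE)) stop("counts must be >= 0")
  ebv_read_count >= threshold
}

#' Cohort summary by subtype
#'
#' Per-subtype counts of assessable, monoclonal and biallelic cases and EBV
#' positives, plus — when mutation metadata is present — the
#' mutation-by-clonality 2x2 table and its Fisher p-value over the whole
#' cohort.
#'
#' @param case_calls data.frame with columns `sample_id`, `status` (case
#'   level), `biallelic` (logical, any chain).
#' @param metadata data.frame with `sample_id`, `subtype`, and optionally
#'   `mutation_positive`, `ebv_read_count`.
#' @param ebv_threshold EBV positivity threshold (default 100 reads).
#' @return A list of class `cohort_summary` with `by_subtype` (data.frame)
#'   and, when computable, `mutation_table` and `fisher_p`.
#' @export
cohort_summary <- function(case_calls, metadata, ebv_threshold = 100L) {
  if (!nrow(case_calls)) stop("no clonality calls supplied")
  df <- merge(case_calls, metadata, by = "sample_id", all.x = TRUE)
  df$subtype[is.na(df$subtype)] <- "unknown"
  rows <- lapply(split(df, df$subtype), function(g) {
    assessable <- g$status != "not_assessable"
    mono <- g$status == "monoclonal"
    data.frame(
      subtype = g$subtype[1],
      n = nrow(g),
      n_assessable = sum(assessable),
      n_monoclonal = sum(mono),
      fraction_monoclonal = if (sum(assessable)) sum(mono) / sum(assessable)
                            else NA_real_,
      n_biallelic = sum(mono & g$biallelic %in% TRUE),
      n_ebv_positive = if ("ebv_read_count" %in% names(g))
        sum(classify_ebv(g$ebv_read_count[!is.na(g$ebv_read_count)],
                         ebv_threshold))
      else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- list(by_subtype = do.call(rbind, c(rows, list(make.row.names = FALSE))))
  if ("mutation_positive" %in% names(df) &&
      any(!is.na(df$mutation_positive))) {
    sub <- df[!is.na(df$mutation_positive) & df$status != "not_assessable", ]
    if (nrow(sub)) {
      tab <- c(a = sum(sub$status == "monoclonal" & sub$mutation_positive),
               b = sum(sub$status == "monoclonal" & !sub$mutation_positive),
               c = sum(sub$status == "polyclonal" & sub$mutation_positive),
               d = sum(sub$status == "polyclonal" & !sub$mutation_positive))
      out$mutation_table <- tab
      out$fisher_p <- fisher_exact_2x2(tab["a"], tab["b"], tab["c"], tab["d"])
    }
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort clonality summary\n")
  print(x$by_subtype, row.names = FALSE)
  if (!is.null(x$fisher_p)) {
    cat(sprintf(
      "\nMutation x clonality 2x2 [mono+: %d, mono-: %d, poly+: %d, poly-: %d]",
      x$mutation_table["a"], x$mutation_table["b"],
      x$mutation_table["c"], x$mutation_table["d"]))
    cat(sprintf("\nFisher's exact test (two-sided): p = %.4g\n", x$fisher_p))
  }
  invisible(x)
}
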