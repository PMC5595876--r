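# Orchestration: the per-sample clonality assessment object, and the
# cohort pipeline (filter -> quantify -> classify -> reconcile -> report)
# with a run manifest.

#' Assess TCR clonality of one repertoire sample
#'
#' The package's central entry point. Optionally applies the alignment and
#' genomic decontamination filters (steps 1 and 2; the cohort-level
#' recurrence filter is applied by [run_pipeline()]), quantifies each
#' chain's transcript level in RPM, gates chains on expression adequacy,
#' applies the CDR3 monoclonality and biallelic rules, the V-usage fallback
#' rule when FPKM data is present, reconciles the two (CDR3 takes
#' precedence), and derives the case-level status.
#'
#' @param sample a [repertoire_sample()].
#' @param vusage optional list of [vusage_vector()]s for this sample.
#' @param read_hits,genome_hits optional [alignment_hits()] tables keyed by
#'   clone id, enabling filter steps 1 and 2.
#' @param filter_cfg a [filter_config()].
#' @param rules a [rule_config()].
#' @param adequacy an [adequacy_thresholds()].
#' @return An object of class `tcr_clonality`: a list with `sample_id`,
#'   `case_status`, `chain_calls` (final reconciled `clonality_call`s),
#'   `cdr3_calls`, `vusage_calls`, `quant` (per-chain `chain_quant`),
#'   `filter_audit`, and the retained `clonotypes`.
#' @examples
#' clones <- clonotype_table(
#'   clone_id = c("c1", "c2", "c3", "c4"),
#'   chain = "TRB",
#'   cdr3_nt = c("TGTGCCAGCAGCTTGGGAACTGAAGCTTTCTTT",
#'               "TGTGCCAGCAGTGAAGACACCCAGTACTTC",
#'               "TGTGCCTGGAGTGTAGCTCAGCCCCAGCATTTT",
#'               "TGTGCCAGCAGCCCAGGACAGGGGGCGACCGAAGCTTTCTTT"),
#'   read_count = c(700, 250, 30, 20),
#'   v_gene = c("TRBV1", "TRBV2", "TRBV3", "TRBV4"),
#'   j_gene = c("TRBJ1", "TRBJ2", "TRBJ1", "TRBJ3"))
#' s <- repertoire_sample("example", clones, total_mapped_reads = 2e7)
#' fit <- tcr_clonality(s)
#' fit
#' summary(fit)
#' @export
tcr_clonality <- function(sample, vusage = NULL, read_hits = NULL,
                          genome_hits = NULL,
                          filter_cfg = filter_config(),
                          rules = rule_config(),
                          adequacy = adequacy_thresholds()) {
  if (!inherits(sample, "repertoire_sample")) stop("expected a repertoire_sample")
  clones <- sample$clonotypes
  audit <- new_filter_audit("read_alignment")
  if (!is.null(read_hits) && nrow(read_hits)) {
    reads <- stats::setNames(clones$chain, clones$clone_id)
    # hits may cover clones an earlier (cohort-level) filter already removed
    read_hits <- read_hits[read_hits$query_id %in% clones$clone_id, ,
                           drop = FALSE]
    f1 <- filter_reads_by_alignment(reads, read_hits, filter_cfg)
    clones <- clones[clones$clone_id %in% f1$retained, , drop = FALSE]
    audit <- rbind(audit, f1$audit)
  }
  if (!is.null(genome_hits) && nrow(genome_hits)) {
    f2 <- filter_clones_genomic(clones, genome_hits, filter_cfg)
    clones <- f2$retained
    audit <- rbind(audit, f2$audit)
  }
  sample$clonotypes <- clones

  quant <- lapply(TCR_CHAINS, function(ch) compute_rpm(sample, ch))
  names(quant) <- TCR_CHAINS
  ab <- assess_adequacy(quant$TRA, quant$TRB, adequacy)
  quant$TRA <- ab$TRA
  quant$TRB <- ab$TRB
  quant$TRG <- assess_adequacy_depth(quant$TRG, adequacy)
  quant$TRD <- assess_adequacy_depth(quant$TRD, adequacy)

  vus <- list()
  for (v in vusage) vus[[v$chain]] <- v

  cdr3_calls <- list(); vusage_calls <- list(); final_calls <- list()
  for (ch in TCR_CHAINS) {
    sub <- clones[clones$chain == ch, , drop = FALSE]
    if (!nrow(sub) && is.null(vus[[ch]])) next
    ranked <- rank_clones(sub)
    call <- classify_chain_cdr3(ranked, sum(ranked$read_count),
                                adequate = quant[[ch]]$adequate,
                                cfg = rules, sample_id = sample$sample_id)
    if (call$status == "monoclonal") {
      call <- detect_biallelic(call, rules, ranked)
    }
    cdr3_calls[[ch]] <- call
    vcall <- if (!is.null(vus[[ch]])) classify_chain_vusage(vus[[ch]], rules)
             else NULL
    if (!is.null(vcall)) vusage_calls[[ch]] <- vcall
    final_calls[[ch]] <- reconcile(call, vcall)
  }
  case <- if (length(final_calls)) classify_sample(final_calls)
          else list(sample_id = sample$sample_id, status = "not_assessable",
                    supporting_chains = character(0))
  structure(
    list(sample_id = sample$sample_id, case_status = case$status,
         supporting_chains = case$supporting_chains,
         chain_calls = final_calls, cdr3_calls = cdr3_calls,
         vusage_calls = vusage_calls, quant = quant,
         filter_audit = audit, clonotypes = clones),
    class = "tcr_clonality"
  )
}

#' @export
print.tcr_clonality <- function(x, ...) {
  cat("TCR clonality assessment of sample", x$sample_id, "\n")
  cat("Case status:", x$case_status)
  if (length(x$supporting_chains)) {
    cat(" (", paste(x$supporting_chains, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  for (call in x$chain_calls) print(call)
  invisible(x)
}

#' @export
summary.tcr_clonality <- function(object, ...) {
  df <- calls_to_frame(object$chain_calls)
  rpm <- vapply(object$quant, `[[`, 0, "rpm")
  adequate <- vapply(object$quant, `[[`, NA, "adequate")
  df$rpm <- rpm[df$chain]
  df$adequate <- adequate[df$chain]
  structure(list(sample_id = object$sample_id,
                 case_status = object$case_status,
                 chains = df,
                 n_filtered = nrow(object$filter_audit)),
            class = "summary.tcr_clonality")
}

#' @export
print.summary.tcr_clonality <- function(x, ...) {
  cat("Sample", x$sample_id, "-", x$case_status, "\n")
  if (x$n_filtered) cat(x$n_filtered, "clone(s) removed by filtering\n")
  print(x$chains[, c("chain", "status", "rule_fired", "biallelic", "c1",
                     "c2", "c3", "top2_fraction", "top2_to_third", "rpm",
                     "adequate", "source", "conflict")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.tcr_clonality <- function(x, ...) {
  calls_to_frame(x$chain_calls)
}

#' Plot ranked clonotype fractions
#'
#' Stacked-bar view of the top-k clonotype fractions of one chain, the
#' standard visual for repertoire dominance.
#'
#' @param x a `tcr_clonality` object.
#' @param chain chain to plot (default `"TRB"`).
#' @param k number of ranked clones to color individually.
#' @param ... passed to [graphics::barplot()].
#' @return The top-k profile, invisibly.
#' @export
plot.tcr_clonality <- function(x, chain = "TRB", k = 10L, ...) {
  sub <- x$clonotypes[x$clonotypes$chain == chain, , drop = FALSE]
  if (!nrow(sub)) stop("no clonotypes on chain ", chain)
  prof <- top_k_fractions(sub, k = k, sample_id = x$sample_id)
  vals <- c(prof$fractions, prof$rest_fraction)
  graphics::barplot(matrix(vals, ncol = 1),
                    col = c(grDevices::rainbow(k), "grey"),
                    ylab = "fraction of CDR3 reads",
                    main = paste(x$sample_id, chain), ...)
  invisible(prof)
}

#' Run the full cohort pipeline
#'
#' Stages, in order: read all inputs; filter step 1 (read alignment) and
#' step 2 (genomic CDR3) per sample; filter step 3 (recurrence) across the
#' cohort; quantify; classify (CDR3 and V-usage when FPKM data is
#' present); reconcile; report. Writes the clonality report (TSV + JSON
#' twin), the cohort summary, the filter audit, and a run manifest
#' sufficient to re-execute the run bit-identically.
#'
#' @param sample_sheet path to a sample sheet (see [read_sample_sheet()]);
#'   file paths in it are resolved relative to its directory.
#' @param config path to a YAML configuration (see
#'   [read_pipeline_config()]) or a configuration list.
#' @param out_dir output directory.
#' @return A list of class `tcr_clonality_run` with `fits` (per-sample
#'   `tcr_clonality`), `report` (data.frame), `summary`
#'   ([cohort_summary()]), and `manifest`.
#' @export
run_pipeline <- function(sample_sheet, config = NULL, out_dir) {
  cfg <- if (is.character(config) || is.null(config))
    read_pipeline_config(config) else config
  sheet <- read_sample_sheet(sample_sheet)
  base <- dirname(normalizePath(sample_sheet))
  resolve <- function(p) {
    if (is.na(p) || !nzchar(p)) return(NA_character_)
    if (file.exists(p)) p else file.path(base, p)
  }

  stage_counts <- list()
  cohort <- list(); read_hits <- list(); genome_hits <- list()
  vusage_all <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    cf <- resolve(sheet$clonotype_file[i])
    if (!file.exists(cf)) {
      stop("stage input, sample ", sid, ": clonotype file not found: ", cf)
    }
    cohort[[sid]] <- read_clonotype_table(cf)
    hf <- resolve(sheet$hits_file[i])
    if (!is.na(hf)) {
      if (!file.exists(hf)) stop("stage input, sample ", sid,
                                 ": hits file not found: ", hf)
      read_hits[[sid]] <- read_alignment_hits(hf)
    }
    gf <- if ("genome_hits_file" %in% names(sheet))
      resolve(sheet$genome_hits_file[i]) else NA
    if (!is.na(gf)) {
      if (!file.exists(gf)) stop("stage input, sample ", sid,
                                 ": genome hits file not found: ", gf)
      genome_hits[[sid]] <- read_alignment_hits(gf)
    }
    ff <- resolve(sheet$fpkm_file[i])
    if (!is.na(ff)) {
      if (!file.exists(ff)) stop("stage input, sample ", sid,
                                 ": FPKM file not found: ", ff)
      vus <- read_fpkm_matrix(ff)
      vusage_all[[sid]] <- Filter(function(v) v$sample_id == sid, vus)
    }
  }
  stage_counts$input_clones <- vapply(cohort, nrow, 0L)

  # cohort-level recurrence filter (step 3) runs before per-sample stages
  f3 <- filter_recurrent(cohort, cfg$filter)
  cohort <- f3$retained
  stage_counts$after_recurrence <- vapply(cohort, nrow, 0L)

  fits <- list(); audits <- list(f3$audit)
  for (sid in names(cohort)) {
    row <- sheet[sheet$sample_id == sid, ]
    s <- repertoire_sample(
      sid, cohort[[sid]], row$total_mapped_reads,
      subtype = if (is.na(row$subtype)) "unknown" else row$subtype,
      mutation_positive = row$mutation_positive,
      ebv_read_count = row$ebv_read_count)
    fits[[sid]] <- tcr_clonality(
      s, vusage = vusage_all[[sid]], read_hits = read_hits[[sid]],
      genome_hits = genome_hits[[sid]], filter_cfg = cfg$filter,
      rules = cfg$rules, adequacy = cfg$adequacy)
    audits[[sid]] <- fits[[sid]]$filter_audit
  }
  stage_counts$after_all_filters <- vapply(fits,
                                           function(f) nrow(f$clonotypes), 0L)

  report <- do.call(rbind, lapply(fits, as.data.frame))
  rownames(report) <- NULL
  case_calls <- do.call(rbind, lapply(fits, function(f) {
    data.frame(sample_id = f$sample_id, status = f$case_status,
               biallelic = any(vapply(f$chain_calls, `[[`, NA, "biallelic")),
               stringsAsFactors = FALSE)
  }))
  summary <- cohort_summary(case_calls, sheet, cfg$ebv_min_reads)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(report, file.path(out_dir, "clonality_report.tsv"))
  utils::write.table(case_calls, file.path(out_dir, "case_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$by_subtype,
                     file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  audit <- do.call(rbind, audits)
  utils::write.table(audit, file.path(out_dir, "filter_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  inputs <- stats::na.omit(c(normalizePath(sample_sheet),
                             vapply(sheet$clonotype_file, resolve, "")))
  manifest <- list(
    tool = "tcrclonality",
    version = as.character(utils::packageVersion("tcrclonality")),
    config = list(filter = unclass(cfg$filter), rules = unclass(cfg$rules),
                  adequacy = unclass(cfg$adequacy),
                  ebv_min_reads = cfg$ebv_min_reads),
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stage_counts = lapply(stage_counts, as.list),
    fisher_p = summary$fisher_p
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(fits = fits, report = report, case_calls = case_calls,
                 summary = summary, manifest = manifest),
            class = "tcr_clonality_run")
}

#' @export
print.tcr_clonality_run <- function(x, ...) {
  cat("tcrclonality pipeline run:", length(x$fits), "sample(s)\n\n")
  print(x$summary)
  invisible(x)
}
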