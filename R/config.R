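#' Filtering thresholds for CDR3 decontamination
#'
#' One auditable place for the three decontamination thresholds: the read
#' mismatch threshold (a read is suspect when it matches a non-TCR or
#' different TCR region at more than this fraction), the genomic match
#' threshold (a clone whose CDR3 is nearly fully templated on the genome is a
#' contaminant), and the recurrence limit (a CDR3 found in more than this
#' many patient cases is treated as noise). All comparisons are strict,
#' mirroring the ">80%", ">90%" and "more than eight" wording they encode.
#'
#' @param read_mismatch_threshold fraction in (0, 1\]; default 0.80.
#' @param genome_match_threshold fraction in (0, 1\]; default 0.90.
#' @param recurrence_patient_limit integer >= 1; default 8.
#' @param alt_match_threshold fraction in (0, 1\] for the "alternative match
#'   to the reported locus" rescue in step 1; default 0.80.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(read_mismatch_threshold = 0.80,
                          genome_match_threshold = 0.90,
                          recurrence_patient_limit = 8L,
                          alt_match_threshold = 0.80) {
  for (x in c(read_mismatch_threshold, genome_match_threshold,
              alt_match_threshold)) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1) {
      stop("fraction thresholds must lie in (0, 1]")
    }
  }
  if (recurrence_patient_limit < 1L) stop("recurrence_patient_limit must be >= 1")
  structure(
    list(read_mismatch_threshold = read_mismatch_threshold,
         genome_match_threshold = genome_match_threshold,
         recurrence_patient_limit = as.integer(recurrence_patient_limit),
         alt_match_threshold = alt_match_threshold),
    class = "filter_config"
  )
}

#' Clonality rule thresholds
#'
#' The numeric thresholds of the rule engine. A chain is called monoclonal
#' when the top two clones together exceed `dominant_fraction_min` of the
#' chain's CDR3-containing reads (strict \code{>}), or when their sum is at
#' least `ratio_top2_to_third_min` times the third largest clone
#' (\code{>=}). A monoclonal chain is biallelic when the second clone is at
#' least `biallelic_second_to_third_min` times the third. The V-usage rule
#' applies `vusage_top2_to_third_min` to FPKM values the same way.
#'
#' @param dominant_fraction_min default 0.10 (the "10% rule").
#' @param ratio_top2_to_third_min default 10 (the "10x rule").
#' @param biallelic_second_to_third_min default 5.
#' @param vusage_top2_to_third_min default 10.
#' @param normal_max_clone_fraction default 0.02; reference ceiling for any
#'   single clonotype in a polyclonal background, used by the simulator.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(dominant_fraction_min = 0.10,
                        ratio_top2_to_third_min = 10,
                        biallelic_second_to_third_min = 5,
                        vusage_top2_to_third_min = 10,
                        normal_max_clone_fraction = 0.02) {
  vals <- c(dominant_fraction_min, ratio_top2_to_third_min,
            biallelic_second_to_third_min, vusage_top2_to_third_min,
            normal_max_clone_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0)) stop("all rule thresholds must be > 0")
  if (dominant_fraction_min >= 1) stop("dominant_fraction_min must be < 1")
  structure(
    list(dominant_fraction_min = dominant_fraction_min,
         ratio_top2_to_third_min = ratio_top2_to_third_min,
         biallelic_second_to_third_min = biallelic_second_to_third_min,
         vusage_top2_to_third_min = vusage_top2_to_third_min,
         normal_max_clone_fraction = normal_max_clone_fraction),
    class = "rule_config"
  )
}

#' Expression-adequacy thresholds
#'
#' Minimum per-chain RPM below which clonality assessment is unreliable
#' (dominated by infiltrating non-neoplastic T cells). The defaults are the
#' TRA/TRB cutoffs calibrated on NK-cell lymphoma expression; a chain at
#' exactly the cutoff is adequate ("lower than" is strict). TRG/TRD carry no
#' RPM cutoff and are instead gated on a minimum number of CDR3-containing
#' reads.
#'
#' @param tra_min_rpm default 15.82.
#' @param trb_min_rpm default 12.21.
#' @param gd_min_reads minimum CDR3 read total for TRG/TRD assessment;
#'   default 100.
#' @return A list of class `adequacy_thresholds`.
#' @export
adequacy_thresholds <- function(tra_min_rpm = 15.82, trb_min_rpm = 12.21,
                                gd_min_reads = 100L) {
  if (tra_min_rpm <= 0 || trb_min_rpm <= 0) stop("RPM thresholds must be > 0")
  if (gd_min_reads < 0) stop("gd_min_reads must be >= 0")
  structure(
    list(tra_min_rpm = tra_min_rpm, trb_min_rpm = trb_min_rpm,
         gd_min_reads = as.integer(gd_min_reads)),
    class = "adequacy_thresholds"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file with optional top-level sections `filter`, `rules`,
#' `adequacy` and `ebv_min_reads`, each overriding the corresponding
#' defaults.
#'
#' @param path path to a YAML file, or `NULL` for all defaults.
#' @return A list with elements `filter` ([filter_config()]), `rules`
#'   ([rule_config()]), `adequacy` ([adequacy_thresholds()]) and
#'   `ebv_min_reads`.
#' @export
read_pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(fun, section) do.call(fun, as.list(raw[[section]]))
  list(
    filter = build(filter_config, "filter"),
    rules = build(rule_config, "rules"),
    adequacy = build(adequacy_thresholds, "adequacy"),
    ebv_min_reads = if (is.null(raw$ebv_min_reads)) 100L
                    else as.integer(raw$ebv_min_reads)
  )
}
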