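# Per-chain TCR transcript quantification (RPM), expression adequacy, and
# the binomial sampling-error machinery behind the clone-fraction thresholds.

#' Per-chain CDR3 transcript abundance (RPM)
#'
#' Computes the number of CDR3-containing reads per million mapped reads for
#' one chain of one sample:
#' \deqn{RPM = \frac{\sum_i C_i}{N} \times 10^6}
#' where \eqn{C_i} is the read count of clonotype \eqn{i} on the chain and
#' \eqn{N} the sample's total mapped reads.
#'
#' @param sample a [repertoire_sample()].
#' @param chain one of `"TRA"`, `"TRB"`, `"TRG"`, `"TRD"`.
#' @return A list of class `chain_quant` with elements `sample_id`, `chain`,
#'   `rpm`, `cdr3_read_total` and `adequate` (`NA` until
#'   [assess_adequacy()] is applied).
#' @export
compute_rpm <- function(sample, chain) {
  chain <- match.arg(chain, TCR_CHAINS)
  if (!inherits(sample, "repertoire_sample")) stop("expected a repertoire_sample")
  n <- sample$total_mapped_reads
  if (is.na(n) || n <= 0) stop("total_mapped_reads must be > 0")
  counts <- sample$clonotypes$read_count[sample$clonotypes$chain == chain]
  total <- sum(counts)
  structure(
    list(sample_id = sample$sample_id, chain = chain,
         rpm = total / n * 1e6, cdr3_read_total = as.integer(total),
         adequate = NA),
    class = "chain_quant"
  )
}

#' @export
print.chain_quant <- function(x, ...) {
  cat(sprintf("%s %s: RPM %.3f (%d CDR3 reads)%s\n", x$sample_id, x$chain,
              x$rpm, x$cdr3_read_total,
              if (is.na(x$adequate)) "" else
                if (x$adequate) ", adequate" else ", inadequate"))
  invisible(x)
}

#' Assess TRA/TRB expression adequacy
#'
#' A chain is adequate for clonality assessment when its RPM is at or above
#' the chain threshold (`rpm >= tra_min_rpm` for TRA, `rpm >= trb_min_rpm`
#' for TRB); "lower expression than" the cutoff is strict, so a chain at
#' exactly the threshold is adequate. Each chain is assessed independently:
#' a sample with one adequate and one inadequate chain is still assessable
#' on the adequate chain.
#'
#' @param quant_tra,quant_trb `chain_quant` objects of the same sample for
#'   TRA and TRB.
#' @param thr an [adequacy_thresholds()].
#' @return A list with elements `TRA` and `TRB`, the input quantifications
#'   with `adequate` set.
#' @export
assess_adequacy <- function(quant_tra, quant_trb,
                            thr = adequacy_thresholds()) {
  if (quant_tra$sample_id != quant_trb$sample_id) {
    stop("adequacy assessed across different samples: ",
         quant_tra$sample_id, " vs ", quant_trb$sample_id)
  }
  if (quant_tra$chain != "TRA" || quant_trb$chain != "TRB") {
    stop("assess_adequacy expects a TRA and a TRB quantification, in order")
  }
  quant_tra$adequate <- quant_tra$rpm >= thr$tra_min_rpm
  quant_trb$adequate <- quant_trb$rpm >= thr$trb_min_rpm
  list(TRA = quant_tra, TRB = quant_trb)
}

# TRG/TRD have no published RPM cutoff; gate on CDR3 read depth instead.
assess_adequacy_depth <- function(quant, thr = adequacy_thresholds()) {
  quant$adequate <- quant$cdr3_read_total >= thr$gd_min_reads
  quant
}

#' Standard error of an observed clone proportion
#'
#' With \eqn{n} CDR3-containing reads, the observed fraction of a clone with
#' true proportion \eqn{p} has binomial standard error
#' \deqn{SE = \sqrt{p (1 - p) / n}.}
#' This is the error model used to justify the dominant-fraction threshold.
#'
#' @param p proportion(s) in \[0, 1\].
#' @param n positive integer read depth(s).
#' @return Numeric vector of standard errors.
#' @export
clone_proportion_se <- function(p, n) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(!is.finite(n)) || any(n < 1)) stop("n must be a positive integer")
  sqrt(p * (1 - p) / n)
}

#' Sampling-error profile over candidate clone-fraction thresholds
#'
#' For each candidate threshold \eqn{t} the binomial standard error at
#' \eqn{p = t} and depth `n`, and the relative error \eqn{SE/t} used to
#' balance error rate against sensitivity when fixing the dominant-clone
#' threshold.
#'
#' @param n read depth (the study's observed median CDR3 depth is 1484).
#' @param thresholds numeric grid strictly inside (0, 1).
#' @return A data.frame with columns `threshold`, `se`, `se_over_threshold`,
#'   sorted by threshold.
#' @export
threshold_error_curve <- function(n, thresholds) {
  if (!length(thresholds)) stop("threshold grid is empty")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  thresholds <- sort(thresholds)
  se <- clone_proportion_se(thresholds, n)
  data.frame(threshold = thresholds, se = se,
             se_over_threshold = se / thresholds)
}
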