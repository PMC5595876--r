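# tcrclonality

Assessment of T-cell receptor (TCR) clonality and repertoire structure
from clonotype tables extracted from bulk RNA-seq.

T-cell lymphomas are clonal expansions of mature T cells, and each T-cell
clone is uniquely tagged by the nucleotide sequence of its CDR3 junction.
Bulk RNA-seq of a tumor captures the CDR3 repertoire of the neoplastic
clone together with infiltrating normal T cells, so clonotype tables
extracted from it (e.g. by MiXCR) can substitute for PCR-based clonality
assays — provided the table is decontaminated, the chain is expressed
highly enough to be assessable, and the decision rules account for
read-sampling error. This package implements that pipeline for
hematopathology and immunogenomics analysts:

* **Decontamination** — three filters on extracted clonotypes: removal of
  reads matching non-TCR or different-TCR regions at >80% with no
  alternative on-locus match, removal of clones whose CDR3 matches the
  genome at >90% (a real junction carries nontemplated bases), and removal
  of CDR3s recurring in more than 8 patient cases.
* **Quantification** — per-chain transcript level as CDR3-containing
  reads per million mapped reads, RPM = (Σᵢ Cᵢ / N) × 10⁶, with adequacy
  gates RPM ≥ 15.82 (TRA) and ≥ 12.21 (TRB).
* **Sampling error** — binomial SE of an observed clone fraction,
  SE = √(p(1−p)/n), and the SE/threshold curve behind the 10% rule.
* **Clonality rules** — with c₁ ≥ c₂ ≥ c₃ the top clone read counts and T
  the chain total: monoclonal when (c₁+c₂)/T > 10% or (c₁+c₂)/c₃ ≥ 10;
  biallelic when c₂/c₃ ≥ 5; a V-usage FPKM fallback rule with CDR3
  precedence; case status from per-chain calls.
* **Cohort statistics** — top-10 clonotype profiles, V-gene usage tables,
  Fisher's exact test for mutation–clonality association, Welch's t-test
  on C1/C2 ratios by second-allele productivity, EBV positivity at ≥100
  virus-mapped reads.
* **Synthetic cohorts** — a V(D)J junction simulator and repertoire
  generator (2%-capped polyclonal backgrounds, tumor spikes, biallelic
  alleles with nonsense-mediated-decay attenuation, multinomial read
  sampling at 500–2400 reads, contaminants targeting each filter step)
  with ground truth, so the whole pipeline is testable without patient
  data.

## Worked example

Simulate one monoclonal sample with a nonproductive second allele and
injected contaminants, then assess it:

```r
library(tcrclonality)

cfg <- sim_config(seed = 42, tumor_fraction = 0.3, biallelic = TRUE,
                  second_allele_productive = FALSE, n_cdr3_reads = 1484,
                  contaminant_rates = c(genomic = 0.03, cross_locus = 0.03))
pool <- generate_clone_pool(cfg)
tbl  <- sample_reads(pool, 1484, seed = 7)
inj  <- inject_contaminants(tbl, cfg, seed = 8)
s    <- repertoire_sample("S1", inj$table, total_mapped_reads = 3e7)
fit  <- tcr_clonality(s, read_hits = inj$read_hits,
                      genome_hits = inj$genome_hits)
summary(fit)
#> Sample S1 - monoclonal
#> 38 clone(s) removed by filtering
#>  chain     status rule_fired biallelic  c1  c2 c3 top2_fraction top2_to_third
#>    TRB monoclonal       both      TRUE 457 101  6         0.376            93
#>    rpm adequate source conflict
#>  49.47     TRUE   cdr3    FALSE
```

All 38 injected contaminants were removed before quantification
(`fit$filter_audit`), the chain is adequately expressed (RPM 49.5 ≥
12.21), the top two clones hold 37.6% of CDR3 reads (>10%, fraction rule)
and are 93× the third clone (≥10, ratio rule), and the second clone at
101/6 ≈ 17× the third (≥5) flags a biallelic rearrangement. The observed
C1/C2 ≈ 4.5 reflects the simulated 0.25 expression of the nonproductive
allele.

The sampling-error analysis behind the 10% threshold, at the typical
median depth of 1484 CDR3-containing reads:

```r
threshold_error_curve(1484, c(0.02, 0.05, 0.10, 0.20))
#>   threshold          se se_over_threshold
#> 1      0.02 0.003634219        0.18171095
#> 2      0.05 0.005657569        0.11315138
#> 3      0.10 0.007787612        0.07787612
#> 4      0.20 0.010383483        0.05191741
```

Cohort-level runs go through `run_pipeline(sample_sheet, config, out_dir)`
(filter → quantify → classify → reconcile → report, with a TSV/JSON report
and a run manifest); `inst/scripts/tcrclonality.R` wraps the same
functions for shell use.

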