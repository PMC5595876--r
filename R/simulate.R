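# Synthetic repertoire generator: polyclonal backgrounds capped at a 2%
# clone fraction, monoclonal spike-ins with optional biallelic second
# alleles (attenuated when nonproductive, emulating nonsense-mediated
# decay), multinomial read sampling at realistic CDR3 depths, and
# contaminants targeting each decontamination filter step. Everything is a
# pure function of (config, seed).

the_cache <- new.env(parent = emptyenv())

#' Load the bundled toy germline segment set
#'
#' Ten V and five J segments per chain (plus D segments for TRB/TRD),
#' shipped as a synthetic FASTA fixture. V segments end, in frame, at the
#' conserved CDR3 cysteine codon; J segment starts are stop-free in frame.
#'
#' @return A data.frame with columns `gene`, `segment`, `chain`, `seq`.
#' @export
load_toy_germline <- function() {
  if (!is.null(the_cache$germline)) return(the_cache$germline)
  path <- system.file("extdata", "synthetic_tcr_germline.fasta",
                      package = "tcrclonality")
  seqs <- Biostrings::readDNAStringSet(path)
  meta <- strsplit(names(seqs), " ", fixed = TRUE)
  df <- data.frame(
    gene = vapply(meta, `[`, "", 1L),
    segment = sub("segment=", "", vapply(meta, `[`, "", 2L)),
    chain = sub("chain=", "", vapply(meta, `[`, "", 3L)),
    seq = as.character(seqs),
    stringsAsFactors = FALSE
  )
  the_cache$germline <- df
  df
}

#' Load the bundled toy genome
#'
#' @return A single character string (a synthetic 20 kb non-TCR contig).
#' @export
load_toy_genome <- function() {
  if (!is.null(the_cache$genome)) return(the_cache$genome)
  path <- system.file("extdata", "synthetic_genome.fasta",
                      package = "tcrclonality")
  g <- as.character(Biostrings::readDNAStringSet(path))[[1]]
  the_cache$genome <- g
  g
}

#' Simulation configuration
#'
#' Defines the statistical structure of one synthetic repertoire sample.
#'
#' @param seed integer RNG seed.
#' @param chain the simulated chain (default `"TRB"`).
#' @param n_background_clones number of polyclonal background clones
#'   (default 2000).
#' @param background_distribution `"dirichlet"` (symmetric, parameter
#'   `dirichlet_alpha`) or `"powerlaw"` (rank-frequency exponent
#'   `powerlaw_exponent`).
#' @param dirichlet_alpha,powerlaw_exponent distribution parameters.
#' @param max_background_fraction cap on any single background clone's
#'   frequency (default 0.02, the polyclonal reference ceiling).
#' @param tumor_fraction dominant-clone transcript fraction in \[0, 1);
#'   0 simulates a purely polyclonal sample.
#' @param biallelic whether a second tumor allele is expressed.
#' @param second_allele_relative_expression expression of the second allele
#'   relative to the first (default 0.25, emulating NMD attenuation of a
#'   nonproductive allele).
#' @param second_allele_productive logical; when `FALSE` the second allele's
#'   CDR3 is generated frameshifted or with a stop codon.
#' @param n_cdr3_reads CDR3-containing read depth; `NA` draws uniformly
#'   from 500..2400 (the observed range; median 1484).
#' @param total_mapped_reads library size; `NA` derives it so the chain RPM
#'   is about `rpm_target`.
#' @param rpm_target chain RPM used to derive the library size (default 50).
#' @param contaminant_rates named numeric: `genomic`, `cross_locus`,
#'   `public` contaminant rates in \[0, 1\] (fractions of the sampled clone
#'   table).
#' @param public_span number of cohort samples sharing each public clone
#'   (default 9, one above the recurrence limit).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, chain = "TRB",
                       n_background_clones = 2000L,
                       background_distribution = c("dirichlet", "powerlaw"),
                       dirichlet_alpha = 1, powerlaw_exponent = 1.5,
                       max_background_fraction = 0.02,
                       tumor_fraction = 0,
                       biallelic = FALSE,
                       second_allele_relative_expression = 0.25,
                       second_allele_productive = TRUE,
                       n_cdr3_reads = NA_integer_,
                       total_mapped_reads = NA_real_,
                       rpm_target = 50,
                       contaminant_rates = c(genomic = 0, cross_locus = 0,
                                             public = 0),
                       public_span = 9L) {
  background_distribution <- match.arg(background_distribution)
  chain <- match.arg(chain, TCR_CHAINS)
  if (tumor_fraction < 0 || tumor_fraction >= 1) {
    stop("tumor_fraction must lie in [0, 1)")
  }
  if (biallelic && tumor_fraction == 0) {
    stop("biallelic = TRUE requires tumor_fraction > 0")
  }
  if (second_allele_relative_expression <= 0 ||
      second_allele_relative_expression > 1) {
    stop("second_allele_relative_expression must lie in (0, 1]")
  }
  rates <- c(genomic = 0, cross_locus = 0, public = 0)
  rates[names(contaminant_rates)] <- contaminant_rates
  if (any(rates < 0 | rates > 1)) stop("contaminant rates must lie in [0, 1]")
  structure(
    list(seed = as.integer(seed), chain = chain,
         n_background_clones = as.integer(n_background_clones),
         background_distribution = background_distribution,
         dirichlet_alpha = dirichlet_alpha,
         powerlaw_exponent = powerlaw_exponent,
         max_background_fraction = max_background_fraction,
         tumor_fraction = tumor_fraction, biallelic = biallelic,
         second_allele_relative_expression = second_allele_relative_expression,
         second_allele_productive = second_allele_productive,
         n_cdr3_reads = n_cdr3_reads,
         total_mapped_reads = total_mapped_reads, rpm_target = rpm_target,
         contaminant_rates = rates, public_span = as.integer(public_span)),
    class = "sim_config"
  )
}

rand_base_string <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate polyclonal background clone frequencies
#'
#' Draws `n_background_clones` frequencies from the configured clone-size
#' law, resampling (Dirichlet) until no clone exceeds
#' `max_background_fraction`, then scales the vector to sum to
#' `1 - tumor_fraction` so a tumor spike can be added on top.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return Numeric frequency vector summing to `1 - tumor_fraction`; every
#'   entry is at most `max_background_fraction * (1 - tumor_fraction)`.
#' @export
generate_background <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$n_background_clones
  if (k < 10L) stop("need at least 10 background clones")
  cap <- cfg$max_background_fraction
  if (k * cap < 1) {
    stop("infeasible cap: ", k, " clones cannot each stay below ", cap)
  }
  if (cfg$background_distribution == "dirichlet") {
    for (try in 1:1000) {
      x <- stats::rgamma(k, shape = cfg$dirichlet_alpha)
      f <- x / sum(x)
      if (max(f) <= cap) break
      if (try == 1000) stop("background cap rejection did not converge")
    }
  } else {
    f <- (seq_len(k))^(-cfg$powerlaw_exponent)
    f <- f / sum(f)
    if (max(f) > cap) {
      stop("power-law background violates the clone-fraction cap; ",
           "lower the exponent or raise the clone count")
    }
  }
  f * (1 - cfg$tumor_fraction)
}

#' Generate one CDR3 nucleotide sequence by V(D)J junction simulation
#'
#' Concatenates the 3' end of the V segment (0-5 bases trimmed), 0-10
#' nontemplated N bases, an optional D-segment fragment (TRB/TRD), 0-10
#' more N bases, and the 5' start of the J segment (0-5 bases trimmed).
#' The result is at least 18 nt.
#'
#' @param v_gene,j_gene gene names from the bundled toy germline set.
#' @param d_gene optional D gene name.
#' @param seed optional RNG seed.
#' @return A CDR3 nucleotide string.
#' @export
generate_cdr3_sequence <- function(v_gene, j_gene, d_gene = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  germ <- load_toy_germline()
  vrow <- germ[germ$gene == v_gene & germ$segment == "V", ]
  jrow <- germ[germ$gene == j_gene & germ$segment == "J", ]
  if (!nrow(vrow)) stop("unknown V gene: ", v_gene)
  if (!nrow(jrow)) stop("unknown J gene: ", j_gene)
  v_tail <- substr(vrow$seq, nchar(vrow$seq) - 14L, nchar(vrow$seq))
  j_head <- substr(jrow$seq, 1L, 15L)
  v_trim <- sample(0:5, 1L)
  j_trim <- sample(0:5, 1L)
  n1 <- rand_base_string(sample(0:10, 1L))
  n2 <- rand_base_string(sample(0:10, 1L))
  d_frag <- ""
  if (!is.null(d_gene) && nzchar(d_gene)) {
    drow <- germ[germ$gene == d_gene & germ$segment == "D", ]
    if (!nrow(drow)) stop("unknown D gene: ", d_gene)
    dlen <- sample(0:nchar(drow$seq), 1L)
    if (dlen > 0) {
      start <- sample(seq_len(nchar(drow$seq) - dlen + 1L), 1L)
      d_frag <- substr(drow$seq, start, start + dlen - 1L)
    }
  }
  paste0(substr(v_tail, 1L, 15L - v_trim), n1, d_frag, n2,
         substring(j_head, 1L + j_trim))
}

# vectorized junction generation for n clones of one chain
r_cdr3_batch <- function(n, chain) {
  germ <- load_toy_germline()
  vg <- germ$gene[germ$segment == "V" & germ$chain == chain]
  jg <- germ$gene[germ$segment == "J" & germ$chain == chain]
  dg <- germ$gene[germ$segment == "D" & germ$chain == chain]
  v <- sample(vg, n, replace = TRUE)
  j <- sample(jg, n, replace = TRUE)
  d <- if (length(dg)) sample(dg, n, replace = TRUE) else rep("", n)
  v_tails <- stats::setNames(
    substr(germ$seq, nchar(germ$seq) - 14L, nchar(germ$seq)), germ$gene)
  j_heads <- stats::setNames(substr(germ$seq, 1L, 15L), germ$gene)
  d_seqs <- stats::setNames(germ$seq, germ$gene)
  v_trim <- sample(0:5, n, replace = TRUE)
  j_trim <- sample(0:5, n, replace = TRUE)
  l1 <- sample(0:10, n, replace = TRUE)
  l2 <- sample(0:10, n, replace = TRUE)
  pool_len <- sum(l1) + sum(l2)
  pool <- rand_base_string(pool_len)
  ends <- cumsum(c(l1, l2))
  starts <- ends - c(l1, l2) + 1L
  ins <- substring(pool, starts, ends)
  n1 <- ins[seq_len(n)]
  n2 <- ins[n + seq_len(n)]
  d_frag <- rep("", n)
  has_d <- nzchar(d)
  if (any(has_d)) {
    dl <- nchar(d_seqs[d[has_d]])
    take <- floor(stats::runif(sum(has_d)) * (dl + 1L))
    start <- 1L + floor(stats::runif(sum(has_d)) * (dl - take + 1L))
    d_frag[has_d] <- substring(d_seqs[d[has_d]], start, start + take - 1L)
  }
  cdr3 <- paste0(substr(v_tails[v], 1L, 15L - v_trim), n1, d_frag, n2,
                 substring(j_heads[j], 1L + j_trim))
  data.frame(v_gene = v, d_gene = d, j_gene = j, cdr3_nt = cdr3,
             stringsAsFactors = FALSE)
}

#' Build the full clone pool of one sample
#'
#' Background frequencies plus the tumor spike, with clone identities
#' (V/(D)/J assignment and simulated CDR3 junction) attached.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return A data.frame with columns `clone_id`, `chain`, `v_gene`,
#'   `d_gene`, `j_gene`, `cdr3_nt`, `freq`, `role`
#'   (`background`/`tumor_allele1`/`tumor_allele2`); `freq` sums to 1.
#' @export
generate_clone_pool <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  bg <- generate_background(cfg, seed = NULL)
  spiked <- spike_tumor(bg, cfg, seed = NULL)
  ids <- r_cdr3_batch(length(bg), cfg$chain)
  n_t <- length(spiked$frequencies) - length(bg)
  pool <- data.frame(
    clone_id = c(if (n_t >= 1L) "tumor1", if (n_t == 2L) "tumor2",
                 sprintf("bg%05d", seq_along(bg))),
    chain = cfg$chain,
    stringsAsFactors = FALSE
  )
  tum <- spiked$tumor_clones
  pool$v_gene <- c(tum$v_gene, ids$v_gene)
  pool$d_gene <- c(tum$d_gene, ids$d_gene)
  pool$j_gene <- c(tum$j_gene, ids$j_gene)
  pool$cdr3_nt <- c(tum$cdr3_nt, ids$cdr3_nt)
  pool$freq <- spiked$frequencies
  pool$role <- c(rep(c("tumor_allele1", "tumor_allele2"),
                     length.out = n_t)[seq_len(n_t)],
                 rep("background", length(bg)))
  pool
}

#' Spike a dominant tumor clone into a polyclonal background
#'
#' Adds one dominant clone at `tumor_fraction` and, when `biallelic`, a
#' second allele at `tumor_fraction * second_allele_relative_expression`,
#' renormalizing the whole vector. The second allele's CDR3 is generated
#' nonproductive (frameshifted or carrying a stop codon) when
#' `second_allele_productive` is `FALSE`.
#'
#' @param background frequency vector from [generate_background()] (sums to
#'   `1 - tumor_fraction`).
#' @param cfg a [sim_config()].
#' @param seed optional RNG seed.
#' @return A list with `frequencies` (tumor clones first, renormalized to
#'   sum 1) and `tumor_clones` (data.frame of tumor clone identities;
#'   zero rows for a polyclonal sample).
#' @export
spike_tumor <- function(background, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(v_gene = character(0), d_gene = character(0),
                      j_gene = character(0), cdr3_nt = character(0),
                      productive = character(0), stringsAsFactors = FALSE)
  if (cfg$tumor_fraction == 0) {
    if (cfg$biallelic) stop("biallelic spike requires tumor_fraction > 0")
    return(list(frequencies = background / sum(background),
                tumor_clones = empty))
  }
  tf <- cfg$tumor_fraction
  germ <- load_toy_germline()
  make_allele <- function(productive) {
    for (try in 1:200) {
      row <- r_cdr3_batch(1L, cfg$chain)
      prod <- annotate_productivity(row$cdr3_nt)
      if ((productive && prod == "productive") ||
          (!productive && prod == "nonproductive")) {
        row$productive <- prod
        return(row)
      }
    }
    stop("could not generate a CDR3 with the requested productivity")
  }
  tum <- make_allele(TRUE)
  freqs <- tf
  if (cfg$biallelic) {
    tum <- rbind(tum, make_allele(cfg$second_allele_productive))
    freqs <- c(tf, tf * cfg$second_allele_relative_expression)
  }
  all_f <- c(freqs, background)
  list(frequencies = all_f / sum(all_f), tumor_clones = tum)
}

#' Sample reads from a clone pool
#'
#' One multinomial draw of `n_reads` over the pool's frequencies; clones
#' with zero sampled reads are omitted and the returned read counts sum to
#' `n_reads`.
#'
#' @param pool a clone pool from [generate_clone_pool()] (`freq` must sum
#'   to 1 within 1e-9).
#' @param n_reads number of CDR3-containing reads to draw.
#' @param seed optional RNG seed.
#' @return A clonotype table.
#' @export
sample_reads <- function(pool, n_reads, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(pool$freq) - 1) > 1e-9) {
    stop("pool frequencies must sum to 1 (got ", sum(pool$freq), ")")
  }
  if (n_reads < 1) stop("n_reads must be >= 1")
  counts <- as.integer(stats::rmultinom(1L, n_reads, pool$freq))
  keep <- counts > 0L
  out <- pool[keep, c("clone_id", "chain", "cdr3_nt", "v_gene", "d_gene",
                      "j_gene")]
  out$cdr3_aa <- ""
  out$read_count <- counts[keep]
  out$productive <- annotate_productivity(out$cdr3_nt)
  rownames(out) <- NULL
  validate_clonotypes(out[, c("clone_id", "chain", "cdr3_nt", "cdr3_aa",
                              "v_gene", "d_gene", "j_gene", "read_count",
                              "productive")])
}

#' Inject contaminants and emit matching alignment evidence
#'
#' Adds (i) genomic contaminants whose CDR3 is a contiguous substring of
#' the bundled toy genome (genome hit at match fraction 1.0; removed by
#' filter step 2), (ii) cross-locus mimics with a non-TCR read hit above
#' 0.8 and no alternative same-locus hit (removed by step 1), and (iii)
#' supplied public clones (removed by step 3 when present in more samples
#' than the recurrence limit). Genuine clones receive a strong same-locus
#' read hit and a partial genome hit, so no filter step removes them.
#'
#' @param table a clonotype table from [sample_reads()].
#' @param cfg a [sim_config()]; `contaminant_rates` control how many
#'   contaminants are added relative to the table size.
#' @param seed optional RNG seed.
#' @param public_clones optional data.frame of shared public clone
#'   identities (columns `cdr3_nt`, `v_gene`, `d_gene`, `j_gene`) to
#'   append to this sample.
#' @return A list with `table` (clones + contaminants), `read_hits`,
#'   `genome_hits` (both [alignment_hits()] with a `query_id` per clone),
#'   and `contaminant_ids` (named list by category).
#' @export
inject_contaminants <- function(table, cfg, seed = NULL,
                                public_clones = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- cfg$contaminant_rates
  if ((rates["genomic"] > 0) && is.null(load_toy_genome())) {
    stop("genomic contaminant rate set but no bundled genome available")
  }
  n0 <- nrow(table)
  chain <- cfg$chain
  germ <- load_toy_germline()
  vg <- germ$gene[germ$segment == "V" & germ$chain == chain]
  jg <- germ$gene[germ$segment == "J" & germ$chain == chain]
  contaminant_ids <- list(genomic = character(0), cross_locus = character(0),
                          public = character(0))

  add_rows <- function(tbl, ids, cdr3) {
    data.frame(clone_id = ids, chain = chain, cdr3_nt = cdr3, cdr3_aa = "",
               v_gene = sample(vg, length(ids), replace = TRUE),
               d_gene = "", j_gene = sample(jg, length(ids), replace = TRUE),
               read_count = 1L + stats::rpois(length(ids), 2),
               productive = annotate_productivity(cdr3),
               stringsAsFactors = FALSE)
  }

  n_gen <- round(rates["genomic"] * n0)
  if (n_gen > 0) {
    genome <- load_toy_genome()
    start <- sample(nchar(genome) - 45L, n_gen)
    cdr3 <- substring(genome, start, start + 44L)
    ids <- sprintf("contam_gen%03d", seq_len(n_gen))
    table <- rbind(table, add_rows(table, ids, cdr3))
    contaminant_ids$genomic <- ids
  }
  n_x <- round(rates["cross_locus"] * n0)
  if (n_x > 0) {
    cdr3 <- vapply(seq_len(n_x), function(i) rand_base_string(42L), "")
    ids <- sprintf("contam_xloc%03d", seq_len(n_x))
    table <- rbind(table, add_rows(table, ids, cdr3))
    contaminant_ids$cross_locus <- ids
  }
  if (!is.null(public_clones) && nrow(public_clones)) {
    ids <- sprintf("public%03d", seq_len(nrow(public_clones)))
    rows <- data.frame(clone_id = ids, chain = chain,
                       cdr3_nt = public_clones$cdr3_nt, cdr3_aa = "",
                       v_gene = public_clones$v_gene,
                       d_gene = public_clones$d_gene,
                       j_gene = public_clones$j_gene,
                       read_count = 1L + stats::rpois(length(ids), 2),
                       productive = annotate_productivity(public_clones$cdr3_nt),
                       stringsAsFactors = FALSE)
    table <- rbind(table, rows)
    contaminant_ids$public <- ids
  }
  rownames(table) <- NULL

  id <- table$clone_id
  kind <- rep("genuine", nrow(table))
  kind[id %in% contaminant_ids$genomic] <- "genomic"
  kind[id %in% contaminant_ids$cross_locus] <- "cross_locus"

  # read-level evidence: genuine clones (and genomic contaminants, which
  # MiXCR reported on-locus) match their reported locus strongly; mimics
  # match elsewhere with no alternative
  read_hits <- alignment_hits(
    id,
    ifelse(kind == "cross_locus", "non_tcr", "same_tcr_locus"),
    ifelse(kind == "cross_locus",
           stats::runif(nrow(table), 0.82, 0.99),
           stats::runif(nrow(table), 0.92, 1.00))
  )
  # CDR3-vs-genome evidence: contiguous genomic contaminants match fully;
  # genuine junctions only via their templated V/J portions
  genome_hits <- alignment_hits(
    id, "non_tcr",
    ifelse(kind == "genomic", 1.0, stats::runif(nrow(table), 0.55, 0.85))
  )
  list(table = validate_clonotypes(table), read_hits = read_hits,
       genome_hits = genome_hits, contaminant_ids = contaminant_ids)
}

derive_seed <- function(master, i, stage = 0L) {
  as.integer((as.double(master) * 7919 + i * 104729 + stage * 31337) %%
               2147483000)
}

#' Generate a synthetic cohort with ground truth
#'
#' Generates one repertoire sample per configuration, with deterministic
#' per-sample child seeds derived from `master_seed`. Mutation status is
#' drawn with configurable dependence on the true clonality (to exercise
#' the mutation-association test) and EBV-mapped read counts from a
#' two-component mixture straddling the 100-read positivity threshold.
#' Public clones are shared verbatim across the first `public_span`
#' samples when any configuration requests them.
#'
#' @param configs a list of [sim_config()]s (one per sample) or a single
#'   config recycled `n_samples` times.
#' @param n_samples number of samples when `configs` is a single config.
#' @param master_seed integer master seed.
#' @param p_mut_given_mono,p_mut_given_poly probability of
#'   mutation-positivity given true clonality status.
#' @param ebv_pos_rate fraction of samples drawn from the high (EBV
#'   positive) mixture component.
#' @param out_dir optional directory; when given, writes per-sample native
#'   clonotype and hit TSVs, a sample sheet, and a ground-truth TSV.
#' @return A list of class `synthetic_cohort` with `samples` (list of
#'   [repertoire_sample()]), `read_hits`, `genome_hits` (named lists),
#'   `truth` (data.frame), and `public_clones`.
#' @export
generate_cohort <- function(configs, n_samples = NULL, master_seed = 1L,
                            p_mut_given_mono = 0.85, p_mut_given_poly = 0.25,
                            ebv_pos_rate = 0.5, out_dir = NULL) {
  if (inherits(configs, "sim_config")) {
    if (is.null(n_samples)) stop("n_samples required with a single config")
    configs <- rep(list(configs), n_samples)
  }
  n <- length(configs)
  if (n < 1L) stop("need at least one sample configuration")

  # shared public clone identities, if any config asks for them
  any_public <- any(vapply(configs,
                           function(c) c$contaminant_rates["public"] > 0, TRUE))
  public_clones <- NULL
  public_span <- 0L
  if (any_public) {
    set.seed(derive_seed(master_seed, 0L, 9L))
    rate <- max(vapply(configs,
                       function(c) c$contaminant_rates["public"], 1.0))
    n_public <- max(1L, round(rate * 100))
    ch <- configs[[1]]$chain
    public_clones <- r_cdr3_batch(n_public, ch)
    public_span <- max(vapply(configs, function(c) c$public_span, 1L))
  }

  samples <- list(); read_hits <- list(); genome_hits <- list()
  truth <- list()
  for (i in seq_len(n)) {
    cfg <- configs[[i]]
    sid <- sprintf("S%03d", i)
    pool <- generate_clone_pool(cfg, seed = derive_seed(master_seed, i, 1L))
    set.seed(derive_seed(master_seed, i, 2L))
    n_reads <- if (is.na(cfg$n_cdr3_reads)) sample(500:2400, 1L)
               else cfg$n_cdr3_reads
    tbl <- sample_reads(pool, n_reads, seed = NULL)
    inj <- inject_contaminants(
      tbl, cfg, seed = derive_seed(master_seed, i, 3L),
      public_clones = if (!is.null(public_clones) && i <= public_span)
        public_clones else NULL)
    set.seed(derive_seed(master_seed, i, 4L))
    true_mono <- cfg$tumor_fraction > 0
    mut <- stats::runif(1) < if (true_mono) p_mut_given_mono
                             else p_mut_given_poly
    ebv <- if (stats::runif(1) < ebv_pos_rate) stats::rpois(1, 600)
           else stats::rpois(1, 10)
    n_mapped <- if (is.na(cfg$total_mapped_reads)) {
      round(sum(inj$table$read_count) / cfg$rpm_target * 1e6)
    } else cfg$total_mapped_reads
    samples[[sid]] <- repertoire_sample(
      sid, inj$table, n_mapped,
      subtype = if (true_mono) "PTCL" else "normal",
      mutation_positive = mut, ebv_read_count = ebv)
    read_hits[[sid]] <- inj$read_hits
    genome_hits[[sid]] <- inj$genome_hits
    tumor_ids <- inj$table$clone_id[
      inj$table$clone_id %in% c("tumor1", "tumor2")]
    truth[[sid]] <- data.frame(
      sample_id = sid,
      true_status = if (true_mono) "monoclonal" else "polyclonal",
      true_biallelic = cfg$biallelic,
      tumor_clone_ids = paste(tumor_ids, collapse = ","),
      contaminant_ids = paste(unlist(inj$contaminant_ids), collapse = ","),
      mutation_positive = mut, ebv_read_count = ebv,
      n_cdr3_reads = n_reads, tumor_fraction = cfg$tumor_fraction,
      stringsAsFactors = FALSE)
  }
  out <- structure(
    list(samples = samples, read_hits = read_hits,
         genome_hits = genome_hits,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         public_clones = public_clones),
    class = "synthetic_cohort"
  )
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits native clonotype TSVs, read- and genome-hit TSVs, a sample sheet
#' and the ground-truth table under `out_dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- list()
  for (sid in names(cohort$samples)) {
    s <- cohort$samples[[sid]]
    cf <- file.path(out_dir, paste0(sid, "_clones.tsv"))
    rf <- file.path(out_dir, paste0(sid, "_read_hits.tsv"))
    gf <- file.path(out_dir, paste0(sid, "_genome_hits.tsv"))
    write_clonotype_table(s$clonotypes, cf)
    write_alignment_hits(cohort$read_hits[[sid]], rf)
    write_alignment_hits(cohort$genome_hits[[sid]], gf)
    sheet[[sid]] <- data.frame(
      sample_id = sid, subtype = s$subtype,
      total_mapped_reads = s$total_mapped_reads,
      mutation_positive = s$mutation_positive,
      ebv_read_count = s$ebv_read_count,
      clonotype_file = basename(cf), hits_file = basename(rf),
      genome_hits_file = basename(gf), fpkm_file = NA,
      stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, c(sheet, list(make.row.names = FALSE))),
                     file.path(out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
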