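# The synthetic repertoire generator.

test_that("background frequencies respect the clone-fraction cap", {
  cfg <- sim_config(seed = 1, n_background_clones = 2000)
  f <- generate_background(cfg)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_true(all(f <= 0.02))

  cfg2 <- sim_config(seed = 1, tumor_fraction = 0.4)
  f2 <- generate_background(cfg2)
  expect_equal(sum(f2), 0.6, tolerance = 1e-12)
  expect_true(all(f2 <= 0.02 * 0.6))

  expect_identical(generate_background(cfg), generate_background(cfg))
  expect_error(generate_background(sim_config(n_background_clones = 20,
                                              max_background_fraction = 0.02)),
               "infeasible cap")
})

test_that("power-law backgrounds are monotone in rank", {
  cfg <- sim_config(seed = 2, background_distribution = "powerlaw",
                    powerlaw_exponent = 0.5, n_background_clones = 5000,
                    max_background_fraction = 0.02)
  f <- generate_background(cfg)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f <= 0.02))
})

test_that("junction simulation concatenates V tail, N bases, D, and J head", {
  germ <- load_toy_germline()
  v_seq <- germ$seq[germ$gene == "TRBV1"]
  j_seq <- germ$seq[germ$gene == "TRBJ2"]
  v_tail <- substr(v_seq, nchar(v_seq) - 14, nchar(v_seq))
  j_head <- substr(j_seq, 1, 15)
  for (seed in 1:20) {
    s <- generate_cdr3_sequence("TRBV1", "TRBJ2", d_gene = "TRBD1",
                                seed = seed)
    expect_gte(nchar(s), 18)
    # at most 5 trimmed bases: the first/last 10 are always templated
    expect_equal(substr(s, 1, 10), substr(v_tail, 1, 10))
    expect_equal(substr(s, nchar(s) - 9, nchar(s)),
                 substr(j_head, 6, 15))
  }
  expect_identical(generate_cdr3_sequence("TRBV1", "TRBJ2", seed = 9),
                   generate_cdr3_sequence("TRBV1", "TRBJ2", seed = 9))
  expect_error(generate_cdr3_sequence("TRBV99", "TRBJ2"), "unknown V")
})

test_that("in-frame junction fraction matches an independent convolution", {
  # length mod 3 of the junction: (15 - vt) + (15 - jt) + l1 + l2 + d
  # with vt, jt ~ U{0..5}, l1, l2 ~ U{0..10}, d ~ U{0..14} nested-uniform;
  # enumerate the exact distribution and compare with simulation
  germ <- load_toy_germline()
  dlen <- 14L
  d_mod <- rep(0, 3)
  for (take in 0:dlen) {
    d_mod[(take %% 3) + 1] <- d_mod[(take %% 3) + 1] + 1 / (dlen + 1)
  }
  conv <- function(p, q) {
    out <- rep(0, 3)
    for (i in 0:2) for (j in 0:2) {
      out[((i + j) %% 3) + 1] <- out[((i + j) %% 3) + 1] + p[i + 1] * q[j + 1]
    }
    out
  }
  unif_mod <- function(vals) {
    p <- rep(0, 3)
    for (v in vals) p[(v %% 3) + 1] <- p[(v %% 3) + 1] + 1 / length(vals)
    p
  }
  p_total <- Reduce(conv, list(unif_mod(15 - (0:5)), unif_mod(15 - (0:5)),
                               unif_mod(0:10), unif_mod(0:10), d_mod))
  expected_in_frame <- p_total[1]

  set.seed(404)
  seqs <- tcrclonality:::r_cdr3_batch(20000, "TRB")
  observed <- mean(nchar(seqs$cdr3_nt) %% 3 == 0)
  expect_equal(observed, expected_in_frame, tolerance = 0.05)
  # productive implies in frame
  prod <- annotate_productivity(seqs$cdr3_nt[1:2000])
  expect_true(all(nchar(seqs$cdr3_nt[1:2000])[prod == "productive"] %% 3 == 0))
})

test_that("tumor spiking lands the dominant clone at the configured fraction", {
  cfg <- sim_config(seed = 5, tumor_fraction = 0.5)
  bg <- generate_background(cfg)
  sp <- spike_tumor(bg, cfg, seed = 55)
  expect_equal(max(sp$frequencies), 0.5, tolerance = 1e-12)
  expect_equal(sum(sp$frequencies), 1, tolerance = 1e-12)

  cfgb <- sim_config(seed = 5, tumor_fraction = 0.4, biallelic = TRUE,
                     second_allele_relative_expression = 0.25,
                     second_allele_productive = FALSE)
  bgb <- generate_background(cfgb)
  spb <- spike_tumor(bgb, cfgb, seed = 56)
  f <- sort(spb$frequencies, decreasing = TRUE)
  expect_equal(f[1] / f[2], 4, tolerance = 1e-9)   # 1 / attenuation
  expect_equal(sum(spb$frequencies), 1, tolerance = 1e-12)
  expect_equal(annotate_productivity(spb$tumor_clones$cdr3_nt[2]),
               "nonproductive")
  expect_equal(annotate_productivity(spb$tumor_clones$cdr3_nt[1]),
               "productive")

  expect_error(sim_config(tumor_fraction = 0, biallelic = TRUE),
               "tumor_fraction")
})

test_that("read sampling is multinomial, deterministic, and conserves reads", {
  cfg <- sim_config(seed = 8, tumor_fraction = 0.5)
  pool <- generate_clone_pool(cfg)
  tbl <- sample_reads(pool, 1484, seed = 3)
  expect_equal(sum(tbl$read_count), 1484L)
  expect_true(all(tbl$read_count >= 1L))
  expect_identical(sample_reads(pool, 1484, seed = 3), tbl)

  solo <- pool[1, ]; solo$freq <- 1
  tbl1 <- sample_reads(solo, 100, seed = 1)
  expect_equal(tbl1$read_count, 100L)

  bad <- pool; bad$freq <- bad$freq * 2
  expect_error(sample_reads(bad, 10), "sum to 1")
})

test_that("observed dominant fractions stay within 3 SE of truth", {
  cfg <- sim_config(seed = 1, tumor_fraction = 0.5)
  pool <- generate_clone_pool(cfg)
  se <- clone_proportion_se(0.5, 1484)
  inside <- 0L
  n_seeds <- 150L
  for (seed in seq_len(n_seeds)) {
    tbl <- sample_reads(pool, 1484, seed = 1000 + seed)
    obs <- max(tbl$read_count) / 1484
    if (abs(obs - 0.5) <= 3 * se) inside <- inside + 1L
  }
  expect_gte(inside / n_seeds, 0.97)
})

test_that("contaminant injection targets each filter step and records truth", {
  cfg <- sim_config(seed = 12, tumor_fraction = 0.3, n_cdr3_reads = 1000,
                    contaminant_rates = c(genomic = 0.05, cross_locus = 0.03,
                                          public = 0))
  pool <- generate_clone_pool(cfg)
  tbl <- sample_reads(pool, 1000, seed = 13)
  inj <- inject_contaminants(tbl, cfg, seed = 14)
  n_gen <- length(inj$contaminant_ids$genomic)
  expect_equal(n_gen, round(0.05 * nrow(tbl)))

  # genomic contaminants are contiguous substrings of the toy genome
  genome <- load_toy_genome()
  for (id in inj$contaminant_ids$genomic) {
    cdr3 <- inj$table$cdr3_nt[inj$table$clone_id == id]
    expect_true(grepl(cdr3, genome, fixed = TRUE))
  }
  f2 <- filter_clones_genomic(inj$table, inj$genome_hits)
  expect_setequal(f2$audit$id, inj$contaminant_ids$genomic)

  reads <- stats::setNames(inj$table$chain, inj$table$clone_id)
  f1 <- filter_reads_by_alignment(reads, inj$read_hits)
  expect_setequal(f1$audit$id, inj$contaminant_ids$cross_locus)

  # zero rates leave the table untouched
  cfg0 <- sim_config(seed = 12, tumor_fraction = 0.3, n_cdr3_reads = 1000)
  inj0 <- inject_contaminants(tbl, cfg0, seed = 14)
  expect_equal(inj0$table, tbl)
})

test_that("cohorts are reproducible and carry coherent ground truth", {
  cfgs <- list(sim_config(tumor_fraction = 0.3),
               sim_config(tumor_fraction = 0),
               sim_config(tumor_fraction = 0.6, biallelic = TRUE))
  a <- generate_cohort(cfgs, master_seed = 77)
  b <- generate_cohort(cfgs, master_seed = 77)
  expect_identical(a$truth, b$truth)
  expect_identical(a$samples$S001$clonotypes, b$samples$S001$clonotypes)

  expect_equal(a$truth$true_status,
               c("monoclonal", "polyclonal", "monoclonal"))
  expect_equal(a$truth$tumor_clone_ids[2], "")
  expect_true(all(a$truth$n_cdr3_reads >= 500 & a$truth$n_cdr3_reads <= 2400))

  one <- generate_cohort(sim_config(tumor_fraction = 0.2), n_samples = 1,
                         master_seed = 3)
  expect_length(one$samples, 1L)
})

test_that("public clones appear verbatim across the configured span", {
  cfg <- sim_config(tumor_fraction = 0.2, n_cdr3_reads = 600,
                    contaminant_rates = c(public = 0.02), public_span = 9L)
  cohort <- generate_cohort(cfg, n_samples = 12, master_seed = 21)
  tables <- lapply(cohort$samples, `[[`, "clonotypes")
  pub_cdr3 <- cohort$public_clones$cdr3_nt[1]
  carriers <- sum(vapply(tables, function(t) pub_cdr3 %in% t$cdr3_nt, TRUE))
  expect_equal(carriers, 9L)
  out <- filter_recurrent(tables)
  left <- sum(vapply(out$retained, function(t) pub_cdr3 %in% t$cdr3_nt, TRUE))
  expect_equal(left, 0L)
})

test_that("written cohorts round-trip through the IO layer", {
  dir <- file.path(tempdir(), "cohort_io")
  cohort <- generate_cohort(sim_config(tumor_fraction = 0.3,
                                       n_cdr3_reads = 700),
                            n_samples = 2, master_seed = 9, out_dir = dir)
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(nrow(sheet), 2L)
  cl <- read_clonotype_table(file.path(dir, sheet$clonotype_file[1]))
  orig <- cohort$samples$S001$clonotypes
  expect_equal(cl$cdr3_nt[order(cl$clone_id)],
               orig$cdr3_nt[order(orig$clone_id)])
})
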