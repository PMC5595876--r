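# The three-step decontamination filter.

test_that("step 1 removes off-locus matches unless rescued, boundaries strict", {
  reads <- c(r1 = "TRB", r2 = "TRB", r3 = "TRB", r4 = "TRB")
  hits <- alignment_hits(
    c("r1", "r2", "r2", "r3"),
    c("non_tcr", "non_tcr", "same_tcr_locus", "non_tcr"),
    c(0.85, 0.85, 0.95, 0.80))
  out <- filter_reads_by_alignment(reads, hits)
  expect_setequal(out$retained, c("r2", "r3", "r4"))   # r1 removed
  expect_equal(out$audit$id, "r1")
  expect_match(out$audit$reason, "non_tcr match 0.850")
  # r3 at exactly the threshold is retained (">80%" is strict)
  # r4 has no hits and is retained
})

test_that("step 1 treats other TCR loci like non-TCR targets", {
  reads <- c(r1 = "TRB")
  hits <- alignment_hits("r1", "other_tcr_locus", 0.9)
  expect_equal(filter_reads_by_alignment(reads, hits)$retained, character(0))
})

test_that("step 1 rejects hits for unknown reads and bad thresholds", {
  expect_error(filter_reads_by_alignment(
    c(r1 = "TRB"), alignment_hits("zz", "non_tcr", 0.9)), "zz")
  expect_error(filter_config(read_mismatch_threshold = 1.2), "\\(0, 1\\]")
  expect_error(filter_config(read_mismatch_threshold = 0), "\\(0, 1\\]")
})

test_that("step 2 removes near-complete genomic matches, boundary strict", {
  cl <- make_clones(c(10L, 8L, 5L))
  hits <- alignment_hits(c("c1", "c2"), "non_tcr", c(0.95, 0.90))
  out <- filter_clones_genomic(cl, hits)
  expect_setequal(out$retained$clone_id, c("c2", "c3"))  # 0.90 exactly kept
  expect_match(out$audit$reason, "0.950")
  # target class is irrelevant for the genomic CDR3 filter
  hits2 <- alignment_hits("c1", "same_tcr_locus", 0.95)
  expect_equal(filter_clones_genomic(cl, hits2)$retained$clone_id,
               c("c2", "c3"))
})

test_that("step 3 removes CDR3s recurring in more than the patient limit", {
  shared <- make_clones(5L, prefix = "shared")     # same identity everywhere
  cohort <- lapply(1:20, function(i) {
    own <- make_clones(c(7L, 3L), prefix = paste0("s", i, "_"),
                       offset = 100L + i * 10L)
    if (i <= 9) rbind(shared, own) else own
  })
  names(cohort) <- paste0("P", 1:20)
  out <- filter_recurrent(cohort)
  expect_false(any(vapply(out$retained,
                          function(cl) "shared1" %in% cl$clone_id, TRUE)))
  expect_equal(nrow(out$audit), 9L)

  # exactly 8 carriers: retained
  cohort8 <- cohort
  cohort8[["P9"]] <- cohort[["P9"]][cohort[["P9"]]$clone_id != "shared1", ]
  out8 <- filter_recurrent(cohort8)
  expect_equal(sum(vapply(out8$retained,
                          function(cl) "shared1" %in% cl$clone_id, TRUE)), 8L)

  # single-sample cohort: nothing to remove
  out1 <- filter_recurrent(cohort["P1"])
  expect_equal(nrow(out1$audit), 0L)
  expect_error(filter_recurrent(stats::setNames(cohort[1:2], c("P1", "P1"))),
               "named")
})

test_that("recurrence counting uses presence per patient, not depth", {
  deep <- make_clones(1000L, prefix = "shared")
  cohort <- c(lapply(1:8, function(i) deep),
              lapply(9:12, function(i) make_clones(c(2L, 1L),
                                                   prefix = paste0("s", i),
                                                   offset = i * 10L)))
  names(cohort) <- paste0("P", 1:12)
  out <- filter_recurrent(cohort)   # 8 carriers at huge depth: retained
  expect_true("shared1" %in% out$retained$P1$clone_id)

  # replicate collapsing: 9 samples but 8 patients
  cohort9 <- c(lapply(1:9, function(i) deep),
               lapply(10:12, function(i) make_clones(2L, prefix = "x",
                                                     offset = i * 10L)))
  names(cohort9) <- paste0("S", 1:12)
  pmap <- stats::setNames(c(paste0("pat", c(1:8, 8)), paste0("pat", 10:12)),
                          names(cohort9))
  out9 <- filter_recurrent(cohort9, patient_of = pmap)
  expect_true("shared1" %in% out9$retained$S1$clone_id)
  out9b <- filter_recurrent(cohort9)   # without the map: 9 samples, removed
  expect_false("shared1" %in% out9b$retained$S1$clone_id)
})

test_that("each filter is idempotent and output is a subset of input", {
  cfg <- sim_config(seed = 3, tumor_fraction = 0.2, n_cdr3_reads = 800,
                    contaminant_rates = c(genomic = 0.05, cross_locus = 0.05,
                                          public = 0))
  pool <- generate_clone_pool(cfg)
  tbl <- sample_reads(pool, 800, seed = 4)
  inj <- inject_contaminants(tbl, cfg, seed = 5)

  reads <- stats::setNames(inj$table$chain, inj$table$clone_id)
  f1 <- filter_reads_by_alignment(reads, inj$read_hits)
  expect_true(all(f1$retained %in% names(reads)))
  f1b <- filter_reads_by_alignment(reads[f1$retained], inj$read_hits[
    inj$read_hits$query_id %in% f1$retained, ])
  expect_setequal(f1b$retained, f1$retained)

  f2 <- filter_clones_genomic(inj$table, inj$genome_hits)
  f2b <- filter_clones_genomic(f2$retained, inj$genome_hits)
  expect_equal(f2b$retained, f2$retained)
  expect_equal(nrow(f2b$audit), 0L)
})

test_that("filters commute when their removal sets are disjoint", {
  cfg <- sim_config(seed = 9, tumor_fraction = 0.25, n_cdr3_reads = 600,
                    contaminant_rates = c(genomic = 0.04, cross_locus = 0.04,
                                          public = 0.02), public_span = 9L)
  cohort <- generate_cohort(cfg, n_samples = 10, master_seed = 99)
  tables <- lapply(cohort$samples, `[[`, "clonotypes")

  apply12 <- function(tbl, rh, gh) {
    reads <- stats::setNames(tbl$chain, tbl$clone_id)
    f1 <- filter_reads_by_alignment(reads,
                                    rh[rh$query_id %in% tbl$clone_id, ])
    t1 <- tbl[tbl$clone_id %in% f1$retained, ]
    filter_clones_genomic(t1, gh)$retained
  }
  apply21 <- function(tbl, rh, gh) {
    t2 <- filter_clones_genomic(tbl, gh)$retained
    reads <- stats::setNames(t2$chain, t2$clone_id)
    f1 <- filter_reads_by_alignment(
      reads, rh[rh$query_id %in% t2$clone_id, ])
    t2[t2$clone_id %in% f1$retained, ]
  }
  for (sid in names(tables)) {
    a <- apply12(tables[[sid]], cohort$read_hits[[sid]],
                 cohort$genome_hits[[sid]])
    b <- apply21(tables[[sid]], cohort$read_hits[[sid]],
                 cohort$genome_hits[[sid]])
    expect_setequal(a$clone_id, b$clone_id)
  }

  # step 3 before vs after steps 1-2 (public clones untouched by 1-2)
  filtered12 <- mapply(apply12, tables, cohort$read_hits,
                       cohort$genome_hits, SIMPLIFY = FALSE)
  r3_then <- filter_recurrent(filtered12)$retained
  r3_first <- filter_recurrent(tables)$retained
  both <- mapply(apply12, r3_first, cohort$read_hits, cohort$genome_hits,
                 SIMPLIFY = FALSE)
  for (sid in names(tables)) {
    expect_setequal(r3_then[[sid]]$clone_id, both[[sid]]$clone_id)
  }
})
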