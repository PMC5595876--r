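# The clonality decision engine.

test_that("productivity follows frame and stop-codon rules", {
  s42 <- paste0("TGTGCCAGCAGC", strrep("GCA", 9), "TTT")   # 42 nt, no stop
  expect_equal(nchar(s42), 42L)
  expect_equal(annotate_productivity(s42), "productive")
  expect_equal(annotate_productivity(paste0(s42, "A")), "nonproductive")
  withstop <- paste0("TGTGCC", "TAA", strrep("GCA", 9), "TTT")
  expect_equal(annotate_productivity(withstop), "nonproductive")
  expect_equal(annotate_productivity(c("TGTGCAGGG", "TGTTGAGGG", "TGTGCAG")),
               c("productive", "nonproductive", "nonproductive"))
  expect_error(annotate_productivity(""), "empty")
  expect_error(annotate_productivity("TGTNCA"), "\\{A, C, G, T\\}")
})

test_that("clone ranking is deterministic with lexicographic tie-breaks", {
  cl <- clonotype_table(
    clone_id = c("a", "b", "d"),
    chain = "TRB",
    cdr3_nt = c("TGTCCC", "TGTAAA", "TGTGGG"),
    read_count = c(5L, 9L, 9L),
    v_gene = c("TRBV1", "TRBV2", "TRBV3"),
    j_gene = "TRBJ1")
  ranked <- rank_clones(cl)
  expect_equal(ranked$clone_id, c("b", "d", "a"))   # 9-ties by CDR3
  expect_equal(rank_clones(cl[2, ])$clone_id, "b")
  expect_equal(nrow(rank_clones(cl[0, ])), 0L)
  mixed <- cl; mixed$chain <- c("TRA", "TRB", "TRB")
  expect_error(rank_clones(mixed), "single chain")
})

test_that("the 10x ratio and 10% fraction rules fire as specified", {
  run <- function(counts, extra_total = NULL, adequate = TRUE) {
    cl <- make_clones(counts)
    total <- if (is.null(extra_total)) sum(counts) else extra_total
    # pad with a tail of 1-read clones to reach the stated total
    if (!is.null(extra_total) && extra_total > sum(counts)) {
      pad <- extra_total - sum(counts)
      cl <- rbind(cl, make_clones(rep(1L, pad), prefix = "pad",
                                  offset = 1000L))
    }
    classify_chain_cdr3(rank_clones(cl), total, adequate)
  }
  # ratio 18 fires the ratio rule although the fraction (9%) does not
  call <- run(c(50L, 40L, 5L), extra_total = 1000L)
  expect_equal(call$status, "monoclonal")
  expect_equal(call$rule_fired, "ratio_rule")
  expect_equal(call$top2_to_third, 18)

  # fraction 10.5% fires although the ratio (8.75) does not
  call2 <- run(c(60L, 45L, 12L), extra_total = 1000L)
  expect_equal(call2$status, "monoclonal")
  expect_equal(call2$rule_fired, "fraction_rule")

  # flat repertoire: 100 clones x 10 reads
  call3 <- run(rep(10L, 100L))
  expect_equal(call3$status, "polyclonal")
  expect_equal(call3$top2_fraction, 0.02)
  expect_equal(call3$top2_to_third, 2)

  # adequacy gates the status but not the diagnostics
  call4 <- run(c(100L, 1L, 1L), adequate = FALSE)
  expect_equal(call4$status, "not_assessable")
  expect_equal(call4$rule_fired, "both")

  expect_error(run(c(50L, 40L, 5L), extra_total = 80L), "total")
})

test_that("boundary semantics: ratio >= 10 fires, fraction needs strict > 10%", {
  at_ratio <- classify_chain_cdr3(rank_clones(make_clones(c(30L, 20L, 5L))),
                                  55L, TRUE)
  expect_equal(at_ratio$top2_to_third, 10)
  expect_equal(at_ratio$status, "monoclonal")

  cl <- rbind(make_clones(c(6L, 4L)), make_clones(rep(3L, 30L),
                                                  prefix = "bg",
                                                  offset = 500L))
  at_frac <- classify_chain_cdr3(rank_clones(cl), 100L, TRUE)
  expect_equal(at_frac$top2_fraction, 0.10)
  expect_equal(at_frac$status, "polyclonal")   # exactly 10% does not fire
})

test_that("one- and two-clone repertoires are monoclonal (third clone absent)", {
  call <- classify_chain_cdr3(rank_clones(make_clones(40L)), 40L, TRUE)
  expect_equal(call$status, "monoclonal")
  expect_true(is.infinite(call$top2_to_third))
  call2 <- classify_chain_cdr3(rank_clones(make_clones(c(40L, 8L))), 48L, TRUE)
  expect_equal(call2$status, "monoclonal")
  empty <- classify_chain_cdr3(make_clones(5L)[0, ], 0L, TRUE)
  expect_equal(empty$status, "polyclonal")
})

test_that("biallelic flag needs second clone at >= 5x the third", {
  mk <- function(counts) {
    ranked <- rank_clones(make_clones(counts))
    classify_chain_cdr3(ranked, sum(counts), TRUE)
  }
  expect_true(detect_biallelic(mk(c(200L, 40L, 5L)))$biallelic)    # 8x
  expect_true(detect_biallelic(mk(c(200L, 25L, 5L)))$biallelic)    # exactly 5x
  expect_false(detect_biallelic(mk(c(200L, 9L, 5L)))$biallelic)    # 1.8x
  expect_true(detect_biallelic(mk(c(200L, 10L)))$biallelic)        # no third
  expect_false(detect_biallelic(mk(200L))$biallelic)               # no second
  poly <- mk(rep(5L, 30L))
  expect_error(detect_biallelic(poly), "monoclonal")
})

test_that("V-usage rule mirrors the ratio rule on FPKM values", {
  v <- function(vals) {
    names(vals) <- if (length(vals)) paste0("TRBV", seq_along(vals))
    vusage_vector("S1", "TRB", vals)
  }
  expect_equal(classify_chain_vusage(v(c(100, 30, 10)))$status, "monoclonal")
  expect_equal(classify_chain_vusage(v(c(40, 35, 30)))$status, "polyclonal")
  expect_equal(classify_chain_vusage(v(c(100, 0, 0)))$status, "monoclonal")
  expect_equal(classify_chain_vusage(v(numeric(0)))$status, "not_assessable")
})

test_that("CDR3 assessment takes precedence over V-usage", {
  ranked <- rank_clones(make_clones(c(100L, 40L, 3L)))
  cdr3 <- classify_chain_cdr3(ranked, 143L, TRUE, sample_id = "S1")
  vus <- classify_chain_vusage(
    vusage_vector("S1", "TRB", c(TRBV1 = 40, TRBV2 = 35, TRBV3 = 30)))
  out <- reconcile(cdr3, vus)
  expect_equal(out$status, "monoclonal")
  expect_equal(out$source, "cdr3")
  expect_true(out$conflict)

  # CDR3 not assessable: fall back to V-usage
  cdr3_na <- classify_chain_cdr3(ranked, 143L, FALSE, sample_id = "S1")
  vus_mono <- classify_chain_vusage(
    vusage_vector("S1", "TRB", c(TRBV1 = 100, TRBV2 = 30, TRBV3 = 1)))
  out2 <- reconcile(cdr3_na, vus_mono)
  expect_equal(out2$status, "monoclonal")
  expect_equal(out2$source, "vusage")

  # both polyclonal: no conflict
  cdr3_poly <- classify_chain_cdr3(
    rank_clones(make_clones(rep(5L, 50L))), 250L, TRUE, sample_id = "S1")
  out3 <- reconcile(cdr3_poly, vus)
  expect_equal(out3$status, "polyclonal")
  expect_false(out3$conflict)

  wrong <- vus; wrong$chain <- "TRA"
  expect_error(reconcile(cdr3, wrong), "same sample and chain")
})

test_that("case status is monoclonal when any adequate chain is", {
  mk <- function(chain, counts, adequate = TRUE) {
    classify_chain_cdr3(rank_clones(make_clones(counts, chain = chain)),
                        sum(counts), adequate)
  }
  mono_a <- mk("TRA", c(100L, 2L, 2L))
  poly_b <- mk("TRB", rep(5L, 60L))
  case <- classify_sample(list(mono_a, poly_b))
  expect_equal(case$status, "monoclonal")
  expect_equal(case$supporting_chains, "TRA")

  expect_equal(classify_sample(list(poly_b))$status, "polyclonal")
  na_a <- mk("TRA", c(100L, 2L, 2L), adequate = FALSE)
  expect_equal(classify_sample(list(na_a))$status, "not_assessable")
  expect_error(classify_sample(list()), "at least one")
})

test_that("classification is invariant under clone order permutation", {
  set.seed(99)
  for (rep in 1:20) {
    counts <- sample(1:50, sample(3:12, 1), replace = TRUE)
    cl <- make_clones(counts)
    base <- classify_chain_cdr3(rank_clones(cl), sum(counts), TRUE)
    perm <- cl[sample(nrow(cl)), ]
    again <- classify_chain_cdr3(rank_clones(perm), sum(counts), TRUE)
    expect_equal(again[c("status", "rule_fired", "c1", "c2", "c3",
                         "top2_fraction", "top2_to_third")],
                 base[c("status", "rule_fired", "c1", "c2", "c3",
                        "top2_fraction", "top2_to_third")])
  }
})

test_that("raising the top clone count never flips monoclonal to polyclonal", {
  set.seed(7)
  for (rep in 1:40) {
    counts <- sort(sample(1:30, sample(3:8, 1), replace = TRUE),
                   decreasing = TRUE)
    cl <- make_clones(counts)
    before <- classify_chain_cdr3(rank_clones(cl), sum(counts), TRUE)
    bumped <- counts; bumped[1] <- bumped[1] + sample(1:20, 1)
    cl2 <- make_clones(bumped)
    after <- classify_chain_cdr3(rank_clones(cl2), sum(bumped), TRUE)
    if (before$status == "monoclonal") {
      expect_equal(after$status, "monoclonal")
    }
  }
})
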