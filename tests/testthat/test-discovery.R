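test_that("intergenic filter removes candidates near or over genes", {
  out <- filter_intergenic_novel(tiny_assembled(), tiny_reference(),
                                 window = 2000)
  st <- setNames(out$report$status, out$report$transcript_id)
  expect_equal(unname(st["asm_close"]), "too_close_or_overlapping")
  expect_equal(unname(st["asm_olap"]), "too_close_or_overlapping")
  expect_equal(unname(st["asm_far"]), "retained")
  expect_setequal(out$retained$transcripts$transcript_id,
                  c("asm_far", "asm_short", "asm_mono", "asm_coding"))
})

test_that("window boundary is strict: gap equal to window is removed", {
  ref <- tiny_reference()  # gene_pc 1-based span 10001..13000
  # gap of exactly 2000 bp: candidate starts at 15001
  at <- function(start1) read_gtf(write_gtf_lines(c(
    gtf_line("chr1", "exon", start1, start1 + 299, "+",
             tx_attrs("a", "a", "other")),
    gtf_line("chr1", "exon", start1 + 800, start1 + 1099, "+",
             tx_attrs("a", "a", "other")))), "assembled")
  eq <- filter_intergenic_novel(at(15001), ref, window = 2000)
  expect_equal(nrow(eq$retained$transcripts), 0)
  just_past <- filter_intergenic_novel(at(15002), ref, window = 2000)
  expect_equal(nrow(just_past$retained$transcripts), 1)
})

test_that("structure filter removes short and monoexonic candidates", {
  out <- filter_structure(tiny_assembled())
  st <- setNames(out$report$status, out$report$transcript_id)
  expect_equal(unname(st["asm_short"]), "too_short")
  expect_equal(unname(st["asm_mono"]), "monoexonic")
  expect_equal(unname(st["asm_far"]), "retained")
  # exactly 200 nt is retained (>= 200 rule)
  ann200 <- read_gtf(write_gtf_lines(c(
    gtf_line("chr1", "exon", 1000, 1099, "+", tx_attrs("a", "a", "other")),
    gtf_line("chr1", "exon", 2000, 2099, "+", tx_attrs("a", "a", "other")))),
    "assembled")
  expect_equal(nrow(filter_structure(ann200)$retained$transcripts), 1)
  # 199 nt fails, and a short monoexonic transcript is labelled too_short
  ann199 <- read_gtf(write_gtf_lines(
    gtf_line("chr1", "exon", 1000, 1198, "+", tx_attrs("a", "a", "other"))),
    "assembled")
  expect_equal(filter_structure(ann199)$report$status, "too_short")
})

test_that("coding filter discards on either tool; cutoff 0.44 is inclusive", {
  ts <- tiny_assembled()
  sc <- tiny_scores()
  out <- filter_coding_potential(ts, sc)
  st <- setNames(out$report$status, out$report$transcript_id)
  expect_equal(unname(st["asm_coding"]), "coding_potential")
  expect_equal(unname(st["asm_far"]), "retained")
  expect_true(all(out$retained$transcripts$biotype == "novel_lincRNA"))
  # CPAT exactly at the cutoff counts as coding
  sc2 <- sc; sc2$cpat_probability[sc2$transcript_id == "asm_far"] <- 0.44
  st2 <- filter_coding_potential(ts, sc2)$report
  expect_equal(st2$status[st2$transcript_id == "asm_far"], "coding_potential")
  # 'both' rule keeps a transcript flagged by one tool only
  sc3 <- sc; sc3$cpat_probability[sc3$transcript_id == "asm_far"] <- 0.9
  st3 <- filter_coding_potential(ts, sc3, rule = "both")$report
  expect_equal(st3$status[st3$transcript_id == "asm_far"], "retained")
})

test_that("missing coding-potential scores error or discard as asked", {
  ts <- tiny_assembled()
  sc <- tiny_scores()[-1, ]  # drop asm_far
  expect_error(filter_coding_potential(ts, sc), "asm_far")
  out <- filter_coding_potential(ts, sc, missing = "discard")
  st <- setNames(out$report$status, out$report$transcript_id)
  expect_equal(unname(st["asm_far"]), "coding_potential")
})

test_that("duplicate ids in the coding-potential table are rejected", {
  sc <- rbind(tiny_scores(), tiny_scores()[1, ])
  p <- tempfile(fileext = ".tsv")
  write.table(sc, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_coding_potential(p), "duplicated")
})

test_that("discover_lncrnas reports the first failing filter per candidate", {
  disc <- discover_lncrnas(tiny_assembled(), tiny_reference(), tiny_scores())
  st <- setNames(disc$report$status, disc$report$transcript_id)
  expect_equal(unname(st[c("asm_far", "asm_close", "asm_olap", "asm_short",
                           "asm_mono", "asm_coding")]),
               c("retained", "too_close_or_overlapping",
                 "too_close_or_overlapping", "too_short", "monoexonic",
                 "coding_potential"))
  expect_setequal(disc$catalog$transcript_id,
                  c("tx_linc", "tx_as", "asm_far"))
  expect_equal(
    setNames(disc$catalog$class, disc$catalog$transcript_id)[
      c("tx_linc", "tx_as", "asm_far")],
    c(tx_linc = "lincRNA", tx_as = "antisense", asm_far = "novel_lincRNA"))
})

test_that("catalog construction rejects id collisions", {
  ref <- tiny_reference()
  dup <- subset_annotation(ref, "tx_linc")
  expect_error(build_catalog(ref, dup), "both reference and novel")
})
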