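test_that("genomic_interval validates and converts 0-based half-open input", {
  gr <- genomic_interval("chr1", 100, 200)
  expect_s4_class(gr, "GRanges")
  expect_equal(BiocGenerics::start(gr), 101)
  expect_equal(BiocGenerics::end(gr), 200)
  expect_equal(as.character(BiocGenerics::strand(gr)), "*")
  expect_error(genomic_interval("chr1", -1, 5), "0 <= start < end")
  expect_error(genomic_interval("chr1", 5, 5), "0 <= start < end")
  expect_error(genomic_interval("chr1", 10, 5), "0 <= start < end")
  expect_error(genomic_interval("chr1", 1, 5, "x"), "strand")
})

test_that("genomic_distance gives gap sizes with 0 for overlap/adjacency", {
  a <- genomic_interval("chr1", 100, 200)
  expect_equal(genomic_distance(a, genomic_interval("chr1", 500, 600)), 300)
  expect_equal(genomic_distance(a, genomic_interval("chr1", 200, 300)), 0)
  expect_equal(genomic_distance(a, genomic_interval("chr1", 150, 260)), 0)
  expect_equal(genomic_distance(a, genomic_interval("chr2", 100, 200)), Inf)
  # symmetric and strand-blind
  b <- genomic_interval("chr1", 1000, 1100, "-")
  expect_equal(genomic_distance(a, b), genomic_distance(b, a))
  expect_equal(genomic_distance(a, b), 800)
})

test_that("genomic_distance matches the interval-arithmetic oracle", {
  set.seed(101)
  for (i in 1:100) {
    s1 <- sample(0:5000, 1); e1 <- s1 + sample(1:500, 1)
    s2 <- sample(0:5000, 1); e2 <- s2 + sample(1:500, 1)
    want <- max(0, max(s1, s2) - min(e1, e2))
    expect_equal(
      genomic_distance(genomic_interval("chr1", s1, e1),
                       genomic_interval("chr1", s2, e2)),
      want)
  }
})

test_that("read_gtf builds a consistent AnnotationSet", {
  ref <- tiny_reference()
  expect_s3_class(ref, "AnnotationSet")
  tx <- transcript_table(ref)
  expect_setequal(tx$transcript_id, c("tx_pc", "tx_linc", "tx_as"))
  expect_equal(tx["tx_pc", "n_exons"], 2)
  expect_equal(tx["tx_pc", "mature_length"], 500 + 1000)
  # 0-based half-open span of a 1-based inclusive 10001..13000 feature
  expect_equal(tx["tx_pc", "start"], 10000)
  expect_equal(tx["tx_pc", "end"], 13000)
  expect_equal(tx["tx_pc", "biotype"], "protein_coding")
  expect_equal(tx["tx_as", "biotype"], "antisense")
  genes <- gene_ranges(ref)
  expect_setequal(names(genes), c("gene_pc", "gene_linc", "gene_as"))
})

test_that("GTF validation errors carry line numbers", {
  bad8 <- write_gtf_lines("chr1\ttest\texon\t1\t100\t.\t+\t.")
  expect_error(read_gtf(bad8, "reference"), "line 1.*9")
  rev <- write_gtf_lines(
    gtf_line("chr1", "exon", 500, 100, "+", tx_attrs("g", "t", "other")))
  expect_error(read_gtf(rev, "reference"), "line 1.*end")
  noid <- write_gtf_lines(
    gtf_line("chr1", "exon", 100, 500, "+", 'gene_id "g";'))
  expect_error(read_gtf(noid, "reference"), "line 1.*transcript_id")
  expect_error(read_gtf(tempfile(), "reference"), "not found")
})

test_that("GTF write/read round-trip preserves structure", {
  ref <- tiny_reference()
  path <- tempfile(fileext = ".gtf")
  write_gtf(ref, path)
  back <- read_gtf(path, "reference")
  cols <- c("transcript_id", "gene_id", "chrom", "strand", "biotype",
            "n_exons", "mature_length", "start", "end")
  ord <- order(ref$transcripts$transcript_id)
  expect_equal(back$transcripts[ord, cols], ref$transcripts[ord, cols])
})

test_that("subset_annotation restricts transcripts and genes", {
  ref <- tiny_reference()
  sub <- subset_annotation(ref, "tx_pc")
  expect_equal(sub$transcripts$transcript_id, "tx_pc")
  expect_equal(names(gene_ranges(sub)), "gene_pc")
  expect_error(subset_annotation(ref, "nope"), "unknown transcript")
})

test_that("relation_to_reference classifies with sense precedence", {
  ref <- tiny_reference()
  # gene_pc is chr1:10001-13000 (+); gene_as overlaps it on '-'
  x <- c(genomic_interval("chr1", 11000, 11200, "+"),  # sense overlap
         genomic_interval("chr1", 11000, 11200, "-"),  # antisense of pc, but
                                                       # sense of gene_as
         genomic_interval("chr1", 12500, 12700, "-"),  # antisense only
         genomic_interval("chr1", 900000, 900100, "+")) # intergenic
  rel <- relation_to_reference(x, ref)
  expect_equal(rel, c("sense_overlap", "sense_overlap", "antisense_overlap",
                      "intergenic"))
})

test_that("biotype synonyms normalize to the internal vocabulary", {
  p <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 1, 300, "+", tx_attrs("g1", "t1", "lncRNA")),
    gtf_line("chr1", "exon", 1000, 1300, "+",
             tx_attrs("g2", "t2", "antisense_RNA")),
    gtf_line("chr1", "exon", 2000, 2300, "+",
             tx_attrs("g3", "t3", "misc_RNA"))))
  tx <- transcript_table(read_gtf(p, "reference"))
  expect_equal(tx["t1", "biotype"], "lincRNA")
  expect_equal(tx["t2", "biotype"], "antisense")
  expect_equal(tx["t3", "biotype"], "other")
})

test_that("transcripts with exons on multiple chromosomes are rejected", {
  p <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 1, 100, "+", tx_attrs("g", "t", "other")),
    gtf_line("chr2", "exon", 200, 300, "+", tx_attrs("g", "t", "other"))))
  expect_error(read_gtf(p, "assembled"), "multiple chromosomes")
  p2 <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 1, 100, "+", tx_attrs("g", "t", "other")),
    gtf_line("chr1", "exon", 50, 300, "+", tx_attrs("g", "t", "other"))))
  expect_error(read_gtf(p2, "assembled"), "overlapping exons")
})
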