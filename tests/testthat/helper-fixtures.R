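# shared fixtures: tiny hand-written annotations and expression tables

gtf_line <- function(chrom, feature, start, end, strand, attrs) {
  paste(chrom, "test", feature, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

tx_attrs <- function(gene, tx, biotype) {
  sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
          gene, tx, biotype)
}

write_gtf_lines <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

# reference: one protein-coding gene (chr1:10001-13000, +, 2 exons),
# one lincRNA (chr1:50001-51000, +, 2 exons),
# one antisense lncRNA inside the gene on the - strand
tiny_reference <- function() {
  read_gtf(write_gtf_lines(c(
    gtf_line("chr1", "exon", 10001, 10500, "+",
             tx_attrs("gene_pc", "tx_pc", "protein_coding")),
    gtf_line("chr1", "exon", 12001, 13000, "+",
             tx_attrs("gene_pc", "tx_pc", "protein_coding")),
    gtf_line("chr1", "exon", 50001, 50300, "+",
             tx_attrs("gene_linc", "tx_linc", "lincRNA")),
    gtf_line("chr1", "exon", 50601, 51000, "+",
             tx_attrs("gene_linc", "tx_linc", "lincRNA")),
    gtf_line("chr1", "exon", 10101, 10400, "-",
             tx_attrs("gene_as", "tx_as", "antisense")),
    gtf_line("chr1", "exon", 11001, 11400, "-",
             tx_attrs("gene_as", "tx_as", "antisense")))), "reference")
}

# candidates relative to tiny_reference(): gene_pc spans 10001-13000 (1-based)
#   asm_far:    2 exons, >= 2 kb from everything, length 600   -> retained
#   asm_close:  2 exons, gap 1500 bp from gene_pc              -> too close
#   asm_olap:   2 exons, overlaps gene_pc by 101 bp            -> overlapping
#   asm_short:  2 exons, mature length 170 nt                  -> too short
#   asm_mono:   1 exon                                         -> monoexonic
#   asm_coding: 2 exons, valid placement                       -> coding tools
tiny_assembled <- function() {
  read_gtf(write_gtf_lines(c(
    gtf_line("chr1", "exon", 100001, 100300, "+",
             tx_attrs("asm_far", "asm_far", "other")),
    gtf_line("chr1", "exon", 100801, 101100, "+",
             tx_attrs("asm_far", "asm_far", "other")),
    gtf_line("chr1", "exon", 14501, 14800, "+",
             tx_attrs("asm_close", "asm_close", "other")),
    gtf_line("chr1", "exon", 15201, 15500, "+",
             tx_attrs("asm_close", "asm_close", "other")),
    gtf_line("chr1", "exon", 12900, 13200, "+",
             tx_attrs("asm_olap", "asm_olap", "other")),
    gtf_line("chr1", "exon", 13601, 13900, "+",
             tx_attrs("asm_olap", "asm_olap", "other")),
    gtf_line("chr1", "exon", 200001, 200080, "+",
             tx_attrs("asm_short", "asm_short", "other")),
    gtf_line("chr1", "exon", 200581, 200670, "+",
             tx_attrs("asm_short", "asm_short", "other")),
    gtf_line("chr1", "exon", 300001, 301000, "+",
             tx_attrs("asm_mono", "asm_mono", "other")),
    gtf_line("chr1", "exon", 400001, 400300, "+",
             tx_attrs("asm_coding", "asm_coding", "other")),
    gtf_line("chr1", "exon", 400801, 401100, "+",
             tx_attrs("asm_coding", "asm_coding", "other")))), "assembled")
}

tiny_scores <- function() {
  data.frame(
    transcript_id = c("asm_far", "asm_close", "asm_olap", "asm_short",
                      "asm_mono", "asm_coding"),
    cpc_label = c("noncoding", "noncoding", "noncoding", "noncoding",
                  "noncoding", "coding"),
    cpat_probability = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.9),
    stringsAsFactors = FALSE)
}

# 4 groups x 2 replicates design
tiny_design <- function(reps = 2) {
  groups <- c("ipRGC_normal", "ipRGC_injured", "ooDSGC_normal",
              "ooDSGC_injured")
  data.frame(
    sample_id = paste0(rep(groups, each = reps), "_r", seq_len(reps)),
    rgc_type = rep(c("ipRGC", "ipRGC", "ooDSGC", "ooDSGC"), each = reps),
    condition = rep(c("normal", "injured", "normal", "injured"), each = reps),
    replicate = rep(seq_len(reps), 4),
    group = rep(groups, each = reps),
    stringsAsFactors = FALSE)
}

# expression matrix with exact per-group values: rows of `values` are
# transcripts, columns the 4 groups (vectors are read row by row); every
# replicate gets the group value
tiny_matrix <- function(values, design = tiny_design(), ids = NULL) {
  groups <- unique(design$group)
  if (!is.matrix(values))
    values <- matrix(values, ncol = length(groups), byrow = TRUE)
  m <- values[, match(design$group, groups), drop = FALSE]
  colnames(m) <- design$sample_id
  rownames(m) <- ids %||% paste0("t", seq_len(nrow(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate an expression under a fixed RNG seed
withr_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}
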