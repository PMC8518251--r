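# a small configuration keeps the generator tests fast
small_cfg <- function(seed = 3, ...) {
  simulation_config(
    seed = seed, n_protein_coding = 40, n_ref_lincrna = 10,
    n_ref_antisense = 4,
    novel_counts = c(valid = 4, too_close = 3, overlapping = 3, short = 3,
                     monoexonic = 3, coding = 3),
    n_cis_pairs = 4, n_type_specific = 4, n_exclusive = 4,
    de_extra_lnc = c(1, 2, 2), de_extra_mrna = c(2, 2, 2),
    gba_block_size = 4, ...)
}

test_that("annotation placement matches the planted categories", {
  sim <- simulate_annotation(small_cfg())
  ref <- sim$reference; asm <- sim$assembled
  expect_equal(nrow(asm$transcripts), 19)
  cat_of <- setNames(sim$truth$novel_category$category,
                     sim$truth$novel_category$transcript_id)
  spans <- asm$tx_spans
  genes <- ref$genes[ref$genes$biotype == "protein_coding"]
  d <- sapply(seq_along(spans), function(i)
    min(genomic_distance(spans[i], genes)))
  for (i in seq_along(spans)) {
    id <- names(spans)[i]
    tx <- asm$transcripts[id, ]
    switch(cat_of[[id]],
      valid = , coding = expect_gt(d[i], 2000),
      too_close = expect_true(d[i] >= 1 && d[i] <= 1999),
      overlapping = expect_equal(d[i], 0),
      short = expect_lt(tx$mature_length, 200),
      monoexonic = expect_equal(tx$n_exons, 1))
  }
  # structural validity of short/monoexonic candidates aside from their flaw
  expect_true(all(asm$transcripts$mature_length > 0))
  # antisense reference lncRNAs overlap their host gene on the other strand
  as_tx <- ref$transcripts[ref$transcripts$biotype == "antisense", ]
  hosts <- ref$genes[sprintf("gene_pc_%03d", seq_len(nrow(as_tx)))]
  expect_true(all(genomic_distance(ref$tx_spans[as_tx$transcript_id],
                                   hosts) == 0))
  expect_true(all(as_tx$strand != as.character(BiocGenerics::strand(hosts))))
})

test_that("infeasible placement errors with advice", {
  expect_error(simulate_annotation(small_cfg(chrom_length = 1e6)),
               "chrom_length")
  expect_error(
    simulate_annotation(simulation_config(n_protein_coding = 10)),
    "not enough loci")
})

test_that("the full bundle is byte-identical at a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_study(small_cfg(seed = 5), d1)
  simulate_study(small_cfg(seed = 5), d2)
  simulate_study(small_cfg(seed = 6), d3)
  files <- sort(list.files(d1))
  expect_setequal(list.files(d2), files)
  for (f in files) {
    a <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(a, b)
  }
  expect_false(identical(
    readBin(file.path(d1, "counts.tsv"), "raw", 5000),
    readBin(file.path(d3, "counts.tsv"), "raw", 5000)))
})

test_that("planted type-specific transcripts concentrate psi in one group", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, sim)
  prof <- expr$profiles
  groups <- c("ipRGC_normal", "ipRGC_injured", "ooDSGC_normal",
              "ooDSGC_injured")
  ts <- expr$truth$type_specific
  expect_equal(nrow(ts), 4)
  fel <- prof[ts$id, groups] / rowSums(prof[ts$id, groups])
  target <- fel[cbind(seq_len(nrow(ts)), match(ts$group, groups))]
  # psi = 0.8 up to the multiplicative group noise
  expect_true(all(target > 0.5))
  # exclusive transcripts are zero in the other type's groups
  ex <- expr$truth$exclusive
  for (i in seq_len(nrow(ex))) {
    other <- grep(ex$rgc_type[i], groups, value = TRUE, invert = TRUE)
    expect_equal(unname(prof[ex$id[i], other]), c(0, 0))
  }
})

test_that("planted fold changes appear in the group-mean counts", {
  cfg <- small_cfg(seed = 13)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, sim)
  gm <- group_means(expr$counts, expr$design)
  comp <- standard_comparisons()
  names(comp) <- vapply(comp, `[[`, character(1), "name")
  de <- expr$truth$de
  ratio <- vapply(seq_len(nrow(de)), function(i) {
    cc <- comp[[de$comparison[i]]]
    r <- (gm[de$id[i], cc$group_a] + 0.5) / (gm[de$id[i], cc$group_b] + 0.5)
    if (de$lfc[i] < 0) 1 / r else r
  }, numeric(1))
  # planted log2FC = 3 -> ratio in [4, 16] for >= 90% at default dispersion
  expect_gte(mean(ratio >= 4 & ratio <= 16), 0.9)
})

test_that("planted correlation structure is present in the profiles", {
  cfg <- small_cfg(seed = 21)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, sim)
  prof <- expr$profiles
  cp <- expr$truth$cis_pairs
  r_pairs <- vapply(seq_len(nrow(cp)), function(i)
    cor(prof[cp$lncrna_id[i], ], prof[cp$mrna_id[i], ]), numeric(1))
  expect_true(all(abs(r_pairs) > 0.5))
  gba <- expr$truth$gba
  for (b in unique(gba$block)) {
    lnc <- gba$id[gba$block == b & gba$role == "lncRNA"]
    mem <- gba$id[gba$block == b & gba$role == "mRNA"]
    r <- cor(prof[lnc, ], t(prof[mem, , drop = FALSE]))
    sgn <- gba$sign[gba$block == b & gba$role == "mRNA"][1]
    expect_true(all(sign(r) == sgn))
  }
})

test_that("coding-potential fixtures flag exactly the planted coding set", {
  cfg <- small_cfg(seed = 2)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, sim)
  side <- simulate_side_tables(cfg, expr, sim)
  cp <- side$coding_potential
  cat_of <- setNames(sim$truth$novel_category$category,
                     sim$truth$novel_category$transcript_id)
  flagged <- cp$cpc_label == "coding" | cp$cpat_probability >= 0.44
  expect_equal(sort(cp$transcript_id[flagged]),
               sort(names(cat_of)[cat_of == "coding"]))
  # each block's planted term annotates all of its mRNA genes
  gba <- side$truth$gba
  gene_of <- setNames(sim$reference$transcripts$gene_id,
                      sim$reference$transcripts$transcript_id)
  for (b in seq_along(side$truth$enriched_terms$term_id)) {
    tid <- side$truth$enriched_terms$term_id[b]
    block_genes <- gene_of[gba$id[gba$block == b & gba$role == "mRNA"]]
    expect_true(all(block_genes %in%
                      side$terms$gene_id[side$terms$term_id == tid]))
  }
})

test_that("module-level profile generators hit their correlation targets", {
  set.seed(31)
  pr <- simulate_correlated_profiles(50, target_r = 0.9)
  r <- vapply(1:50, function(i) cor(pr$lnc[i, ], pr$mrna[i, ]), numeric(1))
  expect_gt(median(r), 0.8)
  r0 <- vapply(1:50, function(i) cor(pr$lnc[i, ], pr$unrelated[i, ]),
               numeric(1))
  expect_lt(median(abs(r0)), 0.5)
  gb <- simulate_gba_profiles()
  expect_equal(dim(gb$lnc), c(3, 16))
  expect_equal(dim(gb$mrna), c(30, 16))
})

test_that("null configuration plants nothing", {
  cfg <- small_cfg(seed = 17, plant_effects = FALSE)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, sim)
  expect_equal(nrow(expr$truth$de), 0)
  expect_equal(nrow(expr$truth$exclusive), 0)
  expect_equal(nrow(expr$truth$type_specific), 0)
  expect_equal(nrow(expr$truth$cis_pairs), 0)
})
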