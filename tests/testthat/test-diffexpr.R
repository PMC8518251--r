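test_that("naive_de gives p = 1 for identical groups and small p for a planted shift", {
  design <- tiny_design(reps = 3)
  groups <- unique(design$group)
  # identical multisets across the compared groups
  same <- matrix(rep(c(10, 20, 30), 4), nrow = 1)
  colnames(same) <- design$sample_id
  rownames(same) <- "t1"
  # make both ooDSGC groups carry the same replicate values
  same[1, design$group == "ooDSGC_injured"] <- c(10, 20, 30)
  same[1, design$group == "ooDSGC_normal"] <- c(10, 20, 30)
  cc <- standard_comparisons()[[2]]
  de_same <- naive_de(same, design, cc)
  expect_equal(de_same$p_value, 1)
  expect_equal(de_same$log2_fold_change, 0)

  # planted 8-fold mean shift at low dispersion, 3 vs 3 replicates
  set.seed(42)
  shifted <- same
  shifted[1, design$group == "ooDSGC_injured"] <- 800 * exp(rnorm(3, 0, 0.05))
  shifted[1, design$group == "ooDSGC_normal"] <- 100 * exp(rnorm(3, 0, 0.05))
  de_shift <- naive_de(shifted, design, cc)
  expect_lt(de_shift$adj_p_value, 0.05)
  expect_equal(de_shift$direction, "up")
})

test_that("naive_de separates constant groups with p near 0", {
  design <- tiny_design(reps = 3)
  m <- matrix(1, 1, nrow(design),
              dimnames = list("t1", design$sample_id))
  m[1, design$group == "ooDSGC_injured"] <- 100
  de <- naive_de(m, design, standard_comparisons()[[2]])
  expect_lt(de$p_value, 0.001)
})

test_that("naive_de requires two replicates per compared group", {
  design <- tiny_design(reps = 2)[-7, ]  # ooDSGC_injured down to 1 rep
  m <- matrix(1, 1, nrow(design), dimnames = list("t1", design$sample_id))
  expect_error(naive_de(m, design, standard_comparisons()[[2]]),
               ">= 2 replicates")
})

test_that("BH adjustment matches the step-up oracle on a known example", {
  # frozen worked example: p = (0.01, 0.02, 0.03, 0.04) -> all adjusted to 0.04
  design <- tiny_design(reps = 3)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  # naive_de applies BH across all tested transcripts
  set.seed(7)
  m <- matrix(rlnorm(4 * nrow(design), log(100), 0.3), 4,
              dimnames = list(paste0("t", 1:4), design$sample_id))
  de <- naive_de(m, design, standard_comparisons()[[1]])
  expect_equal(de$adj_p_value, p.adjust(de$p_value, "BH"))
})

test_that("DE tables load with NA padj retained and flagged", {
  tab <- data.frame(transcript_id = c("a", "b", "c"),
                    log2FoldChange = c(2, -3, 0.5),
                    pvalue = c(0.001, 0.002, NA),
                    padj = c(0.01, NA, NA))
  p <- tempfile(fileext = ".tsv")
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- load_de_table(p, standard_comparisons()[[1]])
  expect_equal(rec$adj_p_value, c(0.01, 1, 1))
  expect_equal(rec$flagged_na_padj, c(FALSE, TRUE, TRUE))
  expect_equal(rec$direction, c("up", "down", "up"))
  expect_equal(nrow(significant(rec)), 1)
  # strictly below alpha
  rec$adj_p_value[1] <- 0.05
  expect_equal(nrow(significant(rec, 0.05)), 0)
  bad <- tab[, -2]
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_de_table(p, "c1"), "log2FoldChange")
})

test_that("heat-map Z-scores match the frozen oracle (sample sd)", {
  design <- tiny_design()
  m <- tiny_matrix(c(2, 4, 6, 8), design)
  rec <- data.frame(transcript_id = "t1", comparison = "c",
                    log2_fold_change = 1, p_value = 0.001,
                    adj_p_value = 0.001, direction = "up",
                    flagged_na_padj = FALSE, stringsAsFactors = FALSE)
  v <- export_views(rec, m, design)
  expect_equal(unname(v$heatmap["t1", ]),
               c(-1.161895, -0.387298, 0.387298, 1.161895),
               tolerance = 1e-6)
  expect_true(v$volcano$significant)
})

test_that("constant significant rows are zeroed and flagged", {
  design <- tiny_design()
  m <- tiny_matrix(c(5, 5, 5, 5), design)
  rec <- data.frame(transcript_id = "t1", comparison = "c",
                    log2_fold_change = 0, p_value = 0.001,
                    adj_p_value = 0.001, direction = "up",
                    flagged_na_padj = FALSE, stringsAsFactors = FALSE)
  v <- export_views(rec, m, design)
  expect_equal(unname(v$heatmap["t1", ]), rep(0, 4))
  expect_equal(v$constant_rows, "t1")
  # no significant rows -> warning and empty heat map
  rec$adj_p_value <- 0.9
  expect_warning(v2 <- export_views(rec, m, design), "no significant")
  expect_equal(dim(v2$heatmap), c(0, 0))
})

test_that("volcano clamps zero adjusted p-values", {
  design <- tiny_design()
  m <- tiny_matrix(c(2, 4, 6, 8), design)
  rec <- data.frame(transcript_id = "t1", comparison = "c",
                    log2_fold_change = 1, p_value = 0, adj_p_value = 0,
                    direction = "up", flagged_na_padj = FALSE,
                    stringsAsFactors = FALSE)
  v <- export_views(rec, m, design)
  expect_true(is.finite(v$volcano$neg_log10_adj_p))
})
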