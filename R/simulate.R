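# Seeded generator of annotation, expression, coding-potential and
# term-annotation fixtures with recorded ground truth. The layout mirrors the
# statistical structure the analysis assumes: four in-study sample groups
# (two RGC types x two conditions) with negative-binomial replicate counts,
# external cell-type profile columns, planted type-specific and
# injury-responsive transcripts, planted lncRNA-mRNA neighbour pairs with a
# target correlation, sign-coherent co-expression blocks, and novel-transcript
# candidates planted to fail each discovery filter.

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator with their default study
#' conditions. Genes are laid out one per 250 kb locus slot; each slot can
#' additionally host an antisense lncRNA (inside the gene body, opposite
#' strand), a lincRNA and one novel candidate at controlled distances.
#'
#' @param seed Integer seed; the full output bundle is a deterministic
#'   function of the configuration.
#' @param n_chromosomes,chrom_length,slot_bp Genome layout (bp).
#' @param n_protein_coding Number of protein-coding genes (one per slot).
#' @param n_ref_lincrna,n_ref_antisense Reference lncRNA counts.
#' @param novel_counts Named vector of novel-candidate counts per planted
#'   category: `valid`, `too_close`, `overlapping`, `short`, `monoexonic`,
#'   `coding`.
#' @param n_external_groups Number of external cell-type profile columns
#'   appended to the four in-study groups.
#' @param replicates Replicates per in-study group.
#' @param nb_dispersion Negative-binomial dispersion of replicate counts.
#' @param depth_factor Expected fragments per (TPM x kb) unit, setting
#'   sequencing depth.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance.
#' @param group_noise_sd Log-scale sd of in-study group-to-group biological
#'   noise.
#' @param profile_cv Coefficient of variation of the profile modulation
#'   shared by the latent-factor construction.
#' @param psi Specificity concentration: fraction of a planted type-specific
#'   transcript's total in-study expression assigned to its target group.
#' @param n_type_specific,n_exclusive Planted type-specific (psi
#'   reallocation) and type-exclusive (zero in the other RGC type)
#'   transcripts, split evenly between lncRNAs and mRNAs.
#' @param planted_lfc Planted log2 fold change for injury/type-contrast DE
#'   transcripts.
#' @param de_extra_lnc,de_extra_mrna Additional DE transcripts planted in
#'   comparisons 1, 3 and 4 (the ooDSGC injury comparison gets the cis pairs
#'   and co-expression blocks), split as lncRNAs/mRNAs.
#' @param n_cis_pairs,cis_target_r Planted lncRNA-mRNA neighbour pairs and
#'   their target Pearson correlation.
#' @param gba_blocks,gba_block_size,gba_target_r,gba_block_signs Co-expression
#'   block design: number of blocks, mRNAs per block, target correlation of
#'   members with the block lncRNA, and the correlation sign per block.
#' @param plant_effects When `FALSE`, no effects are planted (no exclusive,
#'   type-specific or DE transcripts, no correlated pairs or blocks),
#'   yielding effect-free null data for calibration.
#' @param n_background_terms,term_bg_rate,term_out_rate Term-annotation table:
#'   background terms annotate each gene independently at `term_bg_rate`;
#'   each block's planted term annotates all block genes and outside genes at
#'   `term_out_rate`.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 2,
                              chrom_length = 13e6,
                              slot_bp = 250000,
                              n_protein_coding = 100,
                              n_ref_lincrna = 25,
                              n_ref_antisense = 15,
                              novel_counts = c(valid = 12, too_close = 8,
                                               overlapping = 8, short = 8,
                                               monoexonic = 8, coding = 8),
                              n_external_groups = 12,
                              replicates = 2,
                              nb_dispersion = 0.05,
                              depth_factor = 30,
                              baseline_meanlog = log(100),
                              baseline_sdlog = 0.8,
                              group_noise_sd = 0.15,
                              profile_cv = 0.4,
                              psi = 0.8,
                              n_type_specific = 16,
                              n_exclusive = 16,
                              planted_lfc = 3,
                              de_extra_lnc = c(2, 5, 5),
                              de_extra_mrna = c(3, 5, 5),
                              n_cis_pairs = 16,
                              cis_target_r = 0.9,
                              gba_blocks = 3,
                              gba_block_size = 10,
                              gba_target_r = 0.95,
                              gba_block_signs = c(1, -1, 1),
                              n_background_terms = 30,
                              term_bg_rate = 0.1,
                              term_out_rate = 0.05,
                              plant_effects = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$psi > 0.25, cfg$psi <= 1,
            cfg$cis_target_r > 0, cfg$cis_target_r < 1,
            cfg$gba_target_r > 0, cfg$gba_target_r < 1,
            all(cfg$novel_counts >= 0), cfg$replicates >= 2,
            length(cfg$gba_block_signs) == cfg$gba_blocks,
            length(cfg$de_extra_lnc) == 3, length(cfg$de_extra_mrna) == 3)
  class(cfg) <- "simulation_config"
  cfg
}

# multiplicative profile modulation shared by the latent-factor construction;
# truncation keeps values positive (rare at the default cv)
modulate <- function(m, z, cv) m * pmax(0.05, 1 + cv * z)

# latent-factor pair: two standard-normal vectors with expected correlation r
factor_pair <- function(f, r) {
  lam <- sqrt(r)
  list(a = lam * f + sqrt(1 - r) * stats::rnorm(length(f)),
       b = lam * f + sqrt(1 - r) * stats::rnorm(length(f)))
}

in_study_groups <- c("ipRGC_normal", "ipRGC_injured",
                     "ooDSGC_normal", "ooDSGC_injured")

# ---- annotation -------------------------------------------------------------

# one multi-exon transcript as an exon table (1-based inclusive coords)
make_tx <- function(transcript_id, gene_id, chrom, strand, start1,
                    exon_lens, intron_lens, biotype) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1L)
  starts <- start1 + cumsum(c(0, exon_lens[-length(exon_lens)] +
                                intron_lens))
  data.frame(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
             strand = strand, start = starts, end = starts + exon_lens - 1L,
             biotype = biotype, stringsAsFactors = FALSE)
}

random_tx <- function(id, gid, chrom, strand, start1, n_exons, total_len,
                      biotype, max_intron = 3000) {
  cuts <- if (n_exons > 1L) sort(sample(seq_len(total_len - 1L),
                                        n_exons - 1L)) else integer(0)
  exon_lens <- diff(c(0L, cuts, total_len))
  exon_lens <- pmax(exon_lens, 1L)
  introns <- if (n_exons > 1L) sample(500:max_intron, n_exons - 1L,
                                      replace = TRUE) else integer(0)
  make_tx(id, gid, chrom, strand, start1, exon_lens, introns, biotype)
}

#' Generate reference and assembled annotations with planted truth
#'
#' Protein-coding genes are placed one per locus slot; antisense lncRNAs
#' overlap chosen genes on the opposite strand; lincRNAs sit in intergenic
#' space; novel candidates are planted per category: `valid` (farther than
#' the exclusion window from every gene), `too_close` (1-1999 bp gap),
#' `overlapping` (>= 1 bp overlap), `short` (< 200 nt), `monoexonic`, and
#' `coding` (valid placement, flagged coding in the side tables).
#'
#' @param cfg A [simulation_config()].
#' @return List with `reference` and `assembled` (`AnnotationSet`s) and
#'   `truth` (planted labels).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(child_seed(cfg$seed, 1L))
  n_slots <- cfg$n_protein_coding
  slots_per_chrom <- ceiling(n_slots / cfg$n_chromosomes)
  if (slots_per_chrom * cfg$slot_bp + 2 * cfg$slot_bp > cfg$chrom_length)
    abort(paste("cannot place %d loci per chromosome of %g bp;",
                "increase chrom_length"), slots_per_chrom, cfg$chrom_length)
  n_novel <- sum(cfg$novel_counts)
  n_lnc_slots <- cfg$n_ref_antisense + cfg$n_ref_lincrna
  if (n_lnc_slots + n_novel > n_slots)
    abort("not enough loci: need %d gene slots, have %d",
          n_lnc_slots + n_novel, n_slots)

  slot_chrom <- paste0("chr", ceiling(seq_len(n_slots) / slots_per_chrom))
  slot_off <- ((seq_len(n_slots) - 1L) %% slots_per_chrom) * cfg$slot_bp

  ref <- list(); asm <- list()
  gene_end1 <- numeric(n_slots)

  # protein-coding genes
  for (i in seq_len(n_slots)) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(4:10, 1)
    exon_lens <- sample(120:300, n_ex, replace = TRUE)
    introns <- sample(500:3000, n_ex - 1, replace = TRUE)
    tx <- make_tx(sprintf("tx_pc_%03d", i), sprintf("gene_pc_%03d", i),
                  slot_chrom[i], strand, slot_off[i] + 10001L,
                  exon_lens, introns, "protein_coding")
    gene_end1[i] <- max(tx$end)
    ref[[length(ref) + 1L]] <- tx
  }

  # antisense lncRNAs inside the first genes, opposite strand
  for (j in seq_len(cfg$n_ref_antisense)) {
    host <- j
    strand <- if (ref[[host]]$strand[1] == "+") "-" else "+"
    ref[[length(ref) + 1L]] <- make_tx(
      sprintf("tx_as_%02d", j), sprintf("gene_as_%02d", j),
      slot_chrom[host], strand, slot_off[host] + 10501L,
      sample(300:800, 2, replace = TRUE), sample(400:1200, 1), "antisense")
  }

  # lincRNAs (the first n_cis_pairs of them are the planted cis partners of
  # their slot's gene)
  lnc_slot0 <- cfg$n_ref_antisense
  for (j in seq_len(cfg$n_ref_lincrna)) {
    s <- lnc_slot0 + j
    ref[[length(ref) + 1L]] <- random_tx(
      sprintf("tx_linc_%02d", j), sprintf("gene_linc_%02d", j),
      slot_chrom[s], sample(c("+", "-"), 1), slot_off[s] + 90001L,
      sample(2:3, 1), sample(600:2500, 1), "lincRNA")
  }

  # novel candidates, one per remaining slot
  categories <- rep(names(cfg$novel_counts), cfg$novel_counts)
  novel_slot0 <- n_lnc_slots
  novel_cat <- character(0)
  for (k in seq_along(categories)) {
    s <- novel_slot0 + k
    cat_k <- categories[k]
    id <- sprintf("asm_%03d", k)
    strand <- sample(c("+", "-"), 1)
    tx <- switch(
      cat_k,
      valid = ,
      coding = random_tx(id, id, slot_chrom[s], strand,
                         slot_off[s] + 190001L, sample(2:3, 1),
                         sample(400:2000, 1), "other"),
      too_close = make_tx(id, id, slot_chrom[s], strand,
                          gene_end1[s] + sample(1:1999, 1) + 1L,
                          sample(250:400, 2, replace = TRUE),
                          sample(500:1500, 1), "other"),
      overlapping = make_tx(id, id, slot_chrom[s], strand,
                            gene_end1[s] - 100L,
                            c(400L, sample(250:400, 1)),
                            sample(500:1500, 1), "other"),
      short = make_tx(id, id, slot_chrom[s], strand, slot_off[s] + 190001L,
                      c(80L, 90L), sample(500:1500, 1), "other"),
      monoexonic = make_tx(id, id, slot_chrom[s], strand,
                           slot_off[s] + 190001L, 1000L, integer(0), "other"))
    novel_cat[id] <- cat_k
    asm[[length(asm) + 1L]] <- tx
  }

  reference <- build_annotation_set(do.call(rbind, ref), "reference")
  assembled <- build_annotation_set(do.call(rbind, asm), "assembled")

  truth <- list(
    novel_category = data.frame(transcript_id = names(novel_cat),
                                category = unname(novel_cat),
                                stringsAsFactors = FALSE),
    expected_novel = names(novel_cat)[novel_cat == "valid"],
    cis_pairs = data.frame(
      lncrna_id = sprintf("tx_linc_%02d", seq_len(cfg$n_cis_pairs)),
      mrna_id = sprintf("tx_pc_%03d", lnc_slot0 + seq_len(cfg$n_cis_pairs)),
      target_r = cfg$cis_target_r, stringsAsFactors = FALSE))
  truth$expected_catalog <- c(
    sprintf("tx_as_%02d", seq_len(cfg$n_ref_antisense)),
    sprintf("tx_linc_%02d", seq_len(cfg$n_ref_lincrna)),
    truth$expected_novel)
  list(reference = reference, assembled = assembled, truth = truth)
}

# ---- expression -------------------------------------------------------------

# disjoint planting pools over catalog lncRNAs and mRNAs
assign_plantings <- function(cfg, truth) {
  if (!cfg$plant_effects)
    return(list(
      exclusive = data.frame(id = character(0), rgc_type = character(0),
                             stringsAsFactors = FALSE),
      type_specific = data.frame(id = character(0), group = character(0),
                                 stringsAsFactors = FALSE),
      de = data.frame(id = character(0), comparison = character(0),
                      lfc = numeric(0), stringsAsFactors = FALSE),
      gba = data.frame(id = character(0), role = character(0),
                       block = integer(0), sign = numeric(0),
                       stringsAsFactors = FALSE)))
  n_gba_mrna <- cfg$gba_blocks * cfg$gba_block_size
  lnc_pool <- setdiff(
    truth$expected_catalog,
    c(truth$cis_pairs$lncrna_id,
      sprintf("tx_linc_%02d", cfg$n_cis_pairs + seq_len(cfg$gba_blocks))))
  gba_lnc <- sprintf("tx_linc_%02d", cfg$n_cis_pairs + seq_len(cfg$gba_blocks))
  novel_slot0 <- cfg$n_ref_antisense + cfg$n_ref_lincrna
  gba_mrna <- sprintf("tx_pc_%03d", novel_slot0 + seq_len(n_gba_mrna))
  mrna_pool <- setdiff(sprintf("tx_pc_%03d", seq_len(cfg$n_protein_coding)),
                       c(truth$cis_pairs$mrna_id, gba_mrna))

  take <- function(pool, n, used) {
    avail <- setdiff(pool, used)
    if (length(avail) < n) abort("planting pools exhausted; enlarge the genome")
    avail[seq_len(n)]
  }
  used_l <- character(0); used_m <- character(0)
  half <- function(n) c(floor(n / 2), ceiling(n / 2))

  ex_l <- take(lnc_pool, half(cfg$n_exclusive)[1], used_l)
  used_l <- c(used_l, ex_l)
  ex_m <- take(mrna_pool, half(cfg$n_exclusive)[2], used_m)
  used_m <- c(used_m, ex_m)
  exclusive <- data.frame(
    id = c(ex_l, ex_m),
    rgc_type = rep_len(c("ipRGC", "ooDSGC"), length(c(ex_l, ex_m))),
    stringsAsFactors = FALSE)

  sp_l <- take(lnc_pool, half(cfg$n_type_specific)[1], used_l)
  used_l <- c(used_l, sp_l)
  sp_m <- take(mrna_pool, half(cfg$n_type_specific)[2], used_m)
  used_m <- c(used_m, sp_m)
  type_specific <- data.frame(
    id = c(sp_l, sp_m),
    group = rep_len(in_study_groups, length(c(sp_l, sp_m))),
    stringsAsFactors = FALSE)

  de <- list()
  plant_de <- function(comparison, lnc_n, mrna_n, lfc_signs) {
    l <- take(lnc_pool, lnc_n, used_l); used_l <<- c(used_l, l)
    m <- take(mrna_pool, mrna_n, used_m); used_m <<- c(used_m, m)
    ids <- c(l, m)
    data.frame(id = ids, comparison = comparison,
               lfc = cfg$planted_lfc * rep_len(lfc_signs, length(ids)),
               stringsAsFactors = FALSE)
  }
  de[[1]] <- plant_de("injured_vs_normal_ipRGC", cfg$de_extra_lnc[1],
                      cfg$de_extra_mrna[1], 1)
  de[[2]] <- rbind(
    data.frame(id = c(truth$cis_pairs$lncrna_id, truth$cis_pairs$mrna_id),
               comparison = "injured_vs_normal_ooDSGC",
               lfc = cfg$planted_lfc *
                 rep(rep_len(c(1, -1), cfg$n_cis_pairs), 2),
               stringsAsFactors = FALSE),
    # each block lncRNA responds upward; members follow the block's
    # correlation sign so the injury response is coherent with the
    # planted co-expression structure
    data.frame(id = c(gba_lnc, gba_mrna),
               comparison = "injured_vs_normal_ooDSGC",
               lfc = cfg$planted_lfc *
                 c(rep(1, cfg$gba_blocks),
                   rep(sign(cfg$gba_block_signs), each = cfg$gba_block_size)),
               stringsAsFactors = FALSE))
  de[[3]] <- plant_de("injured_ooDSGC_vs_injured_ipRGC", cfg$de_extra_lnc[2],
                      cfg$de_extra_mrna[2], c(1, -1))
  de[[4]] <- plant_de("normal_ooDSGC_vs_normal_ipRGC", cfg$de_extra_lnc[3],
                      cfg$de_extra_mrna[3], c(1, -1))

  gba <- data.frame(
    id = c(gba_lnc, gba_mrna),
    role = c(rep("lncRNA", cfg$gba_blocks), rep("mRNA", n_gba_mrna)),
    block = c(seq_len(cfg$gba_blocks),
              rep(seq_len(cfg$gba_blocks), each = cfg$gba_block_size)),
    sign = c(rep(1, cfg$gba_blocks),
             rep(cfg$gba_block_signs, each = cfg$gba_block_size)),
    stringsAsFactors = FALSE)

  list(exclusive = exclusive, type_specific = type_specific,
       de = do.call(rbind, de), gba = gba)
}

#' Generate expression counts, design and profile tables
#'
#' Baseline abundances are log-normal; planted type-exclusive transcripts are
#' zeroed in the other RGC type, type-specific transcripts concentrate a
#' fraction `psi` of their in-study expression in one group, and planted DE
#' transcripts apply the configured log2 fold change between the compared
#' groups. Planted cis pairs and co-expression blocks share latent factors
#' across all profile columns with loadings set so the expected Pearson
#' correlation equals the target. Replicate counts are negative-binomial
#' around expected fragment counts.
#'
#' @param cfg A [simulation_config()].
#' @param sim Result of [simulate_annotation()].
#' @return List with `counts` (matrix), `design` (data frame), `profiles`
#'   (matrix over the 4 in-study + external profile columns), `lengths`
#'   (mature lengths) and the enriched `truth`.
#' @export
simulate_expression <- function(cfg, sim) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(child_seed(cfg$seed, 2L))
  truth <- sim$truth
  if (!cfg$plant_effects)
    truth$cis_pairs <- truth$cis_pairs[0, , drop = FALSE]
  plant <- assign_plantings(cfg, truth)
  truth[names(plant)] <- plant

  tx <- rbind(sim$reference$transcripts, sim$assembled$transcripts)
  ids <- tx$transcript_id
  n <- length(ids)
  G <- 4L + cfg$n_external_groups
  cols <- c(in_study_groups, sprintf("extRGC_%02d", seq_len(cfg$n_external_groups)))
  comparisons <- standard_comparisons()
  comp_groups <- stats::setNames(
    lapply(comparisons, function(cc) c(cc$group_a, cc$group_b)),
    vapply(comparisons, `[[`, character(1), "name"))

  mu <- matrix(rlnorm2(n, cfg$baseline_meanlog, cfg$baseline_sdlog),
               n, G, dimnames = list(ids, cols))

  # type-exclusive: zero in the other RGC type
  for (i in seq_len(nrow(plant$exclusive))) {
    other <- if (plant$exclusive$rgc_type[i] == "ipRGC") "ooDSGC" else "ipRGC"
    mu[plant$exclusive$id[i], grep(other, in_study_groups, value = TRUE)] <- 0
  }
  # type-specific: reallocate psi of the in-study total to the target group
  for (i in seq_len(nrow(plant$type_specific))) {
    id <- plant$type_specific$id[i]
    S <- sum(mu[id, in_study_groups])
    w <- rep((1 - cfg$psi) / 3, 4)
    w[match(plant$type_specific$group[i], in_study_groups)] <- cfg$psi
    mu[id, in_study_groups] <- S * w
  }
  # planted DE: fold change on the comparison's numerator group
  for (i in seq_len(nrow(plant$de))) {
    g <- comp_groups[[plant$de$comparison[i]]][1]
    mu[plant$de$id[i], g] <- mu[plant$de$id[i], g] * 2^plant$de$lfc[i]
  }

  # noise structure: every transcript gets a standard-normal deviation per
  # profile column, iid by default and factor-structured for planted cis
  # pairs and co-expression blocks; the noise scale is uniform across
  # transcripts (cv `profile_cv` on the external cell-type columns, log-sd
  # `group_noise_sd` on the in-study columns)
  z <- matrix(stats::rnorm(n * G), n, G, dimnames = list(ids, cols))
  for (i in seq_len(nrow(truth$cis_pairs))) {
    f <- stats::rnorm(G)
    fp <- factor_pair(f, cfg$cis_target_r)
    z[truth$cis_pairs$lncrna_id[i], ] <- fp$a
    z[truth$cis_pairs$mrna_id[i], ] <- fp$b
  }
  lam <- sqrt(cfg$gba_target_r)
  for (b in seq_len(cfg$gba_blocks)) {
    f <- stats::rnorm(G)
    members <- plant$gba[plant$gba$block == b, ]
    for (i in seq_len(nrow(members))) {
      z[members$id[i], ] <- if (members$role[i] == "lncRNA") f
        else members$sign[i] * (lam * f + sqrt(1 - cfg$gba_target_r) *
                                  stats::rnorm(G))
    }
  }

  prof <- mu
  ext <- cols[-(1:4)]
  prof[, ext] <- modulate(mu[, ext], z[, ext], cfg$profile_cv)
  prof[, 1:4] <- mu[, 1:4] * exp(cfg$group_noise_sd * z[, 1:4])

  # replicate counts, negative binomial around expected fragment counts
  design <- data.frame(
    sample_id = paste0(rep(in_study_groups, each = cfg$replicates), "_r",
                       seq_len(cfg$replicates)),
    rgc_type = rep(sub("_.*", "", in_study_groups), each = cfg$replicates),
    condition = rep(sub(".*_", "", in_study_groups), each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), 4),
    stringsAsFactors = FALSE)
  design$group <- paste(design$rgc_type, design$condition, sep = "_")

  len_kb <- tx$mature_length / 1000
  counts <- matrix(0, n, nrow(design),
                   dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu_j <- prof[, design$group[j]] * len_kb * cfg$depth_factor
    counts[, j] <- stats::rnbinom(n, mu = mu_j, size = 1 / cfg$nb_dispersion)
  }

  truth$expected_detected <- lapply(
    stats::setNames(in_study_groups, in_study_groups),
    function(g) ids[mu[, g] > 0])

  list(counts = counts, design = design, profiles = prof,
       lengths = stats::setNames(tx$mature_length, ids), truth = truth)
}

# log-normal with guard against degenerate sd
rlnorm2 <- function(n, meanlog, sdlog) stats::rlnorm(n, meanlog, max(sdlog, 0))

#' Generate coding-potential and term-annotation side tables
#'
#' Novel candidates planted as `coding` receive a coding CPC label or a CPAT
#' probability above the cutoff; all other candidates are scored noncoding.
#' Each co-expression block gets one planted term annotating all of its
#' genes; background terms annotate genes independently at the configured
#' rate.
#'
#' @param cfg A [simulation_config()].
#' @param expr Result of [simulate_expression()] (for the enriched truth).
#' @param sim Result of [simulate_annotation()].
#' @return List with `coding_potential`, `terms` and `de_tables`
#'   (DESeq2-style result fixtures, one per standard comparison) plus the
#'   final `truth`.
#' @export
simulate_side_tables <- function(cfg, expr, sim) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(child_seed(cfg$seed, 3L))
  truth <- expr$truth
  asm_ids <- sim$assembled$transcripts$transcript_id
  cat_of <- stats::setNames(truth$novel_category$category,
                            truth$novel_category$transcript_id)
  is_coding <- cat_of[asm_ids] == "coding"
  cp <- data.frame(
    transcript_id = asm_ids,
    cpc_label = ifelse(is_coding & stats::runif(length(asm_ids)) < 0.5,
                       "coding", "noncoding"),
    cpat_probability = ifelse(is_coding, stats::runif(length(asm_ids), 0.6, 0.99),
                              stats::runif(length(asm_ids), 0.01, 0.3)),
    stringsAsFactors = FALSE)
  # ensure every planted-coding candidate is flagged by at least one tool
  cp$cpat_probability[is_coding & cp$cpc_label == "noncoding"] <-
    pmax(cp$cpat_probability[is_coding & cp$cpc_label == "noncoding"], 0.6)

  mrna_genes <- sim$reference$transcripts$gene_id[
    sim$reference$transcripts$biotype == "protein_coding"]
  gene_of <- stats::setNames(sim$reference$transcripts$gene_id,
                             sim$reference$transcripts$transcript_id)
  rows <- list()
  for (t in seq_len(cfg$n_background_terms)) {
    hit <- mrna_genes[stats::runif(length(mrna_genes)) < cfg$term_bg_rate]
    if (length(hit) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = hit, term_id = sprintf("term_bg_%02d", t),
        term_name = sprintf("background process %d", t),
        stringsAsFactors = FALSE)
  }
  planted_terms <- character(0)
  gba <- truth$gba
  for (b in seq_len(cfg$gba_blocks)) {
    block_genes <- unname(gene_of[gba$id[gba$block == b & gba$role == "mRNA"]])
    outside <- setdiff(mrna_genes, block_genes)
    hit <- c(block_genes, outside[stats::runif(length(outside)) <
                                    cfg$term_out_rate])
    tid <- sprintf("term_block_%d", b)
    planted_terms[b] <- tid
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = hit, term_id = tid,
      term_name = sprintf("planted block process %d", b),
      stringsAsFactors = FALSE)
  }
  truth$enriched_terms <- data.frame(term_id = planted_terms,
                                     block = seq_len(cfg$gba_blocks),
                                     stringsAsFactors = FALSE)

  # DESeq2-style DE result fixtures, one table per standard comparison:
  # planted transcripts carry their planted fold change (with estimation
  # noise) and a small p-value, unplanted ones a null uniform p-value
  all_ids <- c(sim$reference$transcripts$transcript_id, asm_ids)
  de_tables <- lapply(standard_comparisons(), function(cc) {
    planted <- truth$de[truth$de$comparison == cc$name, ]
    idx <- match(all_ids, planted$id)
    hit <- !is.na(idx)
    lfc <- ifelse(hit, planted$lfc[idx] + stats::rnorm(length(all_ids), 0, 0.2),
                  stats::rnorm(length(all_ids), 0, 0.3))
    p <- ifelse(hit, 10^-stats::runif(length(all_ids), 4, 12),
                stats::runif(length(all_ids)))
    data.frame(transcript_id = all_ids, log2FoldChange = lfc, pvalue = p,
               padj = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  })
  names(de_tables) <- vapply(standard_comparisons(), `[[`, character(1), "name")

  list(coding_potential = cp, terms = do.call(rbind, rows),
       de_tables = de_tables, truth = truth)
}

#' Generate and write a complete synthetic study bundle
#'
#' Runs [simulate_annotation()], [simulate_expression()] and
#' [simulate_side_tables()] and writes `reference.gtf`, `assembled.gtf`,
#' `counts.tsv`, `design.tsv`, `profiles.tsv`, `coding_potential.tsv`,
#' `terms.tsv`, one `de_<comparison>.tsv` per standard comparison and
#' `truth.json` to `dir`. Byte-identical for identical configurations.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return The truth list, invisibly.
#' @export
simulate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, sim)
  side <- simulate_side_tables(cfg, expr, sim)

  write_gtf(sim$reference, file.path(dir, "reference.gtf"))
  write_gtf(sim$assembled, file.path(dir, "assembled.gtf"))
  wt <- function(x, f, rn = FALSE) {
    if (rn) x <- data.frame(transcript_id = rownames(x), x,
                            check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(expr$counts, "counts.tsv", rn = TRUE)
  wt(expr$design, "design.tsv")
  wt(round(expr$profiles, 6), "profiles.tsv", rn = TRUE)
  wt(side$coding_potential, "coding_potential.tsv")
  wt(side$terms, "terms.tsv")
  for (nm in names(side$de_tables))
    wt(side$de_tables[[nm]], sprintf("de_%s.tsv", nm))
  jsonlite::write_json(side$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side$truth)
}

# ---- module-level profile generators (used by tests and calibration) --------

#' Simulate correlated lncRNA-mRNA profile pairs
#'
#' Each pair shares a standard-normal latent factor with loading
#' `sqrt(target_r)`, so the expected Pearson correlation between the paired
#' profiles equals `target_r`; an additional matrix of unrelated profiles
#' (independent noise) is returned for false-positive calibration.
#'
#' @param n_pairs Number of pairs.
#' @param target_r Target Pearson correlation in (0, 1).
#' @param n_groups Number of profile columns (default 16).
#' @param cv Modulation coefficient of variation.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance.
#' @return List of matrices `lnc`, `mrna` (row i of each forms pair i) and
#'   `unrelated` (independent profiles, one per pair).
#' @export
simulate_correlated_profiles <- function(n_pairs, target_r = 0.9,
                                         n_groups = 16, cv = 0.4,
                                         baseline_meanlog = log(100),
                                         baseline_sdlog = 0.8) {
  lnc <- mrna <- unrel <- matrix(0, n_pairs, n_groups)
  for (i in seq_len(n_pairs)) {
    f <- stats::rnorm(n_groups)
    fp <- factor_pair(f, target_r)
    lnc[i, ] <- modulate(rlnorm2(1, baseline_meanlog, baseline_sdlog), fp$a, cv)
    mrna[i, ] <- modulate(rlnorm2(1, baseline_meanlog, baseline_sdlog), fp$b, cv)
    unrel[i, ] <- modulate(rlnorm2(1, baseline_meanlog, baseline_sdlog),
                           stats::rnorm(n_groups), cv)
  }
  rownames(lnc) <- sprintf("lnc_%03d", seq_len(n_pairs))
  rownames(mrna) <- sprintf("mrna_%03d", seq_len(n_pairs))
  rownames(unrel) <- sprintf("unrel_%03d", seq_len(n_pairs))
  list(lnc = lnc, mrna = mrna, unrelated = unrel)
}

#' Simulate sign-coherent co-expression blocks
#'
#' One lncRNA per block carries the block's latent factor; block mRNAs load
#' on it with `sqrt(target_r)` times the block's sign, yielding clean
#' positively or negatively correlated blocks.
#'
#' @param n_blocks,block_size Block design.
#' @param target_r Target |Pearson correlation| of members with their block
#'   lncRNA.
#' @param n_groups Number of profile columns.
#' @param cv Modulation coefficient of variation.
#' @param signs Correlation sign per block (recycled).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance.
#' @return List with `lnc`, `mrna` matrices and `blocks` (planted block label
#'   per mRNA row).
#' @export
simulate_gba_profiles <- function(n_blocks = 3, block_size = 10,
                                  target_r = 0.95, n_groups = 16, cv = 0.4,
                                  signs = c(1, -1, 1),
                                  baseline_meanlog = log(100),
                                  baseline_sdlog = 0.8) {
  signs <- rep_len(signs, n_blocks)
  lam <- sqrt(target_r)
  lnc <- matrix(0, n_blocks, n_groups,
                dimnames = list(sprintf("lnc_b%d", seq_len(n_blocks)), NULL))
  mrna <- matrix(0, n_blocks * block_size, n_groups)
  rownames(mrna) <- sprintf("mrna_b%d_%02d", rep(seq_len(n_blocks),
                                                 each = block_size),
                            rep(seq_len(block_size), n_blocks))
  for (b in seq_len(n_blocks)) {
    f <- stats::rnorm(n_groups)
    lnc[b, ] <- modulate(rlnorm2(1, baseline_meanlog, baseline_sdlog), f, cv)
    for (j in seq_len(block_size)) {
      zz <- signs[b] * (lam * f + sqrt(1 - target_r) * stats::rnorm(n_groups))
      mrna[(b - 1) * block_size + j, ] <-
        modulate(rlnorm2(1, baseline_meanlog, baseline_sdlog), zz, cv)
    }
  }
  list(lnc = lnc, mrna = mrna,
       blocks = rep(seq_len(n_blocks), each = block_size), signs = signs)
}
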