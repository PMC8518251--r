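# End-to-end orchestration over a study bundle on disk: discovery ->
# detection -> specificity -> differential expression -> cis neighbours ->
# guilt-by-association clustering and enrichment, with a run manifest of
# input checksums and stage counts.

#' Pipeline configuration
#'
#' All analysis thresholds in one place, with the study defaults.
#'
#' @param intergenic_window Exclusion distance around reference genes for
#'   novel candidates (bp).
#' @param min_length,min_exons Structural filters for novel candidates.
#' @param cpat_cutoff CPAT coding-probability cutoff.
#' @param fpkm_threshold,min_reps Detection rule: FPKM strictly above the
#'   threshold in at least `min_reps` replicates of a group.
#' @param fel_threshold Cell-type-specificity cutoff on the maximum
#'   fractional expression level (strict).
#' @param range_lo,range_hi Closed TPM interval for the range-matched
#'   specificity contrast.
#' @param de_alpha Adjusted-p cutoff for differential expression (strict).
#' @param neighbor_window cis-candidate window (bp, gene span to gene span).
#' @param cis_r_threshold,cis_alpha cis correlation filter (both strict).
#' @param gba_r_threshold Guilt-by-association |r| cutoff (strict).
#' @param clusters_k Cluster counts for the GBA comparisons (comparisons 2-4
#'   of [standard_comparisons()]).
#' @param enrichment_alpha Raw-p cutoff for term enrichment.
#' @param enrichment_variant `"ease"` (default) or `"fisher"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(intergenic_window = 2000,
                            min_length = 200,
                            min_exons = 2,
                            cpat_cutoff = 0.44,
                            fpkm_threshold = 0.3,
                            min_reps = 2,
                            fel_threshold = 0.5,
                            range_lo = 4,
                            range_hi = 20,
                            de_alpha = 0.05,
                            neighbor_window = 300000,
                            cis_r_threshold = 0.5,
                            cis_alpha = 0.05,
                            gba_r_threshold = 0.88,
                            clusters_k = c(4, 4, 3),
                            enrichment_alpha = 0.05,
                            enrichment_variant = "ease") {
  cfg <- as.list(environment())
  in01 <- function(x) x > 0 && x < 1
  stopifnot(cfg$range_lo < cfg$range_hi, length(cfg$clusters_k) == 3L,
            cfg$enrichment_variant %in% c("ease", "fisher"),
            cfg$intergenic_window >= 0, cfg$neighbor_window >= 0,
            cfg$min_length > 0, cfg$min_exons >= 1, cfg$fpkm_threshold > 0,
            cfg$min_reps >= 1, cfg$fel_threshold > 0, cfg$range_lo > 0,
            in01(cfg$cpat_cutoff), in01(cfg$cis_r_threshold),
            in01(cfg$gba_r_threshold), in01(cfg$de_alpha),
            in01(cfg$cis_alpha), in01(cfg$enrichment_alpha),
            all(cfg$clusters_k >= 1))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' Round-trips exactly: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort("configuration file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# run one stage with an error prefix naming it
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort("stage '%s' failed: %s", name, conditionMessage(e)))
}

# merge reference and novel annotations for span lookups
combine_annotations <- function(a, b) {
  dup <- intersect(a$transcripts$transcript_id, b$transcripts$transcript_id)
  if (length(dup) > 0L)
    abort("duplicated transcript id(s) across annotations: %s",
          paste(dup, collapse = ", "))
  genes <- c(a$genes, b$genes[setdiff(names(b$genes), names(a$genes))])
  structure(list(transcripts = rbind(a$transcripts, b$transcripts),
                 exons = c(a$exons, b$exons),
                 genes = genes,
                 tx_spans = c(a$tx_spans, b$tx_spans)),
            class = "AnnotationSet")
}

#' Run the full analysis pipeline over a study bundle
#'
#' Expects `reference.gtf`, `assembled.gtf`, `counts.tsv`, `design.tsv`,
#' `coding_potential.tsv`, `profiles.tsv` and `terms.tsv` in `input_dir`
#' (the layout written by [simulate_study()]). Stages: novel-lncRNA
#' discovery, FPKM/TPM and detection, exclusive/shared set logic per RGC
#' type, FEL specificity with the range-matched chi-square contrast,
#' differential expression over the four standard comparisons (a supplied
#' `de_<comparison>.tsv` result table is used when present, the naive
#' stand-in [naive_de()] otherwise), cis-neighbour correlation for the
#' ooDSGC injury comparison, and guilt-by-association clustering with term
#' enrichment for comparisons 2-4. Any stage failure aborts with the stage
#' name.
#'
#' @param input_dir Directory holding the input bundle.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, summary tables and the run
#'   manifest are written there.
#' @return List of class `pipeline_result` with components `catalog`,
#'   `report`, `detection`, `venn`, `specificity`, `de`, `cis`, `gba` and
#'   `manifest`.
#' @export
run_pipeline <- function(input_dir, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- c("reference.gtf", "assembled.gtf", "counts.tsv", "design.tsv",
             "coding_potential.tsv", "profiles.tsv", "terms.tsv")
  paths <- file.path(input_dir, files)
  absent <- files[!file.exists(paths)]
  if (length(absent) > 0L)
    abort("missing input file(s) in %s: %s", input_dir,
          paste(absent, collapse = ", "))

  reference <- stage("annotation", read_gtf(paths[1], "reference"))
  assembled <- stage("annotation", read_gtf(paths[2], "assembled"))

  disc <- stage("discovery", discover_lncrnas(
    assembled, reference, read_coding_potential(paths[5]),
    window = config$intergenic_window, min_length = config$min_length,
    min_exons = config$min_exons, cpat_cutoff = config$cpat_cutoff))
  combined <- combine_annotations(reference, disc$novel)

  counts <- stage("expression", read_expression_matrix(paths[3]))
  design <- stage("expression", read_sample_design(paths[4]))
  lengths <- stats::setNames(combined$transcripts$mature_length,
                             combined$transcripts$transcript_id)
  counts <- counts[intersect(rownames(counts), names(lengths)), ,
                   drop = FALSE]
  fpkm <- compute_fpkm(counts, lengths)
  tpm <- compute_tpm(counts, lengths)
  calls <- stage("expression", detect_expressed(
    fpkm, design, config$fpkm_threshold, config$min_reps))

  lnc_ids <- intersect(rownames(counts), disc$catalog$transcript_id)
  mrna_ids <- rownames(counts)[
    combined$transcripts[rownames(counts), "biotype"] == "protein_coding"]
  ip_groups <- grep("^ipRGC", colnames(calls), value = TRUE)
  oo_groups <- grep("^ooDSGC", colnames(calls), value = TRUE)
  venn <- stage("expression", list(
    lncRNA = venn_sets(
      intersect(detected_ids(calls, ip_groups), lnc_ids),
      intersect(detected_ids(calls, oo_groups), lnc_ids),
      names = c("ipRGC", "ooDSGC")),
    mRNA = venn_sets(
      intersect(detected_ids(calls, ip_groups), mrna_ids),
      intersect(detected_ids(calls, oo_groups), mrna_ids),
      names = c("ipRGC", "ooDSGC"))))

  det <- rownames(calls)[attr(calls, "detected")]
  det_lnc <- intersect(det, lnc_ids)
  det_mrna <- intersect(det, mrna_ids)
  spc <- stage("specificity", {
    fel <- compute_fel(tpm[det, , drop = FALSE], design)
    is_spec <- classify_specific(fel, config$fel_threshold)
    matched <- range_matched_subset(tpm[det, , drop = FALSE], design,
                                    config$range_lo, config$range_hi)
    tab <- function(ids) {
      ids <- intersect(ids, names(is_spec))
      c(specific = sum(is_spec[ids]), other = sum(!is_spec[ids]))
    }
    counts2 <- rbind(lncRNA = tab(det_lnc), mRNA = tab(det_mrna))
    list(fel = fel, specific = is_spec,
         pct = c(lncRNA = pct_round(100 * counts2[1, 1] / sum(counts2[1, ])),
                 mRNA = pct_round(100 * counts2[2, 1] / sum(counts2[2, ]))),
         matched = matched,
         matched_pct = c(
           lncRNA = pct_round(100 * sum(is_spec[intersect(det_lnc, matched)]) /
                                max(length(intersect(det_lnc, matched)), 1)),
           mRNA = pct_round(100 * sum(is_spec[intersect(det_mrna, matched)]) /
                              max(length(intersect(det_mrna, matched)), 1))),
         # degenerate tables (e.g. no specific transcripts at a strict
         # threshold) carry no contrast rather than aborting the run
         contrast = if (any(rowSums(counts2) == 0) ||
                        any(colSums(counts2) == 0)) NULL
                    else specificity_contrast(counts2))
  })

  comparisons <- standard_comparisons()
  de <- stage("diffexpr", lapply(comparisons, function(cc) {
    supplied <- file.path(input_dir, sprintf("de_%s.tsv", cc$name))
    if (file.exists(supplied)) load_de_table(supplied, cc)
    else naive_de(tpm[det, , drop = FALSE], design, cc)
  }))
  names(de) <- vapply(comparisons, `[[`, character(1), "name")

  profiles <- stage("expression", read_expression_matrix(paths[6]))
  de_sets <- lapply(de, function(d) significant(d, config$de_alpha)$transcript_id)

  cis <- stage("cis_neighbors", {
    dl <- intersect(de_sets[[2]], det_lnc)
    dm <- intersect(de_sets[[2]], det_mrna)
    pairs <- find_neighbors(dl, dm, combined, config$neighbor_window)
    if (nrow(pairs) > 0L)
      pairs <- filter_correlated(pairs, profiles, config$cis_r_threshold,
                                 config$cis_alpha)
    pairs
  })

  terms <- stage("coexpression", {
    tt <- utils::read.delim(paths[7], stringsAsFactors = FALSE)
    require_columns(tt, c("gene_id", "term_id"), "term table")
    tt
  })
  gene_of <- stats::setNames(combined$transcripts$gene_id,
                             combined$transcripts$transcript_id)
  gba <- stage("coexpression", lapply(2:4, function(i) {
    dl <- intersect(de_sets[[i]], det_lnc)
    dm <- intersect(de_sets[[i]], det_mrna)
    if (length(dl) == 0L || length(dm) == 0L)
      return(list(comparison = names(de)[i], matrix = NULL,
                  clusters = integer(0), enrichment = NULL))
    gm <- gba_matrix(profiles[dl, , drop = FALSE],
                     profiles[dm, , drop = FALSE],
                     config$gba_r_threshold)
    k <- min(config$clusters_k[i - 1], nrow(gm$r))
    clusters <- if (nrow(gm$r) > 0L) cluster_mrnas(gm, k) else integer(0)
    background <- unique(unname(gene_of[dm]))
    enr <- if (length(clusters) == 0L) NULL
      else lapply(split(names(clusters), clusters), function(ids)
        enrich_terms(unique(unname(gene_of[ids])), background, terms,
                     config$enrichment_alpha, config$enrichment_variant))
    list(comparison = names(de)[i], matrix = gm, clusters = clusters,
         enrichment = enr)
  }))

  manifest <- list(
    inputs = as.list(stats::setNames(tools::md5sum(paths), files)),
    config = unclass(config),
    counts = list(
      candidates = nrow(assembled$transcripts),
      novel_retained = nrow(disc$novel$transcripts),
      catalog = nrow(disc$catalog),
      detected = length(det),
      detected_lncrna = length(det_lnc),
      detected_mrna = length(det_mrna),
      de_significant = vapply(de_sets, length, 1L),
      cis_pairs = nrow(cis),
      cis_correlated = if (nrow(cis) > 0L) sum(cis$correlated) else 0L))

  result <- structure(
    list(catalog = disc$catalog, report = disc$report, detection = calls,
         venn = venn, specificity = spc, de = de, cis = cis, gba = gba,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(disc$report, file.path(out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(disc$catalog, file.path(out_dir, "catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, de), file.path(out_dir, "de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cis, file.path(out_dir, "cis_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cn <- x$manifest$counts
  cat(sprintf("Pipeline result: %d/%d novel candidates retained, catalog %d\n",
              cn$novel_retained, cn$candidates, cn$catalog))
  cat(sprintf("Detected: %d (%d lncRNA, %d mRNA)\n",
              cn$detected, cn$detected_lncrna, cn$detected_mrna))
  cat("Significant per comparison:",
      paste(sprintf("%s=%d", names(cn$de_significant), cn$de_significant),
            collapse = ", "), "\n")
  cat(sprintf("cis pairs: %d (%d correlated)\n",
              cn$cis_pairs, cn$cis_correlated))
  invisible(x)
}
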