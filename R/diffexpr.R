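# Differential-expression table consumption plus a declared naive
# stand-in test (Welch t on log2(TPM+1) with Benjamini-Hochberg adjustment)
# so synthetic pipelines run end to end. The negative-binomial GLM machinery
# of dedicated DE tools is deliberately out of scope: real-data workflows
# supply their result tables.

#' The four standard group comparisons
#'
#' @return List of comparisons, each a list with `name`, `group_a`
#'   (numerator) and `group_b` (denominator).
#' @export
standard_comparisons <- function() {
  list(
    list(name = "injured_vs_normal_ipRGC",
         group_a = "ipRGC_injured", group_b = "ipRGC_normal"),
    list(name = "injured_vs_normal_ooDSGC",
         group_a = "ooDSGC_injured", group_b = "ooDSGC_normal"),
    list(name = "injured_ooDSGC_vs_injured_ipRGC",
         group_a = "ooDSGC_injured", group_b = "ipRGC_injured"),
    list(name = "normal_ooDSGC_vs_normal_ipRGC",
         group_a = "ooDSGC_normal", group_b = "ipRGC_normal"))
}

new_de_records <- function(transcript_id, comparison, lfc, p, padj,
                           flagged = FALSE) {
  data.frame(transcript_id = transcript_id, comparison = comparison,
             log2_fold_change = lfc, p_value = p, adj_p_value = padj,
             direction = ifelse(lfc >= 0, "up", "down"),
             flagged_na_padj = flagged, stringsAsFactors = FALSE)
}

#' Load a differential-expression result table
#'
#' @param path TSV with columns `transcript_id`, `log2FoldChange`, `pvalue`,
#'   `padj`.
#' @param comparison Comparison label or a comparison list (see
#'   [standard_comparisons()]).
#' @return Data frame of DE records. Rows with missing adjusted p are
#'   retained with `adj_p_value = 1` and `flagged_na_padj = TRUE`, mirroring
#'   independent-filtering behaviour.
#' @export
load_de_table <- function(path, comparison) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("transcript_id", "log2FoldChange", "pvalue", "padj"),
                  "DE table")
  label <- if (is.list(comparison)) comparison$name else as.character(comparison)
  flagged <- is.na(tab$padj)
  padj <- ifelse(flagged, 1, tab$padj)
  p <- ifelse(is.na(tab$pvalue), 1, tab$pvalue)
  new_de_records(tab$transcript_id, label, tab$log2FoldChange, p, padj, flagged)
}

#' Significant records at an adjusted-p cutoff
#'
#' @param records DE records.
#' @param alpha Cutoff; records with `adj_p_value` strictly below are kept
#'   (default 0.05).
#' @return Subset of `records`.
#' @export
significant <- function(records, alpha = 0.05) {
  records[records$adj_p_value < alpha, , drop = FALSE]
}

#' Naive differential-expression stand-in
#'
#' Per transcript: log2 fold change of (group mean TPM + 1), Welch t-test on
#' log2(TPM + 1), Benjamini-Hochberg adjustment across all tested
#' transcripts. Deterministic given its inputs.
#'
#' @param tpm TPM matrix.
#' @param design Sample design; both compared groups need >= 2 replicates.
#' @param comparison List with `name`, `group_a`, `group_b`.
#' @return Data frame of DE records.
#' @export
naive_de <- function(tpm, design, comparison) {
  groups <- design_groups(design, colnames(tpm))
  ja <- which(groups == comparison$group_a)
  jb <- which(groups == comparison$group_b)
  if (length(ja) < 2L || length(jb) < 2L)
    abort("comparison %s requires >= 2 replicates per group", comparison$name)
  a <- tpm[, ja, drop = FALSE]; b <- tpm[, jb, drop = FALSE]
  lfc <- log2(rowMeans(a) + 1) - log2(rowMeans(b) + 1)
  p <- welch_p(log2(a + 1), log2(b + 1))
  padj <- stats::p.adjust(p, method = "BH")
  new_de_records(rownames(tpm), comparison$name, lfc, p, padj)
}

#' Volcano and heat-map exports for significant transcripts
#'
#' The heat map rows are per-transcript Z-scores of the group-mean TPM
#' vector, `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation;
#' constant rows are emitted as all-zero and flagged.
#'
#' @param records DE records (all tested transcripts).
#' @param tpm TPM matrix.
#' @param design Sample design.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @return List with `volcano` (transcript_id, log2_fold_change,
#'   neg_log10_adj_p, significant), `heatmap` (Z-score matrix for significant
#'   transcripts) and `constant_rows` (flagged ids).
#' @export
export_views <- function(records, tpm, design, alpha = 0.05) {
  volcano <- data.frame(
    transcript_id = records$transcript_id,
    log2_fold_change = records$log2_fold_change,
    neg_log10_adj_p = -log10(pmax(records$adj_p_value, .Machine$double.xmin)),
    significant = records$adj_p_value < alpha,
    stringsAsFactors = FALSE)
  sig <- records$transcript_id[records$adj_p_value < alpha]
  if (length(sig) == 0L) {
    warning("no significant transcripts; empty heat-map export")
    return(list(volcano = volcano,
                heatmap = matrix(numeric(0), 0, 0), constant_rows = character(0)))
  }
  gm <- group_means(tpm[sig, , drop = FALSE], design)
  mu <- rowMeans(gm)
  sd <- apply(gm, 1, stats::sd)
  constant <- sd == 0
  z <- (gm - mu) / ifelse(sd == 0, 1, sd)
  z[constant, ] <- 0
  list(volcano = volcano, heatmap = z,
       constant_rows = rownames(gm)[constant])
}
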