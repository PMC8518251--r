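# Novel-lincRNA filter cascade and combined lncRNA catalog.
#
# Candidate transcripts from a de novo assembly are retained only if they are
# intergenic (farther than a window from every reference gene span, either
# strand), multi-exonic and at least 200 nt of mature length, and flagged
# noncoding by both coding-potential tools. Survivors are combined with the
# reference lincRNA/antisense transcripts into the working lncRNA catalog.

new_filter_report <- function(ids, status) {
  data.frame(transcript_id = ids, status = status, stringsAsFactors = FALSE)
}

#' Remove assembled transcripts overlapping or near reference genes
#'
#' A candidate is retained only when its span neither overlaps any reference
#' gene span (on either strand) nor lies within `window` bp of one; this is
#' the transcript-level equivalent of keeping only fully intergenic
#' ("class code u") assembly products outside a +/- 2 kb exclusion zone.
#'
#' @param assembled `AnnotationSet` of candidate transcripts.
#' @param reference Reference `AnnotationSet`.
#' @param window Exclusion distance in bp (default 2000).
#' @return List with `retained` (an `AnnotationSet`) and `report` (data frame
#'   of transcript_id, status).
#' @export
filter_intergenic_novel <- function(assembled, reference, window = 2000) {
  stopifnot(inherits(assembled, "AnnotationSet"),
            inherits(reference, "AnnotationSet"), window >= 0)
  spans <- assembled$tx_spans
  d <- rep(Inf, length(spans))
  if (length(reference$genes) > 0L) {
    hits <- GenomicRanges::distanceToNearest(spans, reference$genes,
                                             ignore.strand = TRUE)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  keep <- d > window
  status <- ifelse(keep, "retained", "too_close_or_overlapping")
  report <- new_filter_report(names(spans), status)
  list(retained = subset_annotation(assembled, names(spans)[keep]),
       report = report)
}

#' Remove short and monoexonic transcripts
#'
#' Retains transcripts with mature (summed exon) length of at least
#' `min_length` nt and at least `min_exons` exons. A transcript failing both
#' rules is labelled by the first (`too_short`).
#'
#' @param ts `AnnotationSet` of candidates.
#' @param min_length Minimum mature length in nt (default 200; transcripts
#'   strictly shorter are removed).
#' @param min_exons Minimum exon count (default 2, removing monoexonic
#'   transcripts).
#' @return List with `retained` and `report`, as in
#'   [filter_intergenic_novel()].
#' @export
filter_structure <- function(ts, min_length = 200, min_exons = 2) {
  stopifnot(inherits(ts, "AnnotationSet"))
  tx <- ts$transcripts
  status <- rep("retained", nrow(tx))
  status[tx$n_exons < min_exons] <- "monoexonic"
  status[tx$mature_length < min_length] <- "too_short"
  report <- new_filter_report(tx$transcript_id, status)
  list(retained = subset_annotation(ts, tx$transcript_id[status == "retained"]),
       report = report)
}

#' Read a coding-potential score table
#'
#' @param path TSV with columns `transcript_id`, `cpc_label`
#'   (`coding`/`noncoding`) and `cpat_probability` (in `[0, 1]`).
#' @return Data frame keyed by transcript_id.
#' @export
read_coding_potential <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("transcript_id", "cpc_label", "cpat_probability"),
                  "coding-potential table")
  if (anyDuplicated(tab$transcript_id))
    abort("duplicated transcript_id in coding-potential table")
  rownames(tab) <- tab$transcript_id
  tab
}

#' Remove transcripts with coding potential
#'
#' A transcript is discarded when either tool calls it coding: the CPC label
#' is `coding`, or the CPAT coding probability is at or above `cpat_cutoff`
#' (default 0.44, the published mouse cutoff). Survivors are assigned biotype
#' `novel_lincRNA`.
#'
#' @param ts `AnnotationSet` of candidates.
#' @param scores Coding-potential table from [read_coding_potential()] (or a
#'   data frame with the same columns).
#' @param cpat_cutoff CPAT probability cutoff in (0, 1).
#' @param rule `"either"` (default: flagged by either tool is discarded) or
#'   `"both"`.
#' @param missing Policy for transcripts absent from `scores`: `"error"`
#'   (default) or `"discard"`.
#' @return List with `retained` and `report`.
#' @export
filter_coding_potential <- function(ts, scores, cpat_cutoff = 0.44,
                                    rule = c("either", "both"),
                                    missing = c("error", "discard")) {
  stopifnot(inherits(ts, "AnnotationSet"),
            cpat_cutoff > 0, cpat_cutoff < 1)
  rule <- match.arg(rule)
  missing <- match.arg(missing)
  ids <- ts$transcripts$transcript_id
  idx <- match(ids, scores$transcript_id)
  if (anyNA(idx)) {
    absent <- ids[is.na(idx)]
    if (missing == "error")
      abort("transcript(s) missing from coding-potential table: %s",
            paste(absent, collapse = ", "))
  }
  cpc_coding <- scores$cpc_label[idx] == "coding"
  cpat_coding <- scores$cpat_probability[idx] >= cpat_cutoff
  coding <- if (rule == "either") cpc_coding | cpat_coding
            else cpc_coding & cpat_coding
  coding[is.na(idx)] <- TRUE  # missing == "discard"
  status <- ifelse(coding, "coding_potential", "retained")
  report <- new_filter_report(ids, status)
  retained <- subset_annotation(ts, ids[status == "retained"])
  retained$transcripts$biotype <- "novel_lincRNA"
  retained$genes$biotype <- "novel_lincRNA"
  list(retained = retained, report = report)
}

#' Combine reference lncRNAs with retained novel lincRNAs
#'
#' @param reference Reference `AnnotationSet`; its `antisense` and `lincRNA`
#'   transcripts enter the catalog.
#' @param novel `AnnotationSet` of novel lincRNAs that passed all filters.
#' @return Data frame (`transcript_id`, `class`, `gene_id`) with class one of
#'   `antisense`, `lincRNA`, `novel_lincRNA`; classes are disjoint.
#' @export
build_catalog <- function(reference, novel) {
  stopifnot(inherits(reference, "AnnotationSet"),
            inherits(novel, "AnnotationSet"))
  ref_tx <- reference$transcripts
  ref_lnc <- ref_tx[ref_tx$biotype %in% c("antisense", "lincRNA"), ,
                    drop = FALSE]
  dup <- intersect(ref_tx$transcript_id, novel$transcripts$transcript_id)
  if (length(dup) > 0L)
    abort("transcript id(s) present in both reference and novel sets: %s",
          paste(dup, collapse = ", "))
  out <- rbind(
    data.frame(transcript_id = ref_lnc$transcript_id, class = ref_lnc$biotype,
               gene_id = ref_lnc$gene_id, stringsAsFactors = FALSE),
    data.frame(transcript_id = novel$transcripts$transcript_id,
               class = "novel_lincRNA", gene_id = novel$transcripts$gene_id,
               stringsAsFactors = FALSE))
  rownames(out) <- out$transcript_id
  out
}

#' Run the full novel-lincRNA filter cascade
#'
#' Applies [filter_intergenic_novel()], [filter_structure()] and
#' [filter_coding_potential()] in order and combines survivors with the
#' reference lncRNAs via [build_catalog()]. The report records, per candidate,
#' the first filter that removed it.
#'
#' @param assembled,reference `AnnotationSet`s.
#' @param scores Coding-potential table.
#' @param window,min_length,min_exons,cpat_cutoff Filter thresholds; see the
#'   individual filters.
#' @param ... Passed to [filter_coding_potential()].
#' @return List with `catalog`, `novel` (retained `AnnotationSet`) and
#'   `report` (one terminal status per input candidate).
#' @export
discover_lncrnas <- function(assembled, reference, scores, window = 2000,
                             min_length = 200, min_exons = 2,
                             cpat_cutoff = 0.44, ...) {
  s1 <- filter_intergenic_novel(assembled, reference, window)
  s2 <- filter_structure(s1$retained, min_length, min_exons)
  s3 <- filter_coding_potential(s2$retained, scores, cpat_cutoff, ...)
  report <- s1$report
  merge_status <- function(report, sub) {
    idx <- match(sub$transcript_id, report$transcript_id)
    report$status[idx] <- sub$status
    report
  }
  report <- merge_status(report, s2$report)
  report <- merge_status(report, s3$report)
  stopifnot(sum(report$status == "retained") ==
              nrow(s3$retained$transcripts))
  list(catalog = build_catalog(reference, s3$retained),
       novel = s3$retained, report = report)
}
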