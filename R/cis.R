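# Nearest-neighbour cis-candidate analysis: differentially expressed lncRNAs
# paired with differentially expressed protein-coding genes within a genomic
# window (default 300 kb), retaining pairs whose expression profiles are
# Pearson-correlated.

# resolve ids to gene spans: a transcript id maps to its gene's span
resolve_gene_spans <- function(ids, ann) {
  out <- GenomicRanges::GRanges()
  gene_of <- ifelse(ids %in% names(ann$genes), ids,
                    ann$transcripts[ids, "gene_id"])
  bad <- ids[is.na(gene_of) | !(gene_of %in% names(ann$genes))]
  if (length(bad) > 0L)
    abort("id(s) not found in annotation: %s", paste(bad, collapse = ", "))
  out <- ann$genes[gene_of]
  names(out) <- ids
  out
}

#' Protein-coding neighbours of lncRNA loci
#'
#' All (lncRNA, mRNA) pairs whose gene spans lie on the same chromosome
#' within `window` bp (gap distance; 0 when overlapping). Distances are
#' measured span-to-span, strand-agnostic.
#'
#' @param de_lncrnas,de_mrnas Ids (transcript or gene) resolving in `ann`;
#'   transcript ids are mapped to their gene span.
#' @param ann `AnnotationSet` containing both sets.
#' @param window Maximum gap in bp (default 300000).
#' @return Data frame (`lncrna_id`, `mrna_id`, `distance`).
#' @export
find_neighbors <- function(de_lncrnas, de_mrnas, ann, window = 300000) {
  stopifnot(inherits(ann, "AnnotationSet"), window >= 0)
  if (length(de_lncrnas) == 0L || length(de_mrnas) == 0L)
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  ls <- resolve_gene_spans(de_lncrnas, ann)
  ms <- resolve_gene_spans(de_mrnas, ann)
  hits <- GenomicRanges::findOverlaps(ls, ms, maxgap = window,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  data.frame(lncrna_id = names(ls)[q], mrna_id = names(ms)[s],
             distance = genomic_distance(ls[q], ms[s]),
             stringsAsFactors = FALSE)
}

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson r; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (p = 0 at |r| = 1).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Correlation-filter neighbour pairs
#'
#' Computes Pearson r and p over the profile vectors of each pair and flags
#' pairs with `|r| > r_threshold` and `p < alpha` as correlated, labelling
#' the sign. Pairs with a zero-variance profile are dropped with a warning.
#'
#' @param pairs Data frame from [find_neighbors()].
#' @param profiles Numeric matrix of expression profiles (rows = ids, columns
#'   = profile groups) covering every id in `pairs`.
#' @param r_threshold Correlation threshold (default 0.5, strict).
#' @param alpha p-value threshold (default 0.05, strict).
#' @return `pairs` with added `pearson_r`, `p_value`, `correlated`, `sign`
#'   and `n_profile_groups` columns.
#' @export
filter_correlated <- function(pairs, profiles, r_threshold = 0.5,
                              alpha = 0.05) {
  ids <- unique(c(pairs$lncrna_id, pairs$mrna_id))
  missing <- setdiff(ids, rownames(profiles))
  if (length(missing) > 0L)
    abort("id(s) missing from profile matrix: %s",
          paste(missing, collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i)
    pearson_cor(profiles[pairs$lncrna_id[i], ], profiles[pairs$mrna_id[i], ]))
  pairs$pearson_r <- vapply(res, `[[`, numeric(1), "r")
  pairs$p_value <- vapply(res, `[[`, numeric(1), "p")
  pairs$n_profile_groups <- ncol(profiles)
  drop <- is.na(pairs$pearson_r)
  if (any(drop)) {
    warning(sprintf("dropping %d pair(s) with zero-variance profiles",
                    sum(drop)))
    pairs <- pairs[!drop, , drop = FALSE]
  }
  pairs$correlated <- abs(pairs$pearson_r) > r_threshold &
    pairs$p_value < alpha
  pairs$sign <- ifelse(pairs$pearson_r >= 0, "positive", "negative")
  pairs
}
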