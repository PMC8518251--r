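# Abundance units (FPKM/TPM), detection calls, exclusive/shared set logic
# and descriptive feature contrasts between transcript classes.

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `rgc_type` (`ipRGC`/`ooDSGC`),
#'   `condition` (`normal`/`injured`) and `replicate`.
#' @return Data frame with an added `group` column (`rgc_type_condition`).
#' @export
read_sample_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(d, c("sample_id", "rgc_type", "condition", "replicate"),
                  "sample design")
  d$group <- paste(d$rgc_type, d$condition, sep = "_")
  d
}

#' Read a transcript-by-sample expression matrix
#'
#' @param path TSV with transcript ids in the first column and one column per
#'   sample.
#' @return Numeric matrix with transcript rownames.
#' @export
read_expression_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("expression matrix contains negative values")
  m
}

design_groups <- function(design, samples) {
  idx <- match(samples, design$sample_id)
  if (anyNA(idx))
    abort("sample(s) missing from design: %s",
          paste(samples[is.na(idx)], collapse = ", "))
  design$group[idx]
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM[t, s] = counts[t, s] * 1e9 / (total_counts[s] * length[t])`, with the
#' effective length taken as the mature (exonic) length in nt.
#'
#' @param counts Nonnegative count matrix (transcripts x samples).
#' @param lengths Named vector of transcript lengths in nt (> 0), covering
#'   every row of `counts`.
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths) {
  len <- lengths[rownames(counts)]
  if (anyNA(len)) abort("missing transcript length(s)")
  if (any(len <= 0)) abort("transcript lengths must be positive")
  tot <- colSums(counts)
  if (any(tot <= 0)) abort("sample(s) with zero total counts: %s",
                           paste(colnames(counts)[tot <= 0], collapse = ", "))
  sweep(counts * 1e9 / len, 2, tot, "/")
}

#' Transcripts per million
#'
#' Length-normalised rates `counts/length` are rescaled so each sample column
#' sums to 1e6. Invariant to rescaling all counts of a sample.
#'
#' @inheritParams compute_fpkm
#' @return TPM matrix; each column sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  len <- lengths[rownames(counts)]
  if (anyNA(len)) abort("missing transcript length(s)")
  if (any(len <= 0)) abort("transcript lengths must be positive")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot <= 0)) abort("sample(s) with zero total expression: %s",
                           paste(colnames(counts)[tot <= 0], collapse = ", "))
  sweep(rate, 2, tot / 1e6, "/")
}

# per-group column index list, in first-appearance order
group_columns <- function(mat, design) {
  groups <- design_groups(design, colnames(mat))
  split(seq_len(ncol(mat)), factor(groups, levels = unique(groups)))
}

#' Group-mean expression matrix
#'
#' @param mat Expression matrix (transcripts x samples).
#' @param design Sample design (see [read_sample_design()]).
#' @return Matrix of per-group replicate means (transcripts x groups).
#' @export
group_means <- function(mat, design) {
  cols <- group_columns(mat, design)
  out <- vapply(cols, function(j) rowMeans(mat[, j, drop = FALSE]),
                numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), ncol = length(cols),
         dimnames = list(rownames(mat), names(cols)))
}

#' Detection calls from FPKM
#'
#' A transcript is called detected in a group when its FPKM exceeds
#' `threshold` (strictly) in at least `min_reps` replicates of that group;
#' detected overall means detected in at least one group.
#'
#' @param fpkm FPKM matrix (transcripts x samples).
#' @param design Sample design; every group must have at least `min_reps`
#'   samples.
#' @param threshold Detection threshold (default 0.3 FPKM).
#' @param min_reps Minimum replicates above threshold (default 2).
#' @return Logical matrix (transcripts x groups) with attribute `detected`,
#'   the per-transcript any-group call.
#' @export
detect_expressed <- function(fpkm, design, threshold = 0.3, min_reps = 2) {
  cols <- group_columns(fpkm, design)
  small <- names(cols)[vapply(cols, length, 1L) < min_reps]
  if (length(small) > 0L)
    abort("group(s) with fewer than %d replicates: %s", min_reps,
          paste(small, collapse = ", "))
  calls <- vapply(cols, function(j)
    rowSums(fpkm[, j, drop = FALSE] > threshold) >= min_reps,
    logical(nrow(fpkm)))
  calls <- matrix(calls, nrow = nrow(fpkm), ncol = length(cols),
                  dimnames = list(rownames(fpkm), names(cols)))
  attr(calls, "detected") <- rowSums(calls) > 0
  calls
}

#' Transcripts detected in any of the given groups
#'
#' @param calls Detection matrix from [detect_expressed()].
#' @param groups Group names (columns of `calls`); defaults to all.
#' @return Character vector of transcript ids.
#' @export
detected_ids <- function(calls, groups = colnames(calls)) {
  bad <- setdiff(groups, colnames(calls))
  if (length(bad) > 0L) abort("unknown group(s): %s", paste(bad, collapse = ", "))
  rownames(calls)[rowSums(calls[, groups, drop = FALSE]) > 0]
}

#' Exclusive and shared sets of two id collections
#'
#' Partitions the union of two id sets into exclusive-A, shared and
#' exclusive-B, and reports integer percentages (round-half-up) of each
#' side's total that are exclusive or shared.
#'
#' @param a,b Character vectors of ids.
#' @param names Labels for the two sides (length 2).
#' @return List of class `venn_sets` with `sets`, `counts` and `pct`
#'   components.
#' @export
venn_sets <- function(a, b, names = c("A", "B")) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  shared <- intersect(a, b)
  out <- list(
    names = names,
    sets = list(exclusive_a = setdiff(a, b), shared = shared,
                exclusive_b = setdiff(b, a)),
    counts = c(exclusive_a = length(setdiff(a, b)), shared = length(shared),
               exclusive_b = length(setdiff(b, a)),
               total_a = length(a), total_b = length(b)))
  pct <- function(k, n) if (n == 0) NA_integer_ else pct_round(100 * k / n)
  out$pct <- c(exclusive_a = pct(out$counts[["exclusive_a"]], length(a)),
               exclusive_b = pct(out$counts[["exclusive_b"]], length(b)),
               shared_a = pct(length(shared), length(a)),
               shared_b = pct(length(shared), length(b)))
  class(out) <- "venn_sets"
  out
}

#' @export
print.venn_sets <- function(x, ...) {
  cat(sprintf("%s: %d (%d%% exclusive) | shared %d | %s: %d (%d%% exclusive)\n",
              x$names[1], x$counts[["total_a"]], x$pct[["exclusive_a"]],
              x$counts[["shared"]],
              x$names[2], x$counts[["total_b"]], x$pct[["exclusive_b"]]))
  invisible(x)
}

#' Per-class feature summaries and contrasts
#'
#' Summarises mature length, exon count and abundance (maximum group-mean
#' TPM) per transcript class, runs Welch two-sample t-tests between classes
#' on log2(x + 1)-transformed values, and reports each class's top quartile
#' by abundance (maximum group-mean TPM at or above the class's 75th
#' percentile, linear-interpolation rule).
#'
#' @param ann `AnnotationSet` covering the transcripts.
#' @param tpm TPM matrix.
#' @param design Sample design.
#' @param classes Named character vector: transcript_id -> class label.
#' @return List with `summary` (per class), `tests` (pairwise Welch t-tests)
#'   and `top_quartile` (ids per class).
#' @export
feature_stats <- function(ann, tpm, design, classes) {
  ids <- names(classes)
  tx <- ann$transcripts[ids, , drop = FALSE]
  gm <- group_means(tpm[ids, , drop = FALSE], design)
  max_tpm <- apply(gm, 1, max)
  df <- data.frame(transcript_id = ids, class = unname(classes),
                   mature_length = tx$mature_length, n_exons = tx$n_exons,
                   max_group_tpm = max_tpm, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(df, df$class), function(g)
    data.frame(class = g$class[1], n = nrow(g),
               mean_length = mean(g$mature_length),
               median_length = stats::median(g$mature_length),
               mean_exons = mean(g$n_exons),
               median_exons = stats::median(g$n_exons),
               mean_tpm = mean(g$max_group_tpm),
               median_tpm = stats::median(g$max_group_tpm))))
  cls <- unique(df$class)
  tests <- NULL
  if (length(cls) >= 2L) {
    pairs <- utils::combn(cls, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(p) {
      g1 <- df[df$class == p[1], ]; g2 <- df[df$class == p[2], ]
      if (nrow(g1) < 2L || nrow(g2) < 2L) {
        warning(sprintf("class with < 2 members; t-test %s vs %s omitted",
                        p[1], p[2]))
        return(NULL)
      }
      tt <- function(x, y)
        welch_p(matrix(log2(x + 1), nrow = 1), matrix(log2(y + 1), nrow = 1))
      data.frame(class_a = p[1], class_b = p[2],
                 p_length = tt(g1$mature_length, g2$mature_length),
                 p_exons = tt(g1$n_exons, g2$n_exons),
                 p_abundance = tt(g1$max_group_tpm, g2$max_group_tpm),
                 stringsAsFactors = FALSE)
    }))
  }
  top <- lapply(split(df, df$class), function(g) {
    cut <- stats::quantile(g$max_group_tpm, 0.75, type = 7)
    g$transcript_id[g$max_group_tpm >= cut]
  })
  list(summary = summ, tests = tests, top_quartile = top)
}
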