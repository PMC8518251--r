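# Fractional expression level (FEL): per-transcript fraction of cumulative
# group-mean TPM attributable to each sample group. A transcript whose
# maximum fraction exceeds 50% is called cell-type specific.

#' Compute fractional expression levels
#'
#' For each transcript, replicate TPM values are averaged per group and each
#' group mean is divided by the sum over groups, yielding fractions that sum
#' to 1. Transcripts with zero total TPM are excluded (recorded in
#' `$excluded`). FEL is invariant to rescaling a transcript's TPM by a
#' positive constant.
#'
#' @param tpm TPM matrix (transcripts x samples).
#' @param design Sample design with at least 2 groups.
#' @return Object of class `fel_profile`: `fractions` (transcripts x groups),
#'   `max_fel` (named vector) and `excluded` (ids with zero total).
#' @export
compute_fel <- function(tpm, design) {
  gm <- group_means(tpm, design)
  if (ncol(gm) < 2L) abort("FEL requires at least 2 groups")
  tot <- rowSums(gm)
  excluded <- rownames(gm)[tot == 0]
  if (length(excluded) > 0L)
    message(sprintf("compute_fel: excluding %d transcript(s) with zero total TPM",
                    length(excluded)))
  keep <- tot > 0
  fr <- gm[keep, , drop = FALSE] / tot[keep]
  structure(list(fractions = fr, max_fel = apply(fr, 1, max),
                 groups = colnames(gm), excluded = excluded),
            class = "fel_profile")
}

#' @export
print.fel_profile <- function(x, ...) {
  cat(sprintf("FEL profile: %d transcripts x %d groups (%d excluded)\n",
              nrow(x$fractions), length(x$groups), length(x$excluded)))
  invisible(x)
}

#' Call cell-type-specific transcripts from a FEL profile
#'
#' @param fel A `fel_profile` from [compute_fel()].
#' @param threshold Specificity threshold; a transcript is specific when its
#'   maximum FEL is strictly greater than this (default 0.5).
#' @return Named logical vector.
#' @export
classify_specific <- function(fel, threshold = 0.5) {
  stopifnot(inherits(fel, "fel_profile"))
  fel$max_fel > threshold
}

#' Transcripts within an expression range
#'
#' Selects transcripts whose maximum group-mean TPM lies in the closed
#' interval `[lo, hi]`; used to compare specificity of lncRNAs and mRNAs at
#' matched abundance (default 4-20 TPM).
#'
#' @param tpm TPM matrix.
#' @param design Sample design.
#' @param lo,hi Interval bounds in TPM, `lo < hi`.
#' @return Character vector of transcript ids.
#' @export
range_matched_subset <- function(tpm, design, lo = 4, hi = 20) {
  stopifnot(lo < hi)
  gm <- group_means(tpm, design)
  mx <- apply(gm, 1, max)
  rownames(gm)[mx >= lo & mx <= hi]
}

#' Chi-square contrast of specificity between two transcript classes
#'
#' Pearson chi-square test (1 df, upper tail) on a 2x2 table of class by
#' specific/non-specific counts, without continuity correction by default
#' (expected counts are large in this setting).
#'
#' @param counts 2x2 matrix of nonnegative counts; rows are classes, columns
#'   specific / not specific.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List of class `specificity_contrast`: `table`, `statistic`, `df`,
#'   `p_value`.
#' @export
specificity_contrast <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort("contrast table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(table = counts, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value),
            class = "specificity_contrast")
}

#' @export
print.specificity_contrast <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
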