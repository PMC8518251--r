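# Guilt-by-association analysis: correlate differentially expressed lncRNAs
# with differentially expressed mRNAs across the profile groups, keep
# entities with at least one strong partner (|r| above threshold),
# hierarchically cluster the retained mRNAs on their correlation vectors and
# test each cluster for term enrichment (one-sided Fisher exact, plus the
# conservative EASE variant that removes one gene from the overlap).

#' Build a thresholded lncRNA-mRNA correlation matrix
#'
#' Full Pearson correlation matrix of mRNA rows against lncRNA columns over
#' shared profile groups. lncRNAs with no partner exceeding the threshold in
#' absolute value are dropped, then mRNAs with no surviving lncRNA partner.
#' Zero-variance profiles are dropped with a warning.
#'
#' @param lnc_profiles,mrna_profiles Numeric matrices (rows = ids, columns =
#'   profile groups, same column order).
#' @param r_threshold Absolute-correlation threshold (default 0.88, strict).
#' @return Object of class `gba_matrix`: `r` (retained mRNAs x lncRNAs),
#'   `threshold`, `n_profile_groups`, `dropped` (ids failing the threshold or
#'   with zero variance).
#' @export
gba_matrix <- function(lnc_profiles, mrna_profiles, r_threshold = 0.88) {
  stopifnot(ncol(lnc_profiles) == ncol(mrna_profiles))
  drop_const <- function(m, what) {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d zero-variance %s profile(s)",
                      sum(sds == 0), what))
      m <- m[sds > 0, , drop = FALSE]
    }
    m
  }
  lnc_profiles <- drop_const(lnc_profiles, "lncRNA")
  mrna_profiles <- drop_const(mrna_profiles, "mRNA")
  r <- stats::cor(t(mrna_profiles), t(lnc_profiles))
  keep_l <- apply(abs(r) > r_threshold, 2, any)
  keep_m <- if (any(keep_l))
    apply(abs(r[, keep_l, drop = FALSE]) > r_threshold, 1, any)
  else rep(FALSE, nrow(r))
  dropped <- c(colnames(r)[!keep_l], rownames(r)[!keep_m])
  structure(list(r = r[keep_m, keep_l, drop = FALSE],
                 threshold = r_threshold,
                 n_profile_groups = ncol(lnc_profiles),
                 dropped = dropped),
            class = "gba_matrix")
}

#' @export
print.gba_matrix <- function(x, ...) {
  cat(sprintf("GBA matrix: %d mRNAs x %d lncRNAs (|r| > %.2f, %d profile groups)\n",
              nrow(x$r), ncol(x$r), x$threshold, x$n_profile_groups))
  invisible(x)
}

#' Cluster retained mRNAs on their lncRNA-correlation vectors
#'
#' Agglomerative hierarchical clustering (average linkage, Euclidean distance
#' on the rows of the correlation matrix), dendrogram cut to `k` clusters.
#' Deterministic given its inputs and stable under row permutation (up to
#' cluster relabelling).
#'
#' @param gba A `gba_matrix`.
#' @param k Number of clusters (1 <= k <= number of retained mRNAs).
#' @return Named integer vector of cluster indices in `1..k`.
#' @export
cluster_mrnas <- function(gba, k) {
  stopifnot(inherits(gba, "gba_matrix"), k >= 1)
  if (k > nrow(gba$r))
    abort("k = %d exceeds the %d retained mRNAs", k, nrow(gba$r))
  if (nrow(gba$r) == 1L) return(stats::setNames(1L, rownames(gba$r)))
  hc <- stats::hclust(stats::dist(gba$r, method = "euclidean"),
                      method = "average")
  stats::cutree(hc, k = k)
}

# one-sided Fisher upper-tail p for a 2x2 table laid out as
# (in-set & annotated, in-set & not, out & annotated, out & not)
fisher_tail <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Term enrichment of a gene cluster (Fisher and EASE)
#'
#' One-sided Fisher exact test on the 2x2 of cluster membership by term
#' annotation, against the supplied background. The EASE variant recomputes
#' the p-value after removing one gene from the cluster-and-annotated cell
#' (floored at 0), which is never smaller than the Fisher p. BH-adjusted
#' values over the tested terms are included for transparency; the enrichment
#' flag uses the raw p of the chosen variant.
#'
#' @param cluster Character vector of gene ids, a subset of `background`.
#' @param background Background gene universe.
#' @param term_table Data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`; genes without entries count as unannotated.
#' @param alpha Enrichment threshold on the raw p (default 0.05).
#' @param variant Which p-value declares enrichment: `"ease"` (default) or
#'   `"fisher"`.
#' @return Data frame sorted by the chosen p: term_id, term_name, overlap,
#'   cluster_size, annotated, background_size, p_fisher, p_ease, padj_fisher,
#'   padj_ease, enriched.
#' @export
enrich_terms <- function(cluster, background, term_table, alpha = 0.05,
                         variant = c("ease", "fisher")) {
  variant <- match.arg(variant)
  cluster <- unique(as.character(cluster))
  background <- unique(as.character(background))
  if (length(cluster) == 0L) abort("empty cluster")
  if (!all(cluster %in% background))
    abort("cluster is not a subset of the background")
  require_columns(term_table, c("gene_id", "term_id"), "term table")
  tt <- term_table[term_table$gene_id %in% background, , drop = FALSE]
  if (nrow(tt) == 0L)
    return(data.frame(term_id = character(0)))
  terms <- split(tt$gene_id, tt$term_id)
  nm <- if ("term_name" %in% names(term_table))
    vapply(split(as.character(tt$term_name), tt$term_id), `[`, character(1), 1)
  else stats::setNames(names(terms), names(terms))
  N <- length(background); n <- length(cluster)
  res <- do.call(rbind, lapply(names(terms), function(t) {
    annotated <- unique(terms[[t]])
    K <- length(annotated)
    k <- length(intersect(cluster, annotated))
    p_f <- fisher_tail(k, n - k, K - k, N - n - K + k)
    ke <- max(k - 1L, 0L)
    p_e <- fisher_tail(ke, n - k, K - k, N - n - K + k)
    data.frame(term_id = t, term_name = unname(nm[t]), overlap = k,
               cluster_size = n, annotated = K, background_size = N,
               p_fisher = p_f, p_ease = p_e, stringsAsFactors = FALSE)
  }))
  res$padj_fisher <- stats::p.adjust(res$p_fisher, "BH")
  res$padj_ease <- stats::p.adjust(res$p_ease, "BH")
  chosen <- if (variant == "ease") res$p_ease else res$p_fisher
  res$enriched <- chosen < alpha
  res[order(chosen), , drop = FALSE]
}
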