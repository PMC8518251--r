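#' Construct a genomic interval
#'
#' Coordinates are given 0-based, half-open (`[start, end)`), the convention
#' used internally for all length and distance arithmetic; on-disk GTF
#' coordinates (1-based, inclusive) are converted on read/write.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start (inclusive).
#' @param end End (exclusive); must satisfy `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` (unstranded).
#' @return A [GenomicRanges::GRanges] of the same length as the inputs.
#' @export
#' @examples
#' genomic_interval("chr1", 100, 200)
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (any(start < 0) || any(start >= end))
    abort("invalid interval: require 0 <= start < end")
  strand <- ifelse(strand == ".", "*", strand)
  if (!all(strand %in% c("+", "-", "*")))
    abort("strand must be one of '+', '-', '.'")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

#' Distance between two genomic intervals
#'
#' Returns 0 when the intervals overlap or abut, the size of the gap between
#' nearest ends otherwise, and `Inf` for intervals on different chromosomes.
#' Strand is ignored. The function is symmetric and vectorised pairwise.
#'
#' @param a,b [GenomicRanges::GRanges] objects of equal length (or length 1,
#'   recycled).
#' @return Numeric vector of distances in bp.
#' @export
genomic_distance <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  d <- suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
  out <- as.numeric(d)
  out[is.na(out)] <- Inf
  out
}

# ---- GTF parsing ------------------------------------------------------------

# line-level validation so parse failures carry a line number
validate_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L)
      abort("malformed GTF line %d: expected 9 tab-separated fields, found %d",
            i, length(fields))
    start <- suppressWarnings(as.numeric(fields[4]))
    end <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(start) || is.na(end))
      abort("malformed GTF line %d: non-numeric coordinates", i)
    if (end < start)
      abort("invalid GTF line %d: end (%s) < start (%s)", i, fields[5], fields[4])
    if (fields[3] == "exon" && !grepl("transcript_id", fields[9], fixed = TRUE))
      abort("invalid GTF line %d: exon feature lacks transcript_id", i)
  }
  invisible(TRUE)
}

normalize_biotype <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  out[x == "protein_coding"] <- "protein_coding"
  out[x %in% c("lincRNA", "lncRNA")] <- "lincRNA"
  out[x %in% c("antisense", "antisense_RNA")] <- "antisense"
  out[x == "novel_lincRNA"] <- "novel_lincRNA"
  out[is.na(x)] <- "other"
  out
}

#' Read a GTF annotation into an `AnnotationSet`
#'
#' Parses a GENCODE/Ensembl-dialect GTF (1-based inclusive coordinates,
#' `key "value";` attributes). Exons are grouped per transcript and sorted by
#' start; gene spans are synthesised as the union of member transcript spans
#' when the file carries no gene features. Internally all coordinates are
#' 0-based half-open (reported in [transcript_table()]).
#'
#' @param path Path to a GTF file.
#' @param source Provenance label, `"reference"` or `"assembled"`.
#' @return An object of class `AnnotationSet` with components
#'   `transcripts` (data frame: transcript_id, gene_id, chrom, strand,
#'   biotype, source, n_exons, mature_length, start, end), `exons`
#'   (a [GenomicRanges::GRangesList] named by transcript), `genes`
#'   (gene-span [GenomicRanges::GRanges] named by gene_id with a `biotype`
#'   column) and `tx_spans` (transcript-span `GRanges`).
#' @export
read_gtf <- function(path, source = c("reference", "assembled")) {
  source <- match.arg(source)
  if (!file.exists(path)) abort("GTF file not found: %s", path)
  validate_gtf(path)
  gr <- rtracklayer::import(path, format = "gtf")

  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) abort("GTF contains no exon features: %s", path)
  if (any(is.na(ex$transcript_id)))
    abort("exon feature without transcript_id in %s", path)
  bt <- ex$transcript_biotype %||% ex$gene_biotype %||%
    ex$transcript_type %||% ex$gene_type %||% rep(NA_character_, length(ex))

  df <- data.frame(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id %||% ex$transcript_id),
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    strand = as.character(BiocGenerics::strand(ex)),
    start = BiocGenerics::start(ex),
    end = BiocGenerics::end(ex),
    biotype = normalize_biotype(bt),
    stringsAsFactors = FALSE
  )
  # gene spans: explicit gene features if present, else synthesised later
  gf <- gr[gr$type == "gene"]
  genes <- NULL
  if (length(gf) > 0L && !any(is.na(gf$gene_id))) {
    gbt <- gf$gene_biotype %||% gf$gene_type %||% rep(NA_character_, length(gf))
    genes <- GenomicRanges::granges(gf)
    names(genes) <- as.character(gf$gene_id)
    genes$gene_id <- names(genes)
    genes$biotype <- normalize_biotype(gbt)
  }
  build_annotation_set(df, source, genes)
}

# Assemble an AnnotationSet from an exon table (1-based inclusive coords,
# columns transcript_id, gene_id, chrom, strand, start, end, biotype).
# Gene spans are synthesised as the union of member transcripts unless an
# explicit gene-span GRanges is supplied.
build_annotation_set <- function(df, source, genes = NULL) {
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]

  # per-transcript consistency checks
  by_tx <- split(df, df$transcript_id)
  for (tx in by_tx) {
    if (length(unique(tx$chrom)) != 1L || length(unique(tx$strand)) != 1L)
      abort("transcript %s has exons on multiple chromosomes or strands",
            tx$transcript_id[1])
    if (nrow(tx) > 1L && any(tx$start[-1] <= tx$end[-nrow(tx)]))
      abort("transcript %s has overlapping exons", tx$transcript_id[1])
  }

  tx_tab <- do.call(rbind, lapply(by_tx, function(tx) {
    data.frame(
      transcript_id = tx$transcript_id[1], gene_id = tx$gene_id[1],
      chrom = tx$chrom[1], strand = tx$strand[1], biotype = tx$biotype[1],
      source = source, n_exons = nrow(tx),
      mature_length = sum(tx$end - tx$start + 1L),
      start = min(tx$start) - 1L,   # 0-based half-open span
      end = max(tx$end),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tx_tab) <- tx_tab$transcript_id

  exons <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand)
  exons <- S4Vectors::split(exons, df$transcript_id)

  tx_spans <- GenomicRanges::GRanges(
    tx_tab$chrom, IRanges::IRanges(tx_tab$start + 1L, tx_tab$end),
    strand = tx_tab$strand)
  names(tx_spans) <- tx_tab$transcript_id

  if (is.null(genes)) {
    gsplit <- split(seq_len(nrow(tx_tab)), tx_tab$gene_id)
    gdat <- lapply(gsplit, function(idx) {
      data.frame(gene_id = tx_tab$gene_id[idx[1]], chrom = tx_tab$chrom[idx[1]],
                 start = min(tx_tab$start[idx]), end = max(tx_tab$end[idx]),
                 strand = tx_tab$strand[idx[1]],
                 biotype = tx_tab$biotype[idx[1]], stringsAsFactors = FALSE)
    })
    gdat <- do.call(rbind, gdat)
    genes <- GenomicRanges::GRanges(
      gdat$chrom, IRanges::IRanges(gdat$start + 1L, gdat$end),
      strand = gdat$strand)
    names(genes) <- gdat$gene_id
    genes$gene_id <- gdat$gene_id
    genes$biotype <- gdat$biotype
  }

  structure(list(transcripts = tx_tab, exons = exons, genes = genes,
                 tx_spans = tx_spans),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d transcripts, %d genes\n",
              nrow(x$transcripts), length(x$genes)))
  print(table(x$transcripts$biotype))
  invisible(x)
}

#' Transcript summary table of an `AnnotationSet`
#'
#' @param ann An `AnnotationSet`.
#' @return Data frame with one row per transcript; `start`/`end` are the
#'   0-based half-open span, `mature_length` the summed exon length in nt.
#' @export
transcript_table <- function(ann) {
  stopifnot(inherits(ann, "AnnotationSet"))
  ann$transcripts
}

#' Gene spans of an `AnnotationSet`
#'
#' @param ann An `AnnotationSet`.
#' @return [GenomicRanges::GRanges] named by gene_id with a `biotype` column.
#' @export
gene_ranges <- function(ann) {
  stopifnot(inherits(ann, "AnnotationSet"))
  ann$genes
}

#' Subset an `AnnotationSet` to a set of transcripts
#'
#' Gene spans are re-synthesised from the remaining transcripts.
#'
#' @param ann An `AnnotationSet`.
#' @param transcript_ids Transcript identifiers to retain.
#' @return An `AnnotationSet`.
#' @export
subset_annotation <- function(ann, transcript_ids) {
  stopifnot(inherits(ann, "AnnotationSet"))
  missing <- setdiff(transcript_ids, ann$transcripts$transcript_id)
  if (length(missing) > 0L)
    abort("unknown transcript id(s): %s", paste(missing, collapse = ", "))
  keep <- ann$transcripts$transcript_id %in% transcript_ids
  tx <- ann$transcripts[keep, , drop = FALSE]
  gkeep <- names(ann$genes) %in% tx$gene_id
  structure(list(transcripts = tx,
                 exons = ann$exons[tx$transcript_id],
                 genes = ann$genes[gkeep],
                 tx_spans = ann$tx_spans[tx$transcript_id]),
            class = "AnnotationSet")
}

#' Write an `AnnotationSet` to GTF
#'
#' Emits exon features in the Ensembl/GENCODE attribute dialect; coordinates
#' are converted back to 1-based inclusive. Reading the file back yields
#' identical transcript spans, exon counts and mature lengths.
#'
#' @param ann An `AnnotationSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationSet"))
  tx <- ann$transcripts
  ex <- unlist(ann$exons, use.names = FALSE)
  n_per <- S4Vectors::elementNROWS(ann$exons)
  tx_id <- rep(names(ann$exons), n_per)
  idx <- match(tx_id, tx$transcript_id)
  ex$type <- "exon"
  ex$gene_id <- tx$gene_id[idx]
  ex$transcript_id <- tx_id
  ex$gene_biotype <- tx$biotype[idx]
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' Classify a transcript span relative to a reference annotation
#'
#' A span overlapping at least one reference gene on the same strand is
#' `sense_overlap` (same-strand overlap takes precedence); a span overlapping
#' a protein-coding reference gene only on the opposite strand is
#' `antisense_overlap`; anything else is `intergenic`. Overlap requires at
#' least one shared base; unstranded reference genes match both strands.
#'
#' @param x Transcript spans as a [GenomicRanges::GRanges] (stranded).
#' @param ref Reference `AnnotationSet`.
#' @return Character vector, one of `intergenic`, `sense_overlap`,
#'   `antisense_overlap` per element of `x`.
#' @export
relation_to_reference <- function(x, ref) {
  stopifnot(inherits(ref, "AnnotationSet"))
  genes <- ref$genes
  out <- rep("intergenic", length(x))
  if (length(genes) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(x, genes, ignore.strand = TRUE,
                                      minoverlap = 1L)
  if (length(hits) == 0L) return(out)
  qs <- as.character(BiocGenerics::strand(x))[S4Vectors::queryHits(hits)]
  ss <- as.character(BiocGenerics::strand(genes))[S4Vectors::subjectHits(hits)]
  same <- ss == "*" | ss == qs
  pc <- genes$biotype[S4Vectors::subjectHits(hits)] == "protein_coding"
  q <- S4Vectors::queryHits(hits)
  sense_q <- unique(q[same])
  anti_q <- unique(q[!same & pc])
  out[anti_q] <- "antisense_overlap"
  out[sense_q] <- "sense_overlap"
  out
}
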