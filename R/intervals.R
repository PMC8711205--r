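# Interval algebra. Genomic intervals are plain data.frames in BED
# convention: 0-based half-open [start, end), optional strand in {+, -, *}.
# Bulk overlap queries go through GenomicRanges; conversion adds 1 to start.

#' Construct a genomic interval table
#'
#' Validates and assembles a data.frame of genomic intervals in 0-based
#' half-open (BED) coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-like vector, 0-based inclusive start (>= 0).
#' @param end Integer-like vector, 0-based exclusive end (> start).
#' @param strand Optional character vector in `{+, -, *}`.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   supplied, `strand`.
#' @examples
#' genomic_intervals("chr1", c(0, 500), c(100, 900))
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("intervals must satisfy start < end")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (length(strand) == 1L) strand <- rep(strand, n)
    if (!all(strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
    out$strand <- strand
  }
  out
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df) {
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# GRanges -> data.frame in BED convention
granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Overlap length between two intervals
#'
#' Number of bases shared by two intervals; 0 when the chromosomes differ
#' or the intervals are disjoint. Vectorised over rows (recycled).
#'
#' @param a,b Interval data.frames (`chrom`, `start`, `end`).
#' @return Non-negative numeric vector of shared base pairs.
#' @examples
#' a <- genomic_intervals("chr1", 100, 500)
#' b <- genomic_intervals("chr1", 300, 900)
#' overlap_length(a, b)  # 200
#' @export
overlap_length <- function(a, b) {
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(a$chrom == b$chrom, ov, 0)
}

# TSS of each gene: first transcribed base. + strand: body start;
# - strand: last base of the body (end - 1).
gene_tss <- function(genes) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene models must be stranded ('+' or '-')")
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Strand-aware window around transcription start sites
#'
#' For each gene, the interval spanning `up` bp upstream and `down` bp
#' downstream of its TSS in the direction of transcription, clipped at the
#' chromosome origin. On the plus strand the window is
#' `[tss - up, tss + down)`; on the minus strand `[tss - down + 1, tss + up + 1)`
#' so that window length is `up + down` on both strands.
#'
#' @param genes Gene table: `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @param up,down Non-negative window extents in bp (`up + down > 0`).
#' @return Interval data.frame with a `gene_id` column.
#' @examples
#' g <- data.frame(chrom = "chr1", start = 10000, end = 20000,
#'                 strand = "+", gene_id = "g1")
#' tss_window(g)  # [5000, 13000)
#' @export
tss_window <- function(genes, up = 5000, down = 3000) {
  if (up < 0 || down < 0) stop("window extents must be non-negative")
  if (up + down <= 0) stop("degenerate window: up + down must be > 0")
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  ws <- ifelse(plus, tss - up, tss - down + 1)
  we <- ifelse(plus, tss + down, tss + up + 1)
  out <- data.frame(chrom = genes$chrom, start = pmax(0, ws), end = we,
                    stringsAsFactors = FALSE)
  if (!is.null(genes$gene_id)) out$gene_id <- genes$gene_id
  out
}

#' Genebody interval extended by a symmetric flank
#'
#' `[start - flank, end + flank)`, clipped at 0; strand-independent.
#'
#' @param genes Gene table (`chrom`, `start`, `end`, optionally `gene_id`).
#' @param flank Non-negative flank size in bp (default 10000).
#' @return Interval data.frame with `gene_id` when present in the input.
#' @export
genebody_flank <- function(genes, flank = 10000) {
  if (flank < 0) stop("flank must be non-negative")
  out <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$start - flank),
                    end = genes$end + flank,
                    stringsAsFactors = FALSE)
  if (!is.null(genes$gene_id)) out$gene_id <- genes$gene_id
  out
}

#' Test a query interval against a target set
#'
#' Reports whether any target shares at least `min_bp` bases with the
#' query, together with the qualifying targets sorted by coordinate.
#'
#' @param query A single-row interval data.frame.
#' @param targets Interval data.frame.
#' @param min_bp Minimum shared bases (>= 1).
#' @return A list with elements `any` (logical) and `hits` (data.frame of
#'   qualifying target rows sorted by chrom, start).
#' @export
any_overlap <- function(query, targets, min_bp = 1) {
  if (nrow(query) != 1L) stop("query must be a single interval")
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (nrow(targets) == 0L)
    return(list(any = FALSE, hits = targets))
  ov <- overlap_length(query[rep(1L, nrow(targets)), , drop = FALSE], targets)
  hits <- targets[ov >= min_bp, , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  list(any = nrow(hits) > 0L, hits = hits)
}
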