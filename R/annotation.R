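# Peak-to-feature annotation: nearest-gene assignment within a genebody
# flank, promoter/genebody/intergenic classification, and
# transposable-element overlap proportions.

#' Assign peaks to genes and genomic features
#'
#' A peak overlapping (>= 1 bp) the `flank`-extended body of a gene is
#' assigned to that gene; when several genes qualify the one with the
#' largest overlap wins, ties going to the smallest gene start. The
#' feature is `promoter` if the peak also overlaps the assigned gene's TSS
#' window (`tss_up`/`tss_down`, strand-aware; promoter takes precedence),
#' otherwise `genebody`. Peaks hitting no flanked gene are `intergenic`
#' with no gene id.
#'
#' @param peaks Interval data.frame (e.g. a [peak_set()]).
#' @param genes Gene table (`chrom`, `start`, `end`, `strand`, `gene_id`).
#' @param flank Genebody flank in bp (default 10000).
#' @param tss_up,tss_down Promoter window extents in bp (defaults
#'   5000/3000).
#' @return Data.frame: peak columns plus `gene_id` (NA when intergenic)
#'   and `feature` in `{promoter, genebody, intergenic}`.
#' @export
assign_genes <- function(peaks, genes, flank = 10000,
                         tss_up = 5000, tss_down = 3000) {
  peaks <- as.data.frame(peaks)
  out <- peaks
  out$gene_id <- NA_character_
  out$feature <- "intergenic"
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(out)
  flanked <- genebody_flank(genes, flank)
  hits <- IRanges::findOverlaps(as_granges(peaks), as_granges(flanked))
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ovlen <- pmin(peaks$end[q], flanked$end[s]) -
    pmax(peaks$start[q], flanked$start[s])
  # per peak: largest overlap, ties by smallest gene start
  ord <- order(q, -ovlen, genes$start[s])
  first <- !duplicated(q[ord])
  pk <- q[ord][first]
  gn <- s[ord][first]
  out$gene_id[pk] <- genes$gene_id[gn]
  win <- tss_window(genes, tss_up, tss_down)
  in_promoter <- overlap_length(peaks[pk, , drop = FALSE],
                                win[gn, , drop = FALSE]) >= 1
  out$feature[pk] <- ifelse(in_promoter, "promoter", "genebody")
  out
}

#' Proportion of peaks per genomic feature
#'
#' @param assignments Output of [assign_genes()] (non-empty).
#' @return Named numeric vector of proportions over
#'   `{promoter, genebody, intergenic}`; sums to 1.
#' @export
feature_fractions <- function(assignments) {
  if (nrow(assignments) == 0L)
    stop("feature_fractions requires a non-empty assignment list")
  tab <- table(factor(assignments$feature,
                      c("promoter", "genebody", "intergenic")))
  prop <- as.numeric(tab) / nrow(assignments)
  names(prop) <- names(tab)
  prop
}

#' Transposable-element overlap proportions of differential peaks
#'
#' For each differential direction and TE class, the percentage of
#' direction-`d` peaks overlapping at least one TE of that class. A peak
#' overlapping TEs of two classes counts once in each class, so
#' percentages within a direction may sum above 100. The denominator is,
#' by default, the number of direction-`d` peaks overlapping any TE
#' (`"te_overlapped"`); `"all_differential"` divides by all direction-`d`
#' peaks instead. Directions with a zero denominator are omitted.
#'
#' @param diff A `diff_regions` data.frame; only rows with direction
#'   `gained-open` or `gained-closed` are used.
#' @param tes TE table (`chrom`, `start`, `end`, `te_class`).
#' @param denominator `"te_overlapped"` (default) or `"all_differential"`.
#' @return Data.frame with columns `direction`, `te_class`, `percentage`.
#' @export
te_overlap_proportions <- function(diff, tes,
                                   denominator = c("te_overlapped",
                                                   "all_differential")) {
  denominator <- match.arg(denominator)
  empty <- data.frame(direction = character(0), te_class = character(0),
                      percentage = numeric(0))
  diff <- as.data.frame(diff)
  diff <- diff[diff$direction %in% c("gained-open", "gained-closed"), ,
               drop = FALSE]
  if (nrow(diff) == 0L || nrow(tes) == 0L) return(empty)
  hits <- IRanges::findOverlaps(as_granges(diff), as_granges(tes))
  rows <- lapply(c("gained-open", "gained-closed"), function(d) {
    in_d <- which(diff$direction == d)
    h <- hits[S4Vectors::queryHits(hits) %in% in_d]
    te_ov_peaks <- unique(S4Vectors::queryHits(h))
    denom <- if (denominator == "te_overlapped") length(te_ov_peaks)
             else length(in_d)
    if (denom == 0L || length(te_ov_peaks) == 0L) return(NULL)
    per_class <- tapply(S4Vectors::queryHits(h),
                        tes$te_class[S4Vectors::subjectHits(h)],
                        function(p) length(unique(p)))
    data.frame(direction = d, te_class = names(per_class),
               percentage = 100 * as.numeric(per_class) / denom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
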