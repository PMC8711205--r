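# SEACR-style sparse-enrichment peak calling from bedGraph coverage, plus
# the post-processing used for CUT&RUN: half-mean signal filtering,
# replicate consensus and condition-unique peak extraction.

#' Construct a peak set
#'
#' A `peak_set` is a data.frame of non-overlapping signal blocks
#' (`chrom`, `start`, `end`, `auc`, `max_value`) sorted by coordinate,
#' carrying `condition` and `replicate` labels as attributes.
#'
#' @param blocks Data.frame with columns `chrom`, `start`, `end`, `auc`,
#'   `max_value`.
#' @param condition Condition label.
#' @param replicate Replicate label, or `"consensus"`.
#' @return A `peak_set` object.
#' @export
peak_set <- function(blocks, condition = NA_character_,
                     replicate = NA_character_) {
  need <- c("chrom", "start", "end", "auc", "max_value")
  missing <- setdiff(need, names(blocks))
  if (length(missing))
    stop("peak_set is missing columns: ", paste(missing, collapse = ", "))
  blocks <- blocks[order(blocks$chrom, blocks$start), need, drop = FALSE]
  rownames(blocks) <- NULL
  structure(blocks, class = c("peak_set", "data.frame"),
            condition = condition, replicate = replicate)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks (condition=%s, replicate=%s)\n",
              nrow(x), attr(x, "condition"), attr(x, "replicate")))
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("...\n")
  }
  invisible(x)
}

#' Filter paired-end fragments by length
#'
#' Retains fragments strictly shorter than `max_fragment_length` (the
#' standard CUT&RUN input filter); input order is preserved. Fragments are
#' intervals, so cross-chromosome pairs are assumed already excluded
#' upstream.
#'
#' @param fragments Interval data.frame of fragment spans.
#' @param max_fragment_length Length cutoff in bp (default 1000);
#'   fragments with `end - start < max_fragment_length` are kept.
#' @return The retained fragments.
#' @export
filter_fragments <- function(fragments, max_fragment_length = 1000) {
  if (max_fragment_length <= 0) stop("max_fragment_length must be > 0")
  keep <- (fragments$end - fragments$start) < max_fragment_length
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment a bedGraph track into maximal signal blocks
#'
#' A signal block is a maximal run of strictly positive coverage:
#' adjacent positive records that abut exactly are merged; zero-valued or
#' absent stretches separate blocks. Each block carries its total signal
#' (`auc` = sum of value x segment length, in signal·bp) and `max_value`.
#'
#' @param track bedGraph data.frame (`chrom`, `start`, `end`, `value`),
#'   sorted by (chrom, start) and non-overlapping within a chromosome.
#' @return Data.frame of blocks: `chrom`, `start`, `end`, `auc`,
#'   `max_value`, sorted by coordinate.
#' @export
segment_signal_blocks <- function(track) {
  if (nrow(track) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), auc = numeric(0),
                      max_value = numeric(0)))
  if (any(track$end <= track$start))
    stop("bedGraph format error: records must have start < end")
  out <- lapply(split(track, track$chrom), function(tr) {
    if (is.unsorted(tr$start, strictly = TRUE))
      stop("bedGraph format error: records must be sorted by start")
    if (any(tr$start[-1L] < tr$end[-nrow(tr)]))
      stop("bedGraph format error: overlapping records")
    pos <- tr[tr$value > 0, , drop = FALSE]
    if (nrow(pos) == 0L) return(NULL)
    # new block wherever a positive record does not abut the previous one
    brk <- c(TRUE, pos$start[-1L] != pos$end[-nrow(pos)])
    grp <- cumsum(brk)
    data.frame(
      chrom = pos$chrom[1L],
      start = tapply(pos$start, grp, min),
      end = tapply(pos$end, grp, max),
      auc = tapply(pos$value * (pos$end - pos$start), grp, sum),
      max_value = tapply(pos$value, grp, max),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), auc = numeric(0),
                      max_value = numeric(0)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call peaks from signal blocks (SEACR-style stringent threshold)
#'
#' Retains the top `ceiling(threshold * N)` blocks ranked by total signal
#' (auc, descending); ties are broken by coordinate. This mirrors the
#' stringent numeric-threshold mode of sparse-enrichment peak calling,
#' where `threshold` is the fraction of blocks reported.
#'
#' @param blocks Signal blocks from [segment_signal_blocks()].
#' @param threshold Fraction of blocks to keep, in (0, 1); default 0.05.
#' @param mode Only `"stringent"` is implemented.
#' @param condition,replicate Labels attached to the returned set.
#' @return A [peak_set()].
#' @export
call_peaks <- function(blocks, threshold = 0.05, mode = "stringent",
                       condition = NA_character_,
                       replicate = NA_character_) {
  mode <- match.arg(mode, "stringent")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  n <- nrow(blocks)
  if (n == 0L)
    return(peak_set(blocks, condition, replicate))
  n_keep <- ceiling(threshold * n)
  ord <- order(-blocks$auc, blocks$chrom, blocks$start)
  kept <- blocks[ord[seq_len(n_keep)], , drop = FALSE]
  peak_set(kept, condition, replicate)
}

#' Remove peaks below half the mean peak signal
#'
#' Drops peaks whose total signal (auc) is below half the mean auc of the
#' input set; the mean is computed once, over the full set, before any
#' removal (a single normalisation pass, not iterated to a fixed point).
#'
#' @param peaks A [peak_set()].
#' @return The filtered `peak_set`.
#' @export
half_mean_filter <- function(peaks) {
  if (nrow(peaks) == 0L) return(peaks)
  cutoff <- mean(peaks$auc) / 2
  peak_set(as.data.frame(peaks)[peaks$auc >= cutoff, , drop = FALSE],
           attr(peaks, "condition"), attr(peaks, "replicate"))
}

#' Consensus peaks across two replicates
#'
#' Every pair of peaks (one per replicate) sharing at least `min_overlap`
#' bases contributes the union span of the pair; chained overlapping pairs
#' are merged into a single consensus region. The consensus auc is the sum
#' of the distinct contributing peaks' aucs and the consensus max_value
#' their maximum.
#'
#' @param rep1,rep2 [peak_set()]s from two replicates of one condition.
#' @param min_overlap Minimum shared bases for a qualifying pair
#'   (default 300).
#' @return A consensus [peak_set()] (replicate label `"consensus"`).
#' @export
replicate_consensus <- function(rep1, rep2, min_overlap = 300) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  cond <- attr(rep1, "condition")
  empty <- peak_set(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), auc = numeric(0),
                               max_value = numeric(0)), cond, "consensus")
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) return(empty)
  g1 <- as_granges(rep1)
  g2 <- as_granges(rep2)
  hits <- IRanges::findOverlaps(g1, g2, minoverlap = min_overlap)
  if (length(hits) == 0L) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  spans <- GenomicRanges::GRanges(
    rep1$chrom[q],
    IRanges::IRanges(start = pmin(rep1$start[q], rep2$start[s]) + 1,
                     end = pmax(rep1$end[q], rep2$end[s])))
  merged <- GenomicRanges::reduce(spans, min.gapwidth = 0L)
  # map each pair span to its merged region; spans lie within one region
  region_of <- S4Vectors::subjectHits(IRanges::findOverlaps(spans, merged,
                                                            select = "all",
                                                            type = "within"))
  contrib <- unique(data.frame(
    region = rep(region_of, 2L),
    rep = rep(c(1L, 2L), each = length(q)),
    peak = c(q, s)))
  auc1 <- rep1$auc
  auc2 <- rep2$auc
  mx1 <- rep1$max_value
  mx2 <- rep2$max_value
  contrib$auc <- ifelse(contrib$rep == 1L, auc1[contrib$peak],
                        auc2[contrib$peak])
  contrib$mx <- ifelse(contrib$rep == 1L, mx1[contrib$peak],
                       mx2[contrib$peak])
  agg_auc <- tapply(contrib$auc, contrib$region, sum)
  agg_mx <- tapply(contrib$mx, contrib$region, max)
  out <- granges_to_df(merged)
  out$auc <- as.numeric(agg_auc[as.character(seq_along(merged))])
  out$max_value <- as.numeric(agg_mx[as.character(seq_along(merged))])
  peak_set(out, cond, "consensus")
}

#' Peaks unique to one condition
#'
#' Returns the peaks of `consA` that share no base with any peak of
#' `consB` (zero-overlap uniqueness: a single shared base disqualifies).
#'
#' @param consA,consB Consensus [peak_set()]s from the two conditions.
#' @return The condition-A-unique `peak_set` (replicate label `"unique"`).
#' @export
condition_unique <- function(consA, consB) {
  if (nrow(consA) == 0L || nrow(consB) == 0L) {
    out <- as.data.frame(consA)
  } else {
    n_ov <- IRanges::countOverlaps(as_granges(consA), as_granges(consB))
    out <- as.data.frame(consA)[n_ov == 0L, , drop = FALSE]
  }
  peak_set(out, attr(consA, "condition"), "unique")
}
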