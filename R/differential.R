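# Count-based differential chromatin accessibility over ATAC regions.
# The per-region test is an exact binomial test on counts pooled within
# condition, with the success probability set by the library-size split,
# classified with the study's significance and fold-change thresholds.

#' Construct an ATAC region count table
#'
#' @param regions Interval data.frame (one row per region).
#' @param samples Sample sheet data.frame: `sample`, `condition`,
#'   `replicate`, `library_size` (total mapped fragments).
#' @param counts Integer matrix, regions x samples, column order matching
#'   `samples$sample`.
#' @return A `region_counts` object.
#' @export
region_counts <- function(regions, samples, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(regions))
    stop("counts must have one row per region")
  if (ncol(counts) != nrow(samples))
    stop("counts must have one column per sample")
  if (any(counts < 0) || any(!is.finite(counts)) ||
      any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  if (any(samples$library_size <= 0))
    stop("library sizes must be positive")
  if (any(colSums(counts) > samples$library_size))
    stop("per-sample column sums exceed the stated library size")
  colnames(counts) <- samples$sample
  structure(list(regions = regions, samples = samples, counts = counts),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("region_counts: %d regions x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = " vs ")))
  invisible(x)
}

#' Counts per million
#'
#' Library-size normalisation: `cpm[r, s] = counts[r, s] * 1e6 /
#' library_size[s]`.
#'
#' @param table A [region_counts()] object.
#' @return Numeric matrix of CPM values.
#' @export
normalize_counts <- function(table) {
  ls <- table$samples$library_size
  if (any(ls <= 0)) stop("library sizes must be positive")
  sweep(table$counts, 2L, ls / 1e6, "/")
}

#' Default differential thresholds
#'
#' The study's decision rule: two-sided p below `p_threshold` and linear
#' fold change above `fc_threshold` (or below its reciprocal), restricted
#' to windows `tss_up` bp upstream to `tss_down` bp downstream of TSSs.
#'
#' @param p_threshold Significance level in (0, 1); default 0.001.
#' @param fc_threshold Linear fold-change cutoff > 1; default 4.
#' @param tss_up,tss_down TSS window extents in bp (defaults 5000/3000).
#' @return A list of thresholds.
#' @export
differential_thresholds <- function(p_threshold = 0.001, fc_threshold = 4,
                                    tss_up = 5000, tss_down = 3000) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0, 1)")
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  list(p_threshold = p_threshold, fc_threshold = fc_threshold,
       tss_up = tss_up, tss_down = tss_down)
}

#' Exact per-region differential test
#'
#' For each region, the treated-vs-control evidence is summarised by an
#' exact two-sided binomial test of `k` = summed treated counts out of
#' `n` = summed counts across both conditions, with success probability
#' `pi` = summed treated library size / summed library size. Two-sided
#' p-values use the minimum-likelihood convention (sum of probabilities of
#' all outcomes no more likely than the observed one). The fold change is
#' the ratio of pseudocounted mean CPMs, `(mean treated cpm + c) /
#' (mean control cpm + c)` with `c = 0.5` cpm.
#'
#' Regions with `n = 0` are flagged untested (`p = 1`, `log2fc = 0`).
#'
#' @param table A [region_counts()] object.
#' @param treated,control Condition labels in `table$samples$condition`.
#' @param pseudocount Pseudocount in cpm units (default 0.5).
#' @return Data.frame with columns `log2fc`, `p_value`, `untested`.
#' @export
exact_region_test <- function(table, treated = "treated",
                              control = "control", pseudocount = 0.5) {
  st <- table$samples$condition == treated
  sc <- table$samples$condition == control
  if (!any(st) || !any(sc))
    stop("need at least one replicate per condition")
  cpm <- normalize_counts(table)
  mt <- rowMeans(cpm[, st, drop = FALSE])
  mc <- rowMeans(cpm[, sc, drop = FALSE])
  fc <- (mt + pseudocount) / (mc + pseudocount)
  kt <- rowSums(table$counts[, st, drop = FALSE])
  kc <- rowSums(table$counts[, sc, drop = FALSE])
  n <- kt + kc
  pi_t <- sum(table$samples$library_size[st]) /
    sum(table$samples$library_size[c(which(st), which(sc))])
  p <- vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(kt[i], n[i], p = pi_t)$p.value
  }, numeric(1))
  untested <- n == 0
  data.frame(log2fc = ifelse(untested, 0, log2(fc)),
             p_value = p, untested = untested)
}

#' Classify regions as gained-open, gained-closed or unchanged
#'
#' `gained-open` when `p < p_threshold` and fold change `> fc_threshold`;
#' `gained-closed` when `p < p_threshold` and fold change
#' `< 1/fc_threshold`; otherwise `unchanged`. A Benjamini-Hochberg FDR
#' column is reported for reference but plays no part in classification.
#'
#' @param regions Interval data.frame of the tested regions.
#' @param test Result of [exact_region_test()] for the same regions.
#' @param thresholds A [differential_thresholds()] list.
#' @return A `diff_regions` data.frame: region columns plus `log2fc`,
#'   `p_value`, `fdr`, `direction`.
#' @export
classify_differential <- function(regions, test,
                                  thresholds = differential_thresholds()) {
  fc <- 2^test$log2fc
  sig <- test$p_value < thresholds$p_threshold & !test$untested
  direction <- ifelse(sig & fc > thresholds$fc_threshold, "gained-open",
               ifelse(sig & fc < 1 / thresholds$fc_threshold,
                      "gained-closed", "unchanged"))
  out <- data.frame(regions, log2fc = test$log2fc, p_value = test$p_value,
                    fdr = stats::p.adjust(test$p_value, method = "BH"),
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("diff_regions", "data.frame")
  out
}

#' @export
print.diff_regions <- function(x, ...) {
  tab <- table(factor(x$direction,
                      c("gained-open", "gained-closed", "unchanged")))
  cat(sprintf("diff_regions: %d regions (%d gained-open, %d gained-closed, %d unchanged)\n",
              nrow(x), tab[["gained-open"]], tab[["gained-closed"]],
              tab[["unchanged"]]))
  invisible(x)
}

#' Restrict differential regions to TSS windows
#'
#' Keeps regions overlapping (by at least 1 bp) some gene's TSS window
#' (`tss_up` upstream to `tss_down` downstream, strand-aware). A region
#' overlapping several windows yields one record per gene.
#'
#' @param diff A `diff_regions` data.frame (or any interval data.frame).
#' @param genes Gene table (`chrom`, `start`, `end`, `strand`, `gene_id`).
#' @param thresholds A [differential_thresholds()] list supplying the
#'   window extents.
#' @return Data.frame of region records with an added `gene_id` column.
#' @export
restrict_to_tss <- function(diff, genes,
                            thresholds = differential_thresholds()) {
  out0 <- cbind(as.data.frame(diff)[0, , drop = FALSE],
                gene_id = character(0))
  if (nrow(diff) == 0L || nrow(genes) == 0L) return(out0)
  win <- tss_window(genes, thresholds$tss_up, thresholds$tss_down)
  hits <- IRanges::findOverlaps(as_granges(diff), as_granges(win))
  if (length(hits) == 0L) return(out0)
  out <- as.data.frame(diff)[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- genes$gene_id[S4Vectors::subjectHits(hits)]
  rownames(out) <- NULL
  out
}
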