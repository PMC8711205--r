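# Joint classification of gene TSSs by ATAC accessibility change and
# H3K56ac CUT&RUN evidence. Categories follow the study's enumeration:
#   I   gain accessibility & gain H3K56ac
#   II  lose accessibility & lose H3K56ac
#   III lose accessibility & gain H3K56ac
#   IV  gain accessibility & lose H3K56ac (the remaining quadrant,
#       reported for losslessness and flagged via the category label)
# Genes lacking either line of evidence are 'uncalled'.

CATEGORY_LEVELS <- c("I", "II", "III", "IV", "uncalled")

#' Integrate ATAC and H3K56ac evidence at gene TSSs
#'
#' H3K56ac gain at a gene means a treated-condition-unique consensus peak
#' overlaps its TSS window; loss means a control-unique peak does.
#' Accessibility direction comes from the gene's TSS-restricted ATAC
#' differential regions (the region with the largest `|log2fc|` wins when
#' several map to one gene). Genes with both gain and loss H3K56ac
#' evidence are flagged ambiguous and left uncalled, as are genes missing
#' either line of evidence or whose ATAC call is `unchanged`.
#'
#' @param atac_diff TSS-restricted differential regions with `gene_id`
#'   (from [restrict_to_tss()]).
#' @param unique_treated,unique_control Condition-unique [peak_set()]s
#'   (from [condition_unique()]); either may be empty.
#' @param genes Gene table; one call is emitted per gene.
#' @param tss_up,tss_down TSS window extents in bp (defaults 5000/3000).
#' @return Data.frame with one row per gene: `gene_id`, `category`,
#'   `atac_direction`, `log2fc`, `p_value`, `k56_evidence`
#'   (`gain`/`loss`/`ambiguous`/`none`), `atac_region`, `k56_region`.
#' @export
integrate_at_tss <- function(atac_diff, unique_treated, unique_control,
                             genes, tss_up = 5000, tss_down = 3000) {
  win <- tss_window(genes, tss_up, tss_down)
  wgr <- as_granges(win)

  hit_coords <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0L)
      return(list(has = rep(FALSE, nrow(genes)),
                  coord = rep(NA_character_, nrow(genes))))
    h <- IRanges::findOverlaps(wgr, as_granges(as.data.frame(peaks)))
    has <- seq_len(nrow(genes)) %in% S4Vectors::queryHits(h)
    coord <- rep(NA_character_, nrow(genes))
    if (length(h) > 0L) {
      p <- as.data.frame(peaks)[S4Vectors::subjectHits(h), , drop = FALSE]
      lab <- sprintf("%s:%.0f-%.0f", p$chrom, p$start, p$end)
      first <- !duplicated(S4Vectors::queryHits(h))
      coord[S4Vectors::queryHits(h)[first]] <- lab[first]
    }
    list(has = has, coord = coord)
  }
  gain <- hit_coords(unique_treated)
  loss <- hit_coords(unique_control)

  k56 <- ifelse(gain$has & loss$has, "ambiguous",
         ifelse(gain$has, "gain", ifelse(loss$has, "loss", "none")))
  k56_region <- ifelse(k56 == "gain", gain$coord,
                ifelse(k56 == "loss", loss$coord, NA_character_))

  atac_dir <- rep(NA_character_, nrow(genes))
  lfc <- rep(NA_real_, nrow(genes))
  pval <- rep(NA_real_, nrow(genes))
  atac_region <- rep(NA_character_, nrow(genes))
  ad <- as.data.frame(atac_diff)
  if (nrow(ad) > 0L) {
    idx <- match(ad$gene_id, genes$gene_id)
    keep <- !is.na(idx)
    ad <- ad[keep, , drop = FALSE]
    idx <- idx[keep]
    ord <- order(idx, -abs(ad$log2fc), ad$p_value)
    first <- !duplicated(idx[ord])
    sel <- ord[first]
    gi <- idx[sel]
    atac_dir[gi] <- ad$direction[sel]
    lfc[gi] <- ad$log2fc[sel]
    pval[gi] <- ad$p_value[sel]
    atac_region[gi] <- sprintf("%s:%.0f-%.0f", ad$chrom[sel], ad$start[sel],
                               ad$end[sel])
  }

  category <- rep("uncalled", nrow(genes))
  category[atac_dir %in% "gained-open" & k56 == "gain"] <- "I"
  category[atac_dir %in% "gained-closed" & k56 == "loss"] <- "II"
  category[atac_dir %in% "gained-closed" & k56 == "gain"] <- "III"
  category[atac_dir %in% "gained-open" & k56 == "loss"] <- "IV"

  data.frame(gene_id = genes$gene_id, category = category,
             atac_direction = ifelse(is.na(atac_dir), "none", atac_dir),
             log2fc = lfc, p_value = pval, k56_evidence = k56,
             atac_region = atac_region, k56_region = k56_region,
             stringsAsFactors = FALSE)
}

#' Count genes per integration category
#'
#' @param calls Output of [integrate_at_tss()].
#' @return Named integer vector over categories I, II, III, IV and
#'   uncalled, counting distinct gene ids.
#' @export
category_counts <- function(calls) {
  out <- vapply(CATEGORY_LEVELS, function(k) {
    length(unique(calls$gene_id[calls$category == k]))
  }, integer(1))
  out
}
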