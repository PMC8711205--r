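# Brute-force oracles and fixture builders shared across the suite.
# Oracles deliberately use per-base arrays / all-pairs scans, independent
# of the interval machinery they check.

# random interval set on a small genome
random_intervals <- function(n, n_chroms = 3, chrom_len = 1e5,
                             max_width = 2000) {
  w <- sample(seq_len(max_width), n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(chrom_len - wi, 1L), integer(1))
  data.frame(chrom = sample(sprintf("chr%d", seq_len(n_chroms)), n,
                            replace = TRUE),
             start = s, end = s + w, stringsAsFactors = FALSE)
}

# per-base overlap length between two single intervals
oracle_overlap_per_base <- function(a, b, chrom_len = 1e5) {
  if (a$chrom != b$chrom) return(0)
  occ <- logical(chrom_len)
  occ[(a$start + 1):a$end] <- TRUE
  sum(occ[(b$start + 1):b$end])
}

# per-base signal-block scan of a bedGraph track (one value per base)
oracle_blocks <- function(track, chrom_len = 1e4) {
  out <- lapply(split(track, track$chrom), function(tr) {
    v <- numeric(chrom_len)
    for (i in seq_len(nrow(tr)))
      v[(tr$start[i] + 1):tr$end[i]] <- tr$value[i]
    pos <- v > 0
    if (!any(pos)) return(NULL)
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(chrom = tr$chrom[1L], start = starts[keep],
               end = ends[keep],
               auc = vapply(which(keep), function(k)
                 sum(v[(starts[k] + 1):ends[k]]), numeric(1)),
               max_value = vapply(which(keep), function(k)
                 max(v[(starts[k] + 1):ends[k]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), auc = numeric(0),
                      max_value = numeric(0)))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# all-pairs + transitive-merge consensus oracle
oracle_consensus <- function(rep1, rep2, min_overlap = 300) {
  pairs <- list()
  for (i in seq_len(nrow(rep1))) for (j in seq_len(nrow(rep2))) {
    ov <- oracle_overlap_simple(rep1[i, ], rep2[j, ])
    if (ov >= min_overlap)
      pairs[[length(pairs) + 1L]] <- list(
        chrom = rep1$chrom[i],
        start = min(rep1$start[i], rep2$start[j]),
        end = max(rep1$end[i], rep2$end[j]),
        members = c(paste0("a", i), paste0("b", j)))
  }
  if (length(pairs) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), auc = numeric(0)))
  # merge chained overlapping spans until stable
  repeat {
    merged <- FALSE
    for (i in seq_along(pairs)) {
      for (j in seq_along(pairs)) {
        if (i >= j) next
        a <- pairs[[i]]; b <- pairs[[j]]
        if (a$chrom == b$chrom &&
            min(a$end, b$end) - max(a$start, b$start) > 0) {
          pairs[[i]] <- list(chrom = a$chrom,
                             start = min(a$start, b$start),
                             end = max(a$end, b$end),
                             members = union(a$members, b$members))
          pairs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  auc_of <- function(m) {
    src <- substr(m, 1, 1)
    idx <- as.integer(substring(m, 2))
    ifelse(src == "a", rep1$auc[idx], rep2$auc[idx])
  }
  out <- do.call(rbind, lapply(pairs, function(p)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               auc = sum(auc_of(p$members)), stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

oracle_overlap_simple <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# all-pairs gene assignment oracle (largest overlap, tie smallest start)
oracle_assign <- function(peaks, genes, flank = 10000,
                          tss_up = 5000, tss_down = 3000) {
  gene_id <- rep(NA_character_, nrow(peaks))
  feature <- rep("intergenic", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    best <- NA_integer_; best_ov <- 0
    for (j in seq_len(nrow(genes))) {
      fl <- list(chrom = genes$chrom[j],
                 start = max(0, genes$start[j] - flank),
                 end = genes$end[j] + flank)
      ov <- oracle_overlap_simple(peaks[i, ], fl)
      if (ov > best_ov ||
          (ov == best_ov && ov > 0 && !is.na(best) &&
           genes$start[j] < genes$start[best])) {
        best <- j; best_ov <- ov
      }
    }
    if (!is.na(best) && best_ov > 0) {
      gene_id[i] <- genes$gene_id[best]
      tss <- if (genes$strand[best] == "+") genes$start[best]
             else genes$end[best] - 1
      win <- if (genes$strand[best] == "+")
        list(chrom = genes$chrom[best], start = max(0, tss - tss_up),
             end = tss + tss_down)
      else
        list(chrom = genes$chrom[best], start = max(0, tss - tss_down + 1),
             end = tss + tss_up + 1)
      feature[i] <- if (oracle_overlap_simple(peaks[i, ], win) >= 1)
        "promoter" else "genebody"
    }
  }
  data.frame(peaks, gene_id = gene_id, feature = feature,
             stringsAsFactors = FALSE)
}

# minimum-likelihood two-sided exact binomial p by full enumeration
oracle_minlike_p <- function(k, n, p) {
  if (n == 0) return(1)
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# small peak_set builder
ps <- function(chrom, start, end, auc = NULL, max_value = NULL,
               condition = "c", replicate = "1") {
  n <- length(start)
  if (is.null(auc)) auc <- (end - start)
  if (is.null(max_value)) max_value <- rep(1, n)
  peak_set(data.frame(chrom = chrom, start = start, end = end, auc = auc,
                      max_value = max_value, stringsAsFactors = FALSE),
           condition, replicate)
}

# small region_counts builder with equal library sizes
rc_fixture <- function(counts, library_size = 1e6) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  regions <- data.frame(chrom = "chr1",
                        start = seq_len(n) * 1000,
                        end = seq_len(n) * 1000 + 500)
  samples <- data.frame(
    sample = c("control_1", "control_2", "treated_1", "treated_2"),
    condition = rep(c("control", "treated"), each = 2),
    replicate = rep(c("1", "2"), 2),
    library_size = rep(library_size, 4), stringsAsFactors = FALSE)
  region_counts(regions, samples, counts)
}

# condition-unique planted blocks taken straight from the truth manifest
# (unambiguous evidence peaks, bypassing track-level calling)
manifest_unique <- function(cfg, ann, condition) {
  b <- simulate_bedgraph(cfg, ann, condition, 1L)$blocks
  roles <- ann$roles$role[match(b$gene_id, ann$roles$gene_id)]
  keep <- if (condition == "treated") roles %in% c("I", "III")
          else roles %in% "II"
  peak_set(data.frame(b[keep, c("chrom", "start", "end")], auc = 1000,
                      max_value = 10), condition, "unique")
}

# BED data.frame -> GRanges (tests avoid reaching into package internals)
as_granges_df <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}
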