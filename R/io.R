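# Readers/writers for the plain-text formats the pipeline consumes.
# All package-written tables are tab-separated with a single header line
# beginning '#'; BED and bedGraph are written headerless, as is standard.

#' Write a tab-separated table with a '#'-prefixed header
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data.frame with column names taken from the '#' header line.
#' @export
read_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("expected a '#'-prefixed header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1L]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          comment.char = "")
  df
}

#' Read a BED3/BED6 interval file
#'
#' Tab-separated, headerless, 0-based half-open. Columns beyond the first
#' three (name, score, strand) are kept when present.
#'
#' @param path Path to a BED file.
#' @return Interval data.frame.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  k <- min(ncol(df) - 3L, 3L)
  if (k > 0L) names(df)[4:(3 + k)] <- extra[seq_len(k)]
  df
}

#' Write intervals as BED
#'
#' @param df Interval data.frame (`chrom`, `start`, `end`, optionally
#'   `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph coverage track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value); `track`
#'   and `#` lines are skipped.
#' @return Data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "track") & !startsWith(lines, "#")
  df <- utils::read.table(text = lines[keep], sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  df
}

#' Write a bedGraph coverage track
#'
#' @param df Data.frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Five tab-separated columns: chrom, start, end, strand, gene_id
#' (0-based half-open body coordinates). A '#' header line is tolerated.
#'
#' @param path Input path.
#' @return Gene data.frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "strand",
                                        "gene_id"))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene table strand column must be '+' or '-'")
  df
}

#' Read a RepeatMasker-style transposable element table
#'
#' Four tab-separated columns: chrom, start, end, te_class.
#'
#' @param path Input path.
#' @return TE data.frame.
#' @export
read_te_table <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    col.names = c("chrom", "start", "end", "te_class"))
}

#' Read an ATAC region count table and sample sheet
#'
#' The count table holds region BED columns followed by one count column
#' per sample; the sample sheet has columns sample, condition, replicate,
#' library_size. Both are '#'-headed TSVs as written by
#' [simulate_bundle()].
#'
#' @param counts_path Path to the region count TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @return A `region_counts` object (see [region_counts()]).
#' @export
read_region_counts <- function(counts_path, samples_path) {
  cts <- read_tsv(counts_path)
  samples <- read_tsv(samples_path)
  regions <- cts[, c("chrom", "start", "end")]
  mat <- as.matrix(cts[, samples$sample, drop = FALSE])
  region_counts(regions, samples, mat)
}

#' Read a chromatogram trace
#'
#' Two-column TSV/CSV (time in minutes, A214 in mAU); the delimiter is
#' sniffed from the first line.
#'
#' @param path Input path.
#' @return A data.frame with columns `time` and `a214`.
#' @export
read_chromatogram <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.table(path, sep = sep, header = FALSE, skip = skip,
                          col.names = c("time", "a214"))
  chromatogram(df$time, df$a214)
}

#' Read a peak window table (label, t_start, t_end)
#'
#' @param path '#'-headed TSV with columns label, t_start, t_end.
#' @return Data.frame of labelled retention-time windows.
#' @export
read_peak_windows <- function(path) {
  df <- read_tsv(path)
  validate_windows(df)
  df
}

#' Read a subtype specification table (label, residues)
#'
#' Peptide-bond counts are `residues - 1`.
#'
#' @param path '#'-headed TSV with columns label, residues.
#' @return Data.frame with columns label, residues, n_peptide_bonds.
#' @export
read_subtype_spec <- function(path) {
  df <- read_tsv(path)
  df$n_peptide_bonds <- df$residues - 1L
  if (any(df$n_peptide_bonds <= 0)) stop("residue counts must be >= 2")
  df
}
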