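# End-to-end orchestration: peak calling -> differential accessibility ->
# annotation -> integration -> H1 quantification, with per-stage TSV
# outputs and a machine-readable run log. Stages whose inputs are absent
# are skipped, with downstream stages degrading gracefully.

#' Pipeline configuration
#'
#' Collects input paths and analysis parameters. Every default matches
#' the study's printed parameter set: peak-calling threshold 0.05
#' (stringent), replicate overlap minimum 300 bp, p-value threshold
#' 0.001, fold-change threshold 4, TSS window 5000 bp upstream / 3000 bp
#' downstream, genebody flank 10000 bp.
#'
#' @param bedgraphs Nested list `condition -> list(rep1_path, rep2_path)`
#'   of CUT&RUN bedGraph tracks, or `NULL` to skip peak calling.
#' @param counts,samples Paths to the ATAC count table and sample sheet,
#'   or `NULL` to skip the differential stage.
#' @param genes Path to the gene table (required for annotation,
#'   TSS restriction and integration).
#' @param tes Path to the TE table, or `NULL` to skip TE proportions.
#' @param chromatograms List `condition -> trace path`, or `NULL` to
#'   skip H1 quantification.
#' @param h1_windows,h1_subtypes Paths to the window and subtype tables.
#' @param outdir Output directory.
#' @param peak_threshold SEACR-style top fraction (default 0.05).
#' @param min_overlap Replicate consensus minimum overlap, bp
#'   (default 300).
#' @param flank Genebody flank for gene assignment, bp (default 10000).
#' @param thresholds A [differential_thresholds()] list.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bedgraphs = NULL, counts = NULL,
                            samples = NULL, genes = NULL, tes = NULL,
                            chromatograms = NULL, h1_windows = NULL,
                            h1_subtypes = NULL, outdir = ".",
                            peak_threshold = 0.05, min_overlap = 300,
                            flank = 10000,
                            thresholds = differential_thresholds(),
                            seed = 1L) {
  structure(list(bedgraphs = bedgraphs, counts = counts,
                 samples = samples, genes = genes, tes = tes,
                 chromatograms = chromatograms, h1_windows = h1_windows,
                 h1_subtypes = h1_subtypes, outdir = outdir,
                 peak_threshold = peak_threshold,
                 min_overlap = min_overlap, flank = flank,
                 thresholds = thresholds, seed = seed),
            class = "pipeline_config")
}

#' Convenience: pipeline configuration for a synthetic bundle
#'
#' @param paths The `paths` element returned by [simulate_bundle()].
#' @param outdir Output directory.
#' @param ... Passed to [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
bundle_config <- function(paths, outdir, ...) {
  pipeline_config(
    bedgraphs = paths$bedgraph, counts = paths$counts,
    samples = paths$samples, genes = paths$genes, tes = paths$tes,
    chromatograms = paths$chromatogram, h1_windows = paths$windows,
    h1_subtypes = paths$subtypes, outdir = outdir, ...)
}

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Executes peak calling, differential accessibility, annotation,
#' integration and H1 quantification on the configured inputs, writing
#' per-stage TSVs and a JSON run log (parameters, package version, input
#' checksums) to `cfg$outdir`. Stages with missing inputs are skipped;
#' integration without CUT&RUN input reports every gene as uncalled.
#' The run is deterministic: identical inputs give byte-identical
#' outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages (default FALSE).
#' @return Invisibly, a list of in-memory stage results plus
#'   `output_files` (paths of everything written).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  res <- list()
  files <- character(0)
  emit <- function(df, name) {
    write_tsv(as.data.frame(df), out(name))
    files <<- c(files, out(name))
  }
  genes <- if (!is.null(cfg$genes)) read_gene_table(cfg$genes) else NULL

  # -- peak calling ---------------------------------------------------
  unique_sets <- list(control = NULL, treated = NULL)
  if (!is.null(cfg$bedgraphs)) {
    consensus <- list()
    for (cond in names(cfg$bedgraphs)) {
      reps <- cfg$bedgraphs[[cond]]
      filtered <- lapply(seq_along(reps), function(i) {
        stage_msg(quiet, "peakcalling: %s replicate %d", cond, i)
        blocks <- segment_signal_blocks(read_bedgraph(reps[[i]]))
        ps <- call_peaks(blocks, cfg$peak_threshold,
                         condition = cond, replicate = as.character(i))
        ps <- half_mean_filter(ps)
        emit(ps, sprintf("peaks_%s_rep%d.tsv", cond, i))
        ps
      })
      cons <- Reduce(function(a, b)
        replicate_consensus(a, b, cfg$min_overlap), filtered)
      consensus[[cond]] <- cons
      emit(cons, sprintf("consensus_%s.tsv", cond))
    }
    if (all(c("control", "treated") %in% names(consensus))) {
      unique_sets$treated <- condition_unique(consensus$treated,
                                              consensus$control)
      unique_sets$control <- condition_unique(consensus$control,
                                              consensus$treated)
      emit(unique_sets$treated, "unique_treated.tsv")
      emit(unique_sets$control, "unique_control.tsv")
    }
    res$consensus <- consensus
    res$unique <- unique_sets
  }

  # -- differential accessibility -------------------------------------
  diff <- NULL
  diff_tss <- NULL
  if (!is.null(cfg$counts) && !is.null(cfg$samples)) {
    stage_msg(quiet, "differential: exact region tests")
    tab <- read_region_counts(cfg$counts, cfg$samples)
    test <- exact_region_test(tab)
    diff <- classify_differential(tab$regions, test, cfg$thresholds)
    emit(diff, "differential.tsv")
    if (!is.null(genes)) {
      diff_tss <- restrict_to_tss(diff, genes, cfg$thresholds)
      emit(diff_tss, "differential_tss.tsv")
    }
    res$differential <- diff
    res$differential_tss <- diff_tss
  }

  # -- annotation ------------------------------------------------------
  if (!is.null(genes) && !is.null(res$unique)) {
    fractions <- NULL
    for (cond in c("control", "treated")) {
      ps <- unique_sets[[cond]]
      if (is.null(ps)) next
      stage_msg(quiet, "annotation: %s unique peaks", cond)
      asg <- assign_genes(ps, genes, cfg$flank,
                          cfg$thresholds$tss_up, cfg$thresholds$tss_down)
      emit(asg, sprintf("annotation_unique_%s.tsv", cond))
      if (nrow(asg) > 0) {
        fr <- feature_fractions(asg)
        fractions <- rbind(fractions,
                           data.frame(condition = cond,
                                      feature = names(fr),
                                      proportion = as.numeric(fr)))
      }
    }
    if (!is.null(fractions)) emit(fractions, "feature_fractions.tsv")
    res$feature_fractions <- fractions
  }
  if (!is.null(cfg$tes) && !is.null(diff)) {
    stage_msg(quiet, "annotation: TE overlap proportions")
    te_prop <- te_overlap_proportions(diff, read_te_table(cfg$tes))
    emit(te_prop, "te_proportions.tsv")
    res$te_proportions <- te_prop
  }

  # -- integration -----------------------------------------------------
  if (!is.null(genes) && !is.null(diff_tss)) {
    stage_msg(quiet, "integration: joint ATAC x H3K56ac calls")
    calls <- integrate_at_tss(diff_tss, unique_sets$treated,
                              unique_sets$control, genes,
                              cfg$thresholds$tss_up,
                              cfg$thresholds$tss_down)
    emit(calls, "integration.tsv")
    cc <- category_counts(calls)
    emit(data.frame(category = names(cc), n_genes = as.integer(cc)),
         "category_counts.tsv")
    res$integration <- calls
    res$category_counts <- cc
  }

  # -- H1 stoichiometry ------------------------------------------------
  if (!is.null(cfg$chromatograms) && !is.null(cfg$h1_windows) &&
      !is.null(cfg$h1_subtypes)) {
    stage_msg(quiet, "h1_quant: chromatogram integration")
    windows <- read_peak_windows(cfg$h1_windows)
    subtypes <- read_subtype_spec(cfg$h1_subtypes)
    stoich <- NULL
    ratios <- list()
    for (cond in names(cfg$chromatograms)) {
      tr <- read_chromatogram(cfg$chromatograms[[cond]])
      q <- quantify_h1(tr, windows, subtypes)
      ratios[[cond]] <- q
      stoich <- rbind(stoich, data.frame(
        condition = cond,
        subtype = c(names(q$per_subtype_ratio), "total"),
        ratio = c(as.numeric(q$per_subtype_ratio), q$total_ratio)))
    }
    emit(stoich, "h1_stoichiometry.tsv")
    if (all(c("control", "treated") %in% names(ratios))) {
      pc <- percent_change(ratios$control$total_ratio,
                           ratios$treated$total_ratio)
      emit(data.frame(ratio_control = ratios$control$total_ratio,
                      ratio_treated = ratios$treated$total_ratio,
                      percent_change_exact = pc$exact,
                      percent_change = pc$truncated),
           "h1_comparison.tsv")
      res$h1_comparison <- pc
    }
    res$h1 <- ratios
  }

  # -- run log ---------------------------------------------------------
  inputs <- unlist(cfg[c("counts", "samples", "genes", "tes",
                         "h1_windows", "h1_subtypes")])
  inputs <- c(inputs, unlist(cfg$bedgraphs), unlist(cfg$chromatograms))
  log <- list(
    package = "chromintegrate",
    version = as.character(utils::packageVersion("chromintegrate")),
    seed = cfg$seed,
    parameters = list(peak_threshold = cfg$peak_threshold,
                      peak_mode = "stringent",
                      min_overlap = cfg$min_overlap,
                      flank = cfg$flank,
                      p_threshold = cfg$thresholds$p_threshold,
                      fc_threshold = cfg$thresholds$fc_threshold,
                      tss_up = cfg$thresholds$tss_up,
                      tss_down = cfg$thresholds$tss_down),
    inputs = as.list(tools::md5sum(inputs[!is.na(inputs)])),
    outputs = basename(files))
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, out("run_log.json"))
  res$output_files <- files
  invisible(res)
}
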